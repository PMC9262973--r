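#' Default pipeline configuration
#'
#' Central defaults for the quantification pipeline. Key constants follow
#' the assay design: fields are 583 x 583 um squares sampled 5 per
#' explant; an explant is a 1.5 x 1.5 cm sample, so it holds
#' `round((15000/583)^2) = 662` such squares; the invasion score averages
#' the `k_deepest = 3` deepest cells per field.
#'
#' @return A named list of class `run_config` with components `detector`
#'   (`radius_um`, `threshold`, `min_separation_um`), `surface`
#'   (`block_um`, `smoothing_scale_um`, `onset_fraction`,
#'   `min_coverage_for_map`, `max_slope`), `scoring` (`k_deepest`,
#'   `n_fields`, `n_squares_per_explant`), `stats` (`alpha`,
#'   `correction`), and `seed`.
#' @export
default_run_config <- function() {
  structure(list(
    detector = list(
      radius_um = 7,           # expected cell blob radius
      threshold = NULL,        # NULL = auto (robust noise-based)
      min_separation_um = NULL # NULL = 1.5 * radius_um
    ),
    surface = list(
      block_um = 9,            # lateral averaging block for column profiles
      smoothing_scale_um = 20, # Gaussian smoothing of the height map
      onset_fraction = 0.5,    # fraction of column robust max defining onset
      min_coverage_for_map = 0.2, # below this, fall back to a global plane
      max_slope = 1            # um height per um lateral, sanity bound (45 deg)
    ),
    scoring = list(
      k_deepest = 3L,
      n_fields = 5L,
      n_squares_per_explant = 662L
    ),
    stats = list(
      alpha = 0.05,
      correction = "bonferroni"
    ),
    seed = 1L
  ), class = "run_config")
}

validate_config <- function(cfg) {
  s <- cfg$scoring
  if (!is.numeric(s$k_deepest) || s$k_deepest < 1)
    stop_bad("scoring$k_deepest must be >= 1")
  if (s$n_fields < 1) stop_bad("scoring$n_fields must be >= 1")
  if (s$n_squares_per_explant < 1)
    stop_bad("scoring$n_squares_per_explant must be >= 1")
  st <- cfg$stats
  if (!is.numeric(st$alpha) || st$alpha <= 0 || st$alpha >= 1)
    stop_bad("stats$alpha must be in (0, 1)")
  d <- cfg$detector
  if (!is.null(d$radius_um) && d$radius_um <= 0)
    stop_bad("detector$radius_um must be positive")
  cfg
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Absent keys take the defaults of [default_run_config()]; an empty file
#' yields the full default configuration. Values violating the config
#' invariants (e.g. `k_deepest < 1`, `alpha` outside (0, 1)) are errors.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for
#'   pure defaults.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(validate_config(cfg))
  if (!file.exists(path)) stop_bad("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop_bad("config must be a mapping of sections")
  for (sec in intersect(names(user), names(cfg))) {
    if (is.list(cfg[[sec]]) && is.list(user[[sec]])) {
      unknown <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
      if (length(unknown))
        stop_bad("unknown config key(s) in ", sec, ": ",
                 paste(unknown, collapse = ", "))
      cfg[[sec]] <- utils::modifyList(cfg[[sec]], user[[sec]], keep.null = TRUE)
    } else {
      cfg[[sec]] <- user[[sec]]
    }
  }
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop_bad("unknown config section(s): ", paste(unknown, collapse = ", "))
  validate_config(cfg)
}

#' Write a configuration back to YAML
#' @param cfg A `run_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Stable short hash of a config (for run logs/manifests): md5 of its
# canonical YAML dump.
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  dump_config(cfg, f)
  unname(tools::md5sum(f))
}
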