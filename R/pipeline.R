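# Pipeline orchestration: simulate -> detect -> surface -> score ->
# compare, reproducible from one master seed. Each stage derives its
# seeds from the master via the documented counter scheme in
# derive_seed(), so stages are individually reproducible.

write_run_log <- function(dir, lines) {
  if (is.null(dir)) return(invisible(NULL))
  cat(paste0(lines, "\n"), file = file.path(dir, "run.log"), append = TRUE)
  invisible(NULL)
}

#' Simulate an explant experiment to disk
#'
#' Renders every field's stack (TIFF + JSON sidecar) plus
#' `manifest.csv`, `suspension.csv`, the configuration used and a run
#' log into `out_dir`.
#'
#' @param arms List of [arm_spec()]s.
#' @param out_dir Output directory; must not exist unless `force`.
#' @param seed Master seed.
#' @param days Assay days.
#' @param params_template Imaging geometry ([generator_params()]).
#' @param config Pipeline configuration (recorded for provenance).
#' @param force Overwrite an existing `out_dir`.
#' @return The `explant_experiment` object, invisibly.
#' @export
run_simulate <- function(arms, out_dir, seed = 1L, days = 1L,
                         params_template = generator_params(),
                         config = default_run_config(), force = FALSE) {
  if (dir.exists(out_dir) && !force)
    stop_bad("output dir exists: ", out_dir, " (use force = TRUE)")
  if (dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)
  dir.create(out_dir, recursive = TRUE)
  t0 <- Sys.time()
  expt <- generate_experiment(arms, seed = seed, days = days,
                              params_template = params_template,
                              stacks = "disk", dir = out_dir)
  dump_config(config, file.path(out_dir, "config.yaml"))
  write_run_log(out_dir, c(
    sprintf("stage: simulate  seed: %d  config: %s", seed, config_hash(config)),
    sprintf("fields: %d  elapsed_s: %.1f", nrow(expt$manifest),
            as.numeric(difftime(Sys.time(), t0, units = "secs")))))
  invisible(expt)
}

# Load a disk dataset written by run_simulate() back into the in-memory
# explant_experiment shape (stacks stay on disk, referenced by path).
load_experiment <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop_bad("no manifest.csv in ", dir)
  manifest <- read.csv(mf, stringsAsFactors = FALSE)
  susp <- read.csv(file.path(dir, "suspension.csv"), stringsAsFactors = FALSE)
  gtf <- file.path(dir, "ground_truth.csv")
  gt <- if (file.exists(gtf)) read.csv(gtf, stringsAsFactors = FALSE) else NULL
  fields <- lapply(seq_len(nrow(manifest)), function(i) {
    rec <- as.list(manifest[i, ])
    if (!is.null(gt)) {
      sel <- gt$sample_id == rec$sample_id & gt$day == rec$day &
        gt$field == rec$field
      rec$cells <- gt[sel, c("x_um", "y_um", "z_mid_um", "depth_um")]
    }
    rec
  })
  structure(list(fields = fields, manifest = manifest, suspension = susp,
                 arms = NULL, seed = NA_integer_, dir = dir),
            class = "explant_experiment")
}

field_stack <- function(rec) {
  if (!is.null(rec$path) && !is.na(rec$path) && file.exists(rec$path)) {
    list(stack = read_stack(rec$path), truth = NULL)
  } else if (!is.null(rec$params)) {
    generate_stack(rec$params)
  } else {
    stop_bad("field has neither a stack file nor generator parameters")
  }
}

#' Quantify an explant dataset: counts, depths, scores, statistics
#'
#' For every field: implantation count from LoG detection on the red
#' maximum projection; invasion depths from 3D detection against the
#' reflectance-estimated surface. Per sample and day, counts become the
#' normalized implantation score and depths the invasion score (mean of
#' the `k_deepest` deepest cells per field, averaged over fields and
#' observers). With `ground_truth_mode = TRUE`, detection and surface
#' estimation are bypassed and planted positions/depths are used
#' directly (the oracle path).
#'
#' @param dataset An `explant_experiment` (in-memory from
#'   [generate_experiment()] or a directory path from [run_simulate()]).
#' @param config Pipeline configuration ([default_run_config()]).
#' @param ground_truth_mode Use planted ground truth instead of
#'   detection.
#' @param out_dir Optional directory for per-field/per-sample/stats CSVs
#'   and a run log.
#' @return List with data frames `fields` (per-field count and invasion),
#'   `scores` (per sample x day ScoreRecord-style rows), and `stats`
#'   (from [compare_arms()]; `NULL` with a single arm).
#' @export
run_quantify <- function(dataset, config = default_run_config(),
                         ground_truth_mode = FALSE, out_dir = NULL) {
  if (is.character(dataset)) dataset <- load_experiment(dataset)
  stopifnot(inherits(dataset, "explant_experiment"))
  if (!length(dataset$fields)) stop_bad("empty dataset")
  cfg <- validate_config(config)
  det <- cfg$detector
  t0 <- Sys.time()
  rows <- list()
  failed <- 0L
  for (rec in dataset$fields) {
    fr <- tryCatch({
      if (ground_truth_mode) {
        cells <- rec$cells %||% rec$params$cells
        if (is.null(cells)) stop_bad("no ground truth cells for field")
        count <- nrow(cells)
        depths <- cells$depth_um
      } else {
        fs <- field_stack(rec)
        proj <- max_project(fs$stack)
        s2 <- detect_spots_2d(proj, radius_um = det$radius_um,
                              threshold = det$threshold,
                              min_separation_um = det$min_separation_um)
        count <- nrow(s2)
        s3 <- detect_spots_3d(fs$stack, radius_um = det$radius_um,
                              threshold = det$threshold,
                              min_separation_um = det$min_separation_um)
        surf <- estimate_surface(fs$stack, cfg$surface)
        depths <- cell_depth(s3, surf)
      }
      fi <- field_invasion(depths, k = cfg$scoring$k_deepest)
      data.frame(arm = rec$arm, sample_id = rec$sample_id, day = rec$day,
                 field = rec$field, count = count,
                 field_invasion_um = as.numeric(fi),
                 short_field = isTRUE(attr(fi, "short_field")),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("field skipped (", rec$sample_id, " day ", rec$day, " field ",
              rec$field, "): ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(fr)) failed <- failed + 1L else rows[[length(rows) + 1L]] <- fr
  }
  if (!length(rows)) stop_bad("all fields failed or missing")
  fields <- do.call(rbind, rows)

  susp <- dataset$suspension
  scores <- do.call(rbind, lapply(
    split(fields, list(fields$sample_id, fields$day), drop = TRUE),
    function(g) {
      live <- susp$live_suspension_count[match(g$sample_id[1L], susp$sample_id)]
      inv <- combine_observers(sample_invasion(g$field_invasion_um))
      data.frame(
        sample_id = g$sample_id[1L], day = g$day[1L], arm = g$arm[1L],
        implantation_score = implantation_score(
          mean(g$count), cfg$scoring$n_squares_per_explant, live),
        invasion_score_um = as.numeric(inv),
        n_fields = nrow(g), observers = 1L,
        live_suspension_count = live, stringsAsFactors = FALSE)
    }))
  rownames(scores) <- NULL
  stats_tab <- if (length(unique(scores$arm)) >= 2L) {
    compare_arms(scores, alpha = cfg$stats$alpha,
                 correction = cfg$stats$correction)
  } else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(fields, file.path(out_dir, "fields.csv"), row.names = FALSE)
    write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)
    if (!is.null(stats_tab))
      write.csv(stats_tab, file.path(out_dir, "stats.csv"), row.names = FALSE)
    write_run_log(out_dir, c(
      sprintf("stage: quantify  config: %s  ground_truth_mode: %s",
              config_hash(cfg), ground_truth_mode),
      sprintf("fields_ok: %d  fields_failed: %d  elapsed_s: %.1f",
              nrow(fields), failed,
              as.numeric(difftime(Sys.time(), t0, units = "secs")))))
  }
  list(fields = fields, scores = scores, stats = stats_tab)
}

#' Publication-style summary: mean +/- SEM per arm per day
#'
#' @param scores Score data frame from [run_quantify()].
#' @param out_path Optional CSV output path.
#' @return Data frame with one row per arm x day: n, mean and SEM of the
#'   implantation and invasion scores, sorted by day then arm.
#' @export
run_report <- function(scores, out_path = NULL) {
  if (!nrow(scores)) stop_bad("no score records")
  out <- do.call(rbind, lapply(
    split(scores, list(scores$arm, scores$day), drop = TRUE),
    function(g) data.frame(
      arm = g$arm[1L], day = g$day[1L], n = nrow(g),
      implantation_mean = mean(g$implantation_score),
      implantation_sem = if (nrow(g) > 1L) sem(g$implantation_score) else 0,
      invasion_mean_um = mean(g$invasion_score_um, na.rm = TRUE),
      invasion_sem_um = if (nrow(g) > 1L) sem(g$invasion_score_um) else 0,
      stringsAsFactors = FALSE)))
  out <- out[order(out$day, out$arm), ]
  rownames(out) <- NULL
  if (!is.null(out_path)) write.csv(out, out_path, row.names = FALSE)
  out
}

#' Run the full pipeline in memory
#'
#' Simulate (lazily, no disk stacks), quantify and report in one call.
#'
#' @inheritParams run_simulate
#' @inheritParams run_quantify
#' @return List with `experiment`, `fields`, `scores`, `stats`, `report`.
#' @export
run_all <- function(arms, seed = 1L, days = 1L,
                    params_template = generator_params(),
                    config = default_run_config(),
                    ground_truth_mode = FALSE) {
  expt <- generate_experiment(arms, seed = seed, days = days,
                              params_template = params_template)
  q <- run_quantify(expt, config = config,
                    ground_truth_mode = ground_truth_mode)
  c(list(experiment = expt), q, list(report = run_report(q$scores)))
}
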