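# Synthetic two-channel confocal stacks with planted ground truth.
#
# The generator emulates the explant imaging design: 583 x 583 um fields
# on a 512 px lateral grid, z-planes 2 um apart over a 50-75 um depth,
# red tracker-stained cell blobs planted at controlled depths below a
# mesothelial surface, and textured green collagen reflectance present
# only at and below that surface. Intensities are detector counts:
# Poisson shot noise on signal plus Gaussian read noise, rounded to
# integer ADUs and clamped at zero.

#' Parameters for the synthetic stack generator
#'
#' Defaults mirror the imaging conditions the pipeline is designed for:
#' five 583 x 583 um fields per explant on a 512 px grid (1.139 um/px),
#' z-step 2 um over 60 um total depth, cell blobs of 7 um radius
#' (isotropic 3D Gaussian, sigma = radius/2), exponential invasion-depth
#' distribution, and blob peak amplitude `snr` times the background noise
#' standard deviation.
#'
#' @param field_size_um Lateral field extent (square), um.
#' @param pixels_per_axis Lateral grid size in pixels.
#' @param z_step_um Axial plane spacing, um.
#' @param z_depth_um Total imaged depth, um; planes sit at
#'   `0, z_step, ..., floor(z_depth/z_step)*z_step` (so 60 um at 2 um
#'   spacing gives 31 planes).
#' @param surface Surface model: `list(type = "plane", z0_um, tilt_x,
#'   tilt_y)` with `z = z0 + tilt_x*x + tilt_y*y`, or `list(type =
#'   "sheet", z0_um, amplitude_um, n_modes, wavelength_um)` for a smooth
#'   random low-order sheet.
#' @param n_cells Number of planted red cell blobs.
#' @param cell_radius_um Blob radius; the Gaussian sigma is half this.
#' @param depth_distribution `list(type = "exponential", mean_um)` for
#'   planted mid-point depths below the surface (shallow penetration), or
#'   `list(type = "fixed", depth_um)`.
#' @param min_cell_separation_um Minimum pairwise lateral (x, y)
#'   distance between planted cell centers (rejection-sampled); lateral
#'   separation is what keeps blobs distinct in the en-face projection.
#' @param snr Blob peak amplitude divided by background noise sd.
#' @param red_baseline,green_baseline Mean background counts per channel.
#' @param read_noise_sd Gaussian read noise sd (counts).
#' @param collagen_texture `list(amplitude, sd, corr_length_um, coverage)`:
#'   mean reflectance level below the surface, texture sd, lateral
#'   correlation length, and the fraction of the field carrying
#'   reflectance at all (`coverage < 1` emulates a patchy, late-day
#'   mesothelial surface).
#' @param noise If `FALSE`, return the noise-free expectation (float,
#'   not rounded) instead of noisy integer counts.
#' @param cells Optional pre-specified cells: a data frame with
#'   `x_um, y_um` and either `depth_um` or `z_mid_um`. When given, the
#'   seed controls only the noise realization.
#' @param seed RNG seed; all generator output is bit-reproducible.
#' @return A validated `generator_params` list.
#' @export
generator_params <- function(field_size_um = 583,
                             pixels_per_axis = 512L,
                             z_step_um = 2,
                             z_depth_um = 60,
                             surface = list(type = "plane", z0_um = 12,
                                            tilt_x = 0, tilt_y = 0),
                             n_cells = 20L,
                             cell_radius_um = 7,
                             depth_distribution = list(type = "exponential",
                                                       mean_um = 10),
                             min_cell_separation_um = 2 * cell_radius_um,
                             snr = 10,
                             red_baseline = 10,
                             green_baseline = 2,
                             read_noise_sd = 3,
                             collagen_texture = list(amplitude = 50, sd = 15,
                                                     corr_length_um = 5,
                                                     coverage = 1),
                             noise = TRUE,
                             cells = NULL,
                             seed = 1L) {
  p <- list(field_size_um = field_size_um, pixels_per_axis = as.integer(pixels_per_axis),
            z_step_um = z_step_um, z_depth_um = z_depth_um, surface = surface,
            n_cells = as.integer(n_cells), cell_radius_um = cell_radius_um,
            depth_distribution = depth_distribution,
            min_cell_separation_um = min_cell_separation_um, snr = snr,
            red_baseline = red_baseline, green_baseline = green_baseline,
            read_noise_sd = read_noise_sd, collagen_texture = collagen_texture,
            noise = isTRUE(noise), cells = cells, seed = as.integer(seed))
  if (p$field_size_um <= 0 || p$pixels_per_axis < 8L)
    stop_bad("invalid lateral geometry: field_size_um must be > 0 and ",
             "pixels_per_axis >= 8")
  if (p$z_step_um <= 0 || p$z_depth_um <= 0)
    stop_bad("invalid axial geometry: z_step_um and z_depth_um must be > 0")
  if (p$n_cells < 0L) stop_bad("n_cells must be >= 0")
  if (p$snr <= 0) stop_bad("snr must be > 0")
  if (p$cell_radius_um <= 0) stop_bad("cell_radius_um must be > 0")
  cov <- p$collagen_texture$coverage %||% 1
  if (cov < 0 || cov > 1) stop_bad("collagen coverage must be in [0, 1]")
  structure(p, class = "generator_params")
}

# z-plane grid implied by the params: planes at 0, dz, ..., k*dz with
# k = floor(z_depth/dz), i.e. floor(depth/step) + 1 planes (equivalently
# ceiling(depth/step) + 1 when step divides depth).
z_grid <- function(params) {
  seq(0, by = params$z_step_um,
      length.out = floor(params$z_depth_um / params$z_step_um) + 1L)
}

# True surface height z_s(x, y) in um for the parametric surface models.
surface_truth_fun <- function(surface, field_size_um, seed) {
  type <- surface$type %||% "plane"
  if (type == "plane") {
    z0 <- surface$z0_um %||% 12
    tx <- surface$tilt_x %||% 0
    ty <- surface$tilt_y %||% 0
    function(x, y) z0 + tx * x + ty * y
  } else if (type == "sheet") {
    z0 <- surface$z0_um %||% 12
    amp <- surface$amplitude_um %||% 3
    n <- surface$n_modes %||% 3L
    wl <- surface$wavelength_um %||% (field_size_um / 2)
    set.seed(derive_seed(seed, 991L))
    th <- runif(n, 0, 2 * pi)
    ph <- runif(n, 0, 2 * pi)
    am <- amp * runif(n, 0.5, 1) / sqrt(n)
    function(x, y) {
      z <- z0
      for (i in seq_len(n))
        z <- z + am[i] * cos(2 * pi * (x * cos(th[i]) + y * sin(th[i])) / wl + ph[i])
      z
    }
  } else stop_bad("unknown surface model type: ", type)
}

# Sample cell positions and depths for one field. Positions are uniform
# with a one-radius lateral margin; pairwise 3D separation is enforced by
# rejection; exponential depths are redrawn (then clamped) to keep the
# blob inside the imaged depth.
plant_cells <- function(params, surf_fun) {
  n <- params$n_cells
  cols <- c("x_um", "y_um", "z_mid_um", "depth_um")
  if (!is.null(params$cells)) {
    cells <- as.data.frame(params$cells)
    if (nrow(cells)) {
      if (is.null(cells$z_mid_um))
        cells$z_mid_um <- surf_fun(cells$x_um, cells$y_um) + cells$depth_um
      if (is.null(cells$depth_um))
        cells$depth_um <- cells$z_mid_um - surf_fun(cells$x_um, cells$y_um)
      if (any(cells$depth_um < -1e-9))
        stop_bad("pre-specified cells must lie at or below the surface")
    } else cells <- data.frame(x_um = numeric(), y_um = numeric(),
                               z_mid_um = numeric(), depth_um = numeric())
    return(cells[cols])
  }
  if (n == 0L)
    return(data.frame(x_um = numeric(), y_um = numeric(),
                      z_mid_um = numeric(), depth_um = numeric()))
  fs <- params$field_size_um
  margin <- min(params$cell_radius_um, fs / 4)
  zmax <- max(z_grid(params))
  dd <- params$depth_distribution
  draw_depth <- function() {
    if ((dd$type %||% "exponential") == "fixed") return(dd$depth_um)
    rexp(1L, rate = 1 / dd$mean_um)
  }
  xs <- ys <- zs <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(5000L)) {
      x <- runif(1L, margin, fs - margin)
      y <- runif(1L, margin, fs - margin)
      s <- surf_fun(x, y)
      d <- NA_real_
      for (dt in seq_len(50L)) {
        d <- draw_depth()
        if (s + d <= zmax - params$z_step_um) break
      }
      d <- min(d, max(0, zmax - params$z_step_um - s))
      z <- s + d
      if (i == 1L) ok <- TRUE
      else {
        j <- seq_len(i - 1L)
        ok <- all(sqrt((xs[j] - x)^2 + (ys[j] - y)^2) >=
                    params$min_cell_separation_um)
      }
      if (ok) { xs[i] <- x; ys[i] <- y; zs[i] <- z; placed <- TRUE; break }
    }
    if (!placed)
      stop_bad("could not place ", n, " cells at the requested separation")
  }
  data.frame(x_um = xs, y_um = ys, z_mid_um = zs,
             depth_um = zs - surf_fun(xs, ys))
}

# Build a surface_map object from the analytic truth surface, sampled on
# a coarse lateral grid (bilinear interpolation is exact for planes).
truth_surface_map <- function(surf_fun, params, step_px = 2L) {
  dxy <- params$field_size_um / params$pixels_per_axis
  cx <- (seq(1, params$pixels_per_axis, by = step_px) - 0.5) * dxy
  zmat <- outer(cx, cx, function(y, x) surf_fun(x, y))
  new_surface_map(z = zmat, x_um = cx, y_um = cx, coverage = 1,
                  settings = list(source = "ground_truth"))
}

#' Generate one synthetic two-channel stack with ground truth
#'
#' The red channel contains `n_cells` isotropic 3D Gaussian blobs
#' (sigma = `cell_radius_um / 2`) with peak amplitude `snr` times the
#' background noise sd; the green channel carries textured collagen
#' reflectance only at and below the mesothelial surface. Noise is
#' Poisson shot noise on signal plus baseline, plus Gaussian read noise,
#' rounded to integer counts. Output is bit-reproducible for a fixed
#' seed.
#'
#' @param params A [generator_params()] object.
#' @return A list with elements `stack` (an [image_stack]) and `truth`
#'   (class `ground_truth`: `cells` data frame with
#'   `x_um, y_um, z_mid_um, depth_um`, `surface` (a `surface_map`), and
#'   `params`).
#' @export
generate_stack <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed)
  np <- params$pixels_per_axis
  dxy <- params$field_size_um / np
  zg <- z_grid(params)
  nz <- length(zg)
  surf_fun <- surface_truth_fun(params$surface, params$field_size_um, params$seed)
  cells <- plant_cells(params, surf_fun)

  sigma_bg_red <- sqrt(params$red_baseline + params$read_noise_sd^2)
  amp <- params$snr * sigma_bg_red
  sig <- params$cell_radius_um / 2

  # red signal: sum of local Gaussian blobs
  red <- array(0, c(nz, np, np))
  px_centers <- (seq_len(np) - 0.5) * dxy
  for (i in seq_len(nrow(cells))) {
    ex <- exp(-(px_centers - cells$x_um[i])^2 / (2 * sig^2))
    ey <- exp(-(px_centers - cells$y_um[i])^2 / (2 * sig^2))
    ez <- exp(-(zg - cells$z_mid_um[i])^2 / (2 * sig^2))
    xi <- which(ex > 1e-4); yi <- which(ey > 1e-4); zi <- which(ez > 1e-4)
    if (!length(xi) || !length(yi) || !length(zi)) next
    blob <- amp * (ez[zi] %o% ey[yi] %o% ex[xi])
    red[zi, yi, xi] <- red[zi, yi, xi] + blob
  }

  # green signal: textured reflectance at/below the surface only.
  # Texture is generated on a half-resolution lateral grid and upsampled:
  # its correlation length (~5 um) is several pixels, so no structure is
  # lost, and the smoothing cost drops fourfold.
  ct <- params$collagen_texture
  xy <- expand.grid(y = px_centers, x = px_centers)
  zs_full <- matrix(surf_fun(xy$x, xy$y), np, np)
  below <- outer(zg, as.vector(zs_full), `>=`)   # nz x (np*np)
  dim(below) <- c(nz, np, np)
  cl_px <- (ct$corr_length_um %||% 5) / dxy
  ds <- if (np >= 128L && cl_px >= 2) 2L else 1L
  npc <- ceiling(np / ds)
  tex <- array(rnorm(nz * npc * npc), c(nz, npc, npc))
  tex <- gauss_smooth(tex, c(max(0.5, cl_px * dxy / params$z_step_um),
                             cl_px / ds, cl_px / ds), cutoff = 2.5)
  tex <- tex / max(sd(as.vector(tex)), 1e-12)
  if (ds > 1L) {
    ii <- pmin(ceiling(seq_len(np) / ds), npc)
    tex <- tex[, ii, ii, drop = FALSE]
  }
  green_level <- pmax(0, (ct$amplitude %||% 50) + (ct$sd %||% 15) * tex)
  cov <- ct$coverage %||% 1
  if (cov < 1) {
    cmask <- matrix(rnorm(np * np), np, np)
    cmask <- gauss_smooth(array(cmask, c(1L, np, np)), c(0, 50 / dxy, 50 / dxy))[1L, , ]
    keep <- cmask <= quantile(cmask, cov)   # smooth contiguous patches
    below <- below * rep(as.numeric(keep), each = nz)
  }
  green <- green_level * below
  rm(green_level, tex, below)

  add_noise <- function(signal, baseline) {
    lam <- signal + baseline
    if (!params$noise) return(lam)
    n <- length(lam)
    obs <- rpois(n, lam) + rnorm(n, 0, params$read_noise_sd)
    a <- round_clamp0(obs)
    dim(a) <- dim(signal)
    a
  }
  red_out <- add_noise(red, params$red_baseline)
  green_out <- add_noise(green, params$green_baseline)

  stack <- image_stack(red = red_out, green = green_out,
                       voxel_size_um = c(params$z_step_um, dxy, dxy))
  truth <- structure(list(cells = cells,
                          surface = truth_surface_map(surf_fun, params),
                          surface_fun = surf_fun,
                          params = params),
                     class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' Specification of one experimental arm
#'
#' Parameterizes the per-arm effect structure of a simulated two-arm
#' explant experiment (e.g. a control vector arm versus an
#' adhesion-restored rescue arm): the probability that a seeded cell
#' implants, the mean invasion depth, and the Day-1 live suspension
#' count used to normalize the implantation score.
#'
#' @param name Arm label (unique within an experiment).
#' @param implant_prob Per-cell implantation probability in `[0, 1]`.
#' @param depth_mean_um Mean of the exponential invasion-depth
#'   distribution, um.
#' @param live_suspension_count Live cells in suspension on Day 1
#'   (implantation-score denominator), > 0.
#' @param n_samples Peritoneal samples (biological replicates) per arm.
#' @param n_fields_per_sample Imaged fields per sample (default 5).
#' @param seeded_per_field Cells whose implantation is attempted per
#'   field (binomial budget).
#' @param growth_per_day Optional per-day multiplicative growth of the
#'   implanted-count expectation (tracker dye persists over several
#'   divisions, so daughters remain countable); 1 disables growth.
#' @return An `arm_spec` list.
#' @export
arm_spec <- function(name, implant_prob, depth_mean_um,
                     live_suspension_count = 1e5,
                     n_samples = 3L, n_fields_per_sample = 5L,
                     seeded_per_field = 60L, growth_per_day = 1) {
  if (implant_prob < 0 || implant_prob > 1)
    stop_bad("implant_prob must be in [0, 1]")
  if (live_suspension_count <= 0)
    stop_bad("live_suspension_count must be > 0")
  if (n_fields_per_sample < 1L) stop_bad("n_fields_per_sample must be >= 1")
  structure(list(name = as.character(name), implant_prob = implant_prob,
                 depth_mean_um = depth_mean_um,
                 live_suspension_count = live_suspension_count,
                 n_samples = as.integer(n_samples),
                 n_fields_per_sample = as.integer(n_fields_per_sample),
                 seeded_per_field = as.integer(seeded_per_field),
                 growth_per_day = growth_per_day),
            class = "arm_spec")
}

#' Generate a multi-arm explant experiment with known ground truth
#'
#' For every arm x sample x day x field, the number of implanted cells is
#' drawn as `Binomial(seeded_per_field, implant_prob * growth^(day-1))`
#' and cell depths from the arm's depth distribution. Stacks are not
#' rendered up front: each field record stores a complete, seeded
#' [generator_params()] (with the planted cells fixed), so its stack can
#' be rendered on demand — identically — by [generate_stack()], or
#' written to disk.
#'
#' @param arms List of [arm_spec()] objects (>= 1, unique names).
#' @param seed Master seed; per-field seeds are derived deterministically.
#' @param days Integer vector of assay days.
#' @param params_template [generator_params()] supplying the imaging
#'   geometry shared by all fields.
#' @param stacks `"none"` (ground truth + lazy params only) or `"disk"`
#'   (render every stack to `dir` as TIFF + sidecar).
#' @param dir Output directory (required for `stacks = "disk"`).
#' @return An `explant_experiment` list: `fields` (list of per-field
#'   records with `arm`, `sample_id`, `day`, `field`, `params`, `cells`),
#'   `manifest` (data frame, one row per stack), `suspension` (data frame
#'   of Day-1 live counts per arm/sample), `arms`, `seed`.
#' @export
generate_experiment <- function(arms, seed = 1L, days = 1L,
                                params_template = generator_params(),
                                stacks = c("none", "disk"), dir = NULL) {
  stacks <- match.arg(stacks)
  if (length(arms) < 1L) stop_bad("at least one arm is required")
  if (inherits(arms, "arm_spec")) arms <- list(arms)
  nm <- vapply(arms, function(a) a$name, "")
  if (anyDuplicated(nm)) stop_bad("duplicate arm names: ",
                                  paste(nm[duplicated(nm)], collapse = ", "))
  if (stacks == "disk") {
    if (is.null(dir)) stop_bad("`dir` is required for stacks = \"disk\"")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  }
  fields <- list()
  man <- list()
  counter <- 0L
  for (a in arms) {
    for (s in seq_len(a$n_samples)) {
      for (d in days) {
        for (f in seq_len(a$n_fields_per_sample)) {
          counter <- counter + 1L
          fseed <- derive_seed(seed, counter)
          set.seed(fseed)
          p_eff <- min(1, a$implant_prob * a$growth_per_day^(d - 1))
          n_impl <- rbinom(1L, a$seeded_per_field, p_eff)
          fp <- params_template
          fp$n_cells <- n_impl
          fp$depth_distribution <- list(type = "exponential",
                                        mean_um = a$depth_mean_um)
          fp$seed <- derive_seed(fseed, 1L)
          surf_fun <- surface_truth_fun(fp$surface, fp$field_size_um, fp$seed)
          set.seed(fp$seed)           # same stream generate_stack will use
          cells <- plant_cells(fp, surf_fun)
          fp$cells <- cells           # freeze: render draws noise only
          sample_id <- paste0(a$name, "_s", s)
          rec <- list(arm = a$name, sample_id = sample_id, day = d, field = f,
                      params = fp, cells = cells,
                      live_suspension_count = a$live_suspension_count)
          path <- NA_character_
          if (stacks == "disk") {
            path <- file.path(dir, sprintf("%s_d%d_f%d.tif", sample_id, d, f))
            gs <- generate_stack(fp)
            write_stack(gs$stack, path,
                        meta = list(arm = a$name, sample_id = sample_id,
                                    day = d, field = f, seed = fp$seed))
          }
          rec$path <- path
          fields[[counter]] <- rec
          man[[counter]] <- data.frame(
            arm = a$name, sample_id = sample_id, day = d, field = f,
            n_planted = nrow(cells), seed = fp$seed, path = path,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, man)
  susp <- unique(do.call(rbind, lapply(arms, function(a)
    data.frame(arm = a$name,
               sample_id = paste0(a$name, "_s", seq_len(a$n_samples)),
               live_suspension_count = a$live_suspension_count,
               stringsAsFactors = FALSE))))
  expt <- structure(list(fields = fields, manifest = manifest,
                         suspension = susp, arms = arms, seed = seed,
                         days = days, dir = dir),
                    class = "explant_experiment")
  if (stacks == "disk") {
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    write.csv(susp, file.path(dir, "suspension.csv"), row.names = FALSE)
    gt <- do.call(rbind, lapply(fields, function(r) {
      if (!nrow(r$cells)) return(NULL)
      cbind(data.frame(arm = r$arm, sample_id = r$sample_id, day = r$day,
                       field = r$field, stringsAsFactors = FALSE), r$cells)
    }))
    if (!is.null(gt))
      write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  }
  expt
}

#' Generate a scratch-wound area time series
#'
#' Expected wound area closes linearly at `closure_rate` (fraction of the
#' initial area per hour), floored at zero, with optional additive
#' Gaussian measurement noise.
#'
#' @param initial_area Wound area at `t = 0` (any consistent unit), > 0.
#' @param closure_rate Fraction of initial area closed per hour.
#' @param times_h Measurement times in hours; must include 0.
#' @param noise_sd Gaussian noise sd on each area (same unit as area).
#' @param seed RNG seed.
#' @return Data frame with columns `time_h`, `area`.
#' @export
generate_wound_series <- function(initial_area, closure_rate,
                                  times_h = c(0, 8, 16, 24),
                                  noise_sd = 0, seed = 1L) {
  if (initial_area <= 0) stop_bad("initial_area must be > 0")
  if (!0 %in% times_h) stop_bad("times must include the t = 0 baseline")
  set.seed(seed)
  area <- initial_area * pmax(0, 1 - closure_rate * times_h)
  if (noise_sd > 0) area <- pmax(0, area + rnorm(length(area), 0, noise_sd))
  data.frame(time_h = times_h, area = area)
}
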