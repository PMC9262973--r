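# Shared fixtures and independent oracles, all built in code.

# Small imaging geometry for fast module tests: same voxel sizes as the
# default field (1.139 um lateral, 2 um axial) on a reduced grid.
small_params <- function(...) {
  args <- utils::modifyList(
    list(field_size_um = 146, pixels_per_axis = 128L, z_depth_um = 30,
         surface = list(type = "plane", z0_um = 8, tilt_x = 0, tilt_y = 0),
         n_cells = 5L, min_cell_separation_um = 28),
    list(...))
  do.call(generator_params, args)
}

# Brute-force strict local maxima of a matrix above a threshold
# (8-neighbourhood), independent of the package's C++ scan.
brute_local_max_2d <- function(m, thr) {
  out <- 0L
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- m[i, j]
    if (v < thr) next
    nb <- m[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
    if (sum(nb >= v) == 1L) out <- out + 1L
  }
  out
}

# Exhaustive (direct-sum) LoG response oracle for a small 2D image:
# Gaussian smoothing + 5-point Laplacian computed with plain R loops.
brute_log_argmax <- function(img, sigma_px) {
  h <- ceiling(3 * sigma_px)
  g <- exp(-((-h:h)^2) / (2 * sigma_px^2)); g <- g / sum(g)
  pad_idx <- function(i, n) pmin(pmax(i, 1L), n)
  nr <- nrow(img); nc <- ncol(img)
  sm <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (u in -h:h) for (v in -h:h) {
      acc <- acc + img[pad_idx(i + u, nr), pad_idx(j + v, nc)] *
        g[u + h + 1] * g[v + h + 1]
    }
    sm[i, j] <- acc
  }
  resp <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    dyy <- sm[pad_idx(i - 1, nr), j] - 2 * sm[i, j] + sm[pad_idx(i + 1, nr), j]
    dxx <- sm[i, pad_idx(j - 1, nc)] - 2 * sm[i, j] + sm[i, pad_idx(j + 1, nc)]
    resp[i, j] <- -sigma_px^2 * (dyy + dxx)
  }
  which(resp == max(resp), arr.ind = TRUE)[1, ]
}

# Greedy one-to-one matching of detected spots to planted truth in the
# lateral plane; returns the count of matches within `tol_um`.
match_spots <- function(spots, truth, tol_um = 7) {
  used <- rep(FALSE, nrow(truth))
  hits <- 0L
  for (i in seq_len(nrow(spots))) {
    d <- sqrt((truth$x_um - spots$x_um[i])^2 + (truth$y_um - spots$y_um[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol_um) { used[j] <- TRUE; hits <- hits + 1L }
  }
  hits
}

# Rasterize an ellipse mask (semi-axes a, b px, rotation theta).
ellipse_mask <- function(n, a, b, theta = 0) {
  cx <- (n + 1) / 2
  idx <- expand.grid(r = seq_len(n), c = seq_len(n))
  x <- idx$c - cx; y <- idx$r - cx
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  matrix((xr / a)^2 + (yr / b)^2 <= 1, n, n)
}
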