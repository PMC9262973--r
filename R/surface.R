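# Mesothelial-surface estimation from the green reflectance channel.
#
# The surface is defined operationally as the reflectance onset: per
# lateral column, the first z (from the objective side) at which the
# axially smoothed green intensity crosses a fixed fraction of that
# column's robust maximum. The criterion is purely relative, so the
# estimate is invariant to uniform intensity rescaling. Columns without
# a confident onset (patchy, degraded mesothelium) are filled from their
# neighbors; if almost nothing is confident, a single global plane is
# fitted instead.

new_surface_map <- function(z, x_um, y_um, coverage, settings) {
  structure(list(z = z, x_um = x_um, y_um = y_um,
                 coverage = coverage, settings = settings),
            class = "surface_map")
}

#' @export
print.surface_map <- function(x, ...) {
  cat(sprintf("<surface_map> %d x %d grid; z in [%.2f, %.2f] um; coverage %.2f\n",
              nrow(x$z), ncol(x$z), min(x$z), max(x$z), x$coverage))
  invisible(x)
}

#' Estimate the mesothelial surface height map from reflectance
#'
#' @param stack An [image_stack] whose green channel carries collagen
#'   reflectance. If the green channel is absent, a `constant_plane_um`
#'   override must be supplied.
#' @param settings Surface settings (see [default_run_config()]
#'   `$surface`); `NULL` for defaults.
#' @param constant_plane_um Fallback constant surface height when no
#'   green channel exists.
#' @return A `surface_map`: lateral grid of surface heights `z` (um,
#'   `[y, x]`), grid coordinates `x_um`/`y_um`, `coverage` (fraction of
#'   columns with a confident onset before interpolation), and the
#'   settings used.
#' @export
estimate_surface <- function(stack, settings = NULL, constant_plane_um = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  s <- utils::modifyList(default_run_config()$surface, settings %||% list())
  dz <- stack$voxel_size_um[1L]
  dy <- stack$voxel_size_um[2L]
  if (is.null(stack$green)) {
    if (is.null(constant_plane_um))
      stop_bad("no green channel and no constant_plane_um override")
    d <- dim(stack$red)
    return(new_surface_map(
      z = matrix(constant_plane_um, 2L, 2L),
      x_um = c(0, d[3L] * stack$voxel_size_um[3L]),
      y_um = c(0, d[2L] * dy),
      coverage = 0, settings = s))
  }
  f <- max(1L, as.integer(round(s$block_um / dy)))
  bl <- block_mean_lateral(stack$green, f)
  gm <- conv_axis(bl$a, rep(1 / 3, 3L), 1L)   # 3-plane axial smoothing
  d <- dim(gm)
  nzp <- d[1L]; gy <- d[2L]; gx <- d[3L]
  m <- matrix(gm, nzp, gy * gx)
  q95 <- apply(m, 2L, quantile, probs = 0.95, names = FALSE)
  ref <- quantile(q95, 0.95, names = FALSE)
  if (ref <= 0) stop_bad("green channel carries no reflectance signal")
  confident <- q95 >= 0.3 * ref
  thr <- s$onset_fraction * q95
  crossed <- m >= rep(thr, each = nzp)
  idx <- max.col(t(crossed), ties.method = "first")
  has <- colSums(crossed) > 0L
  confident <- confident & has
  # sub-plane refinement: linear interpolation of the crossing position
  zs <- (idx - 1) * dz
  interior <- confident & idx > 1L
  if (any(interior)) {
    ii <- which(interior)
    v2 <- m[cbind(idx[ii], ii)]
    v1 <- m[cbind(idx[ii] - 1L, ii)]
    frac <- (thr[ii] - v1) / pmax(v2 - v1, 1e-12)
    frac <- pmin(1, pmax(0, frac))
    zs[ii] <- (idx[ii] - 2 + frac) * dz
  }
  zmat <- matrix(zs, gy, gx)
  conf <- matrix(confident, gy, gx)
  coverage <- mean(conf)
  xc <- bl$centers_x * stack$voxel_size_um[3L] - stack$voxel_size_um[3L] / 2
  yc <- bl$centers_y * dy - dy / 2
  zmax <- (dim(stack$green)[1L] - 1) * dz

  # global plane fit over confident columns (also the low-coverage fallback)
  fit_plane <- function() {
    if (sum(conf) >= 3L) {
      df <- data.frame(z = zmat[conf],
                       x = rep(xc, each = gy)[conf],
                       y = rep(yc, times = gx)[conf])
      co <- stats::coef(stats::lm(z ~ x + y, data = df))
      outer(yc, xc, function(y, x) co[1L] + co[2L] * x + co[3L] * y)
    } else {
      matrix(stats::median(zmat), gy, gx)
    }
  }
  if (coverage < s$min_coverage_for_map) {
    zfill <- fit_plane()
  } else {
    # seed unconfident columns with the plane fit, then blend by
    # confidence-weighted Gaussian smoothing at smoothing_scale_um
    plane <- fit_plane()
    z0 <- ifelse(conf, zmat, plane)
    w <- ifelse(conf, 1, 0.1)
    block_um <- f * dy
    sg <- s$smoothing_scale_um / block_um
    num <- gauss_smooth(array(z0 * w, c(1L, gy, gx)), c(0, sg, sg))[1L, , ]
    den <- gauss_smooth(array(w, c(1L, gy, gx)), c(0, sg, sg))[1L, , ]
    zfill <- num / pmax(den, 1e-9)
  }
  zfill <- pmin(pmax(zfill, 0), zmax)
  grad <- max(abs(diff(zfill)) , abs(t(diff(t(zfill))))) / (f * dy)
  if (is.finite(grad) && grad > s$max_slope)
    warning("surface gradient ", signif(grad, 3), " exceeds max_slope ",
            s$max_slope, call. = FALSE)
  new_surface_map(z = zfill, x_um = xc, y_um = yc,
                  coverage = coverage, settings = s)
}

#' Surface height at arbitrary lateral positions
#'
#' Bilinear interpolation of the height map; queries between the field
#' edge and the outermost grid node use the nearest-node value along the
#' clamped axis.
#'
#' @param map A `surface_map`.
#' @param x_um,y_um Numeric vectors of query positions (recycled).
#' @param field_extent_um Optional `(size_y, size_x)` bound; queries
#'   outside `[0, extent]` are errors. Defaults to the grid extent.
#' @return Numeric vector of surface heights in um.
#' @export
surface_at <- function(map, x_um, y_um, field_extent_um = NULL) {
  stopifnot(inherits(map, "surface_map"))
  n <- max(length(x_um), length(y_um))
  x <- rep_len(x_um, n); y <- rep_len(y_um, n)
  hx <- if (length(map$x_um) > 1L) diff(map$x_um[1:2]) else 1
  hy <- if (length(map$y_um) > 1L) diff(map$y_um[1:2]) else 1
  xmax <- (field_extent_um %||% c(max(map$y_um) + hy / 2, max(map$x_um) + hx / 2))
  if (any(x < -1e-9 | x > xmax[2L] + 1e-9 | y < -1e-9 | y > xmax[1L] + 1e-9))
    stop_bad("query position outside the field")
  gx <- map$x_um; gy <- map$y_um
  xi <- pmin(pmax(x, gx[1L]), gx[length(gx)])
  yi <- pmin(pmax(y, gy[1L]), gy[length(gy)])
  ix <- pmin(pmax(findInterval(xi, gx), 1L), length(gx) - 1L)
  iy <- pmin(pmax(findInterval(yi, gy), 1L), length(gy) - 1L)
  if (length(gx) == 1L) ix <- integer(n) + 1L
  if (length(gy) == 1L) iy <- integer(n) + 1L
  tx <- if (length(gx) > 1L) (xi - gx[ix]) / (gx[ix + 1L] - gx[ix]) else 0
  ty <- if (length(gy) > 1L) (yi - gy[iy]) / (gy[iy + 1L] - gy[iy]) else 0
  ix2 <- pmin(ix + 1L, length(gx)); iy2 <- pmin(iy + 1L, length(gy))
  z11 <- map$z[cbind(iy, ix)];  z12 <- map$z[cbind(iy, ix2)]
  z21 <- map$z[cbind(iy2, ix)]; z22 <- map$z[cbind(iy2, ix2)]
  (1 - ty) * ((1 - tx) * z11 + tx * z12) + ty * ((1 - tx) * z21 + tx * z22)
}
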