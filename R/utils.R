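# Shared numeric helpers. All geometry is in micrometres (um) past I/O;
# arrays are indexed [z, y, x] with z = 0 at the objective-proximal face.

#' Standard error of the mean
#'
#' @param x Numeric vector; `NA`s are dropped.
#' @return `sd(x)/sqrt(n)`, or `NA` if fewer than two values remain.
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# Normalized Gaussian kernel sampled at integer offsets, half-width
# max(1, ceiling(cutoff*sigma)) taps each side.
gauss_kernel <- function(sigma, cutoff = 3) {
  if (sigma <= 0) return(1)
  h <- max(1L, as.integer(ceiling(cutoff * sigma)))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

# Apply a 1-d kernel along one axis of a 3-d [z,y,x] array (or a matrix,
# axes 1..2). Replicate padding; separable filters chain these calls.
conv_axis <- function(a, kernel, axis) {
  if (length(kernel) == 1L) return(a * kernel)
  d <- dim(a)
  nd <- length(d)
  stopifnot(axis >= 1L, axis <= nd)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  ap <- if (axis == 1L) a else aperm(a, perm)
  dp <- dim(ap)
  m <- conv_cols(matrix(ap, nrow = dp[1L]), as.numeric(kernel))
  dim(m) <- dp
  if (axis == 1L) m else aperm(m, order(perm))
}

# Gaussian smoothing with per-axis sigmas (in array-index units).
gauss_smooth <- function(a, sigmas, cutoff = 3) {
  for (ax in seq_along(sigmas)) {
    if (sigmas[ax] > 0) a <- conv_axis(a, gauss_kernel(sigmas[ax], cutoff), ax)
  }
  a
}

# Block-mean downsampling of the lateral (y, x) axes of a [z,y,x] array
# by integer factor f; trailing rows/cols that do not fill a block are
# dropped. Returns list(a = downsampled array, centers_y, centers_x) with
# block centers in pixel index units (1-based, fractional).
block_mean_lateral <- function(a, f) {
  d <- dim(a)
  if (f <= 1L) {
    return(list(a = a, centers_y = seq_len(d[2L]), centers_x = seq_len(d[3L])))
  }
  gy <- d[2L] %/% f
  gx <- d[3L] %/% f
  a <- a[, seq_len(gy * f), seq_len(gx * f), drop = FALSE]
  dim(a) <- c(d[1L], f, gy, f, gx)
  a <- colMeans(aperm(a, c(2L, 4L, 1L, 3L, 5L)), dims = 2L)
  list(a = a,
       centers_y = (seq_len(gy) - 0.5) * f + 0.5,
       centers_x = (seq_len(gx) - 0.5) * f + 0.5)
}

# Deterministic fan-out of one master seed into per-stage/per-item seeds.
# Documented scheme: seed_i = (seed * 1000003 + i) mod (2^31 - 1), kept
# strictly positive so it is always a valid `set.seed()` argument.
derive_seed <- function(seed, i) {
  s <- (as.numeric(seed) %% 2147483647) * 1000003 + as.numeric(i)
  as.integer(s %% 2147483647) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad <- function(...) stop(..., call. = FALSE)
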