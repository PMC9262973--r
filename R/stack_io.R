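#' Two-channel confocal image stack
#'
#' Container for one imaged field: a red channel carrying tracker-stained
#' cancer cells and (optionally) a green channel carrying the collagen
#' reflectance of the tissue. Voxels are indexed `[z, y, x]` with `z = 0`
#' at the objective-proximal face (the explant is imaged from beneath the
#' mesothelial surface, so the surface is the smallest-z tissue boundary).
#' All geometry is in micrometres.
#'
#' @param red 3-d numeric array `[z, y, x]` of red-channel intensities.
#' @param green Optional 3-d numeric array, same shape as `red`.
#' @param voxel_size_um Numeric length-3 `(dz, dy, dx)` voxel size in um.
#' @return An object of class `image_stack`: a list with elements
#'   `red`, `green` (possibly `NULL`), `voxel_size_um`, and `channels`
#'   (the ordered channel roles present).
#' @export
image_stack <- function(red, green = NULL, voxel_size_um) {
  if (!is.array(red) || length(dim(red)) != 3L)
    stop_bad("`red` must be a 3-d array [z, y, x]")
  if (any(dim(red) < 1L)) stop_bad("stack must have at least one plane")
  if (!is.null(green) && !identical(dim(green), dim(red)))
    stop_bad("all channels must share the same shape")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    stop_bad("`voxel_size_um` must be 3 positive numbers (dz, dy, dx)")
  structure(list(
    red = red, green = green,
    voxel_size_um = voxel_size_um,
    channels = c("red_cells", if (!is.null(green)) "green_reflectance")
  ), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$red)
  cat(sprintf("<image_stack> %d z-planes x %d x %d px; voxel %.3g x %.3g x %.3g um (dz,dy,dx); channels: %s\n",
              d[1L], d[2L], d[3L],
              x$voxel_size_um[1L], x$voxel_size_um[2L], x$voxel_size_um[3L],
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Lateral field extent of a stack, in um
#' @param stack An [image_stack].
#' @return Length-2 numeric `(size_y, size_x)` in um.
#' @export
field_extent_um <- function(stack) {
  d <- dim(stack$red)
  c(d[2L] * stack$voxel_size_um[2L], d[3L] * stack$voxel_size_um[3L])
}

# One multi-page TIFF holds all planes of all channels (red planes first,
# then green); a JSON sidecar carries shape, channel order, voxel sizes
# and the power-of-two intensity scale used to map counts into [0, 1].
sidecar_path <- function(path) paste0(path, ".json")

#' Write an image stack to a multi-page TIFF with JSON sidecar
#'
#' Intensities are divided by a power-of-two scale (recorded in the
#' sidecar) to fit the TIFF `[0, 1]` sample range. With `bits = 16` the
#' round-trip is bit-exact for integer-valued grids up to 65535 x scale —
#' the pipeline's canonical representation, since detector output is
#' integer counts. `bits = 32` stores general (non-negative) float grids
#' on a 2^32 - 1 quantization grid, exact for single-precision data whose
#' dynamic range is within 2^9 of the scale.
#'
#' @param stack An [image_stack] with non-negative intensities.
#' @param path Output TIFF path; the sidecar is written to `<path>.json`.
#' @param bits Bits per sample: 16 (default, integer grids) or 32.
#' @param meta Optional named list merged into the sidecar (e.g. seed,
#'   generator parameters).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L, meta = list()) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$red)
  if (d[1L] < 1L) stop_bad("cannot write an empty stack (0 planes)")
  if (!bits %in% c(16L, 32L)) stop_bad("`bits` must be 16 or 32")
  chans <- list(red = stack$red)
  if (!is.null(stack$green)) chans$green <- stack$green
  mx <- max(vapply(chans, max, 0), 0)
  mn <- min(vapply(chans, min, 0))
  if (mn < 0) stop_bad("stack intensities must be non-negative for storage")
  scale <- 2^max(0, ceiling(log2(max(mx, 1) * (1 + 1e-9))))
  pages <- list()
  for (ch in chans) {
    for (z in seq_len(d[1L])) pages[[length(pages) + 1L]] <- ch[z, , ] / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "deflate")
  side <- c(list(
    shape_zyx = d,
    channels = stack$channels,
    voxel_size_um = stack$voxel_size_um,
    intensity_scale = scale,
    bits = bits,
    integer_mode = (bits == 16L)
  ), meta)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' Voxel sizes are mandatory: depths are reported in um, never pixels, so
#' a file without voxel metadata (sidecar or `voxel_size_um` override) is
#' a hard error.
#'
#' @param path TIFF path with a `<path>.json` sidecar.
#' @param voxel_size_um Optional `(dz, dy, dx)` override when the sidecar
#'   is absent or incomplete.
#' @param channel_roles Optional character vector overriding the channel
#'   roles (e.g. `c("red_cells")` for a single-channel file).
#' @return An [image_stack]. The sidecar metadata is attached as
#'   attribute `"meta"`.
#' @export
read_stack <- function(path, voxel_size_um = NULL, channel_roles = NULL) {
  if (!file.exists(path)) stop_bad("no such file: ", path)
  side <- if (file.exists(sidecar_path(path))) {
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  } else list()
  vs <- voxel_size_um %||% side$voxel_size_um
  if (is.null(vs))
    stop_bad("voxel size metadata missing (no sidecar and no `voxel_size_um` ",
             "override); depths are measured in um, not pixels")
  roles <- channel_roles %||% side$channels
  if (is.null(roles))
    stop_bad("channel roles unknown: no sidecar and no `channel_roles` override")
  pages <- tiff::readTIFF(path, all = TRUE)
  n_chan <- length(roles)
  if (length(pages) %% n_chan != 0L)
    stop_bad("page count ", length(pages), " not divisible by ", n_chan, " channels")
  nz <- length(pages) %/% n_chan
  scale <- side$intensity_scale %||% 1
  integer_mode <- isTRUE(side$integer_mode)
  grab <- function(k) {
    a <- array(0, c(nz, nrow(pages[[1L]]), ncol(pages[[1L]])))
    for (z in seq_len(nz)) {
      v <- pages[[(k - 1L) * nz + z]] * scale
      a[z, , ] <- if (integer_mode) round(v) else round_f32(v)
    }
    a
  }
  red_i <- match("red_cells", roles)
  if (is.na(red_i)) stop_bad("no red_cells channel among roles: ",
                             paste(roles, collapse = ", "))
  green_i <- match("green_reflectance", roles)
  st <- image_stack(red = grab(red_i),
                    green = if (!is.na(green_i)) grab(green_i),
                    voxel_size_um = as.numeric(vs))
  if (is.na(green_i)) st$green_absent <- TRUE
  attr(st, "meta") <- side
  st
}
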