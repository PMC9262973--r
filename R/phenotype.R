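# 2D phenotype assay quantification: scratch-wound healing, cell shape
# (axial ratio), viability and proliferation counts.

#' Percent wound healed over time
#'
#' The residual wound area is expressed as a percent of the original
#' (t = 0) area and subtracted from 100:
#' `%healed(t) = 100 - 100 * area(t) / area(0)`, so `%healed(0) = 0`
#' exactly and full closure gives 100. Invariant to uniform rescaling of
#' all areas.
#'
#' @param series Data frame with columns `time_h` (strictly increasing,
#'   including 0) and `area` (>= 0), e.g. from
#'   [generate_wound_series()].
#' @return Data frame with columns `time_h`, `pct_healed`.
#' @export
percent_healed <- function(series) {
  stopifnot(is.data.frame(series), all(c("time_h", "area") %in% names(series)))
  if (is.unsorted(series$time_h, strictly = TRUE))
    stop_bad("times must be strictly increasing")
  if (!0 %in% series$time_h) stop_bad("t = 0 baseline required")
  if (any(series$area < 0)) stop_bad("areas must be >= 0")
  a0 <- series$area[series$time_h == 0]
  if (a0 <= 0) stop_bad("area at t = 0 must be > 0")
  data.frame(time_h = series$time_h,
             pct_healed = 100 - 100 * series$area / a0)
}

#' Cell axial ratio from a binary mask
#'
#' Width/length as the minor/major axis ratio of the mask's second-moment
#' (best-fit) ellipse: 1 is a perfect circle, values near 0 are highly
#' elongated. Rotation-invariant by construction, unlike a bounding-box
#' measure. The 1/12 px^2 discretization variance of square pixels is
#' added to the diagonal so single-pixel and thin masks stay finite.
#'
#' @param mask Logical (or 0/1) matrix; must be non-empty and a single
#'   connected component (segmentation is upstream).
#' @return A list of class `cell_shape`: `width`, `length` (full axis
#'   extents, px), and `axial_ratio = width / length` in (0, 1].
#' @export
axial_ratio <- function(mask) {
  if (!is.matrix(mask)) stop_bad("`mask` must be a matrix")
  m <- mask != 0
  if (!any(m)) stop_bad("empty mask")
  lab <- EBImage::bwlabel(m * 1)
  if (max(lab) > 1L)
    stop_bad("mask has ", max(lab), " connected components; expected 1")
  pts <- which(m, arr.ind = TRUE)
  cv <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts) + diag(1 / 12, 2L)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values)
  structure(list(width = 4 * sqrt(ev[1L]), length = 4 * sqrt(ev[2L]),
                 axial_ratio = sqrt(ev[1L] / ev[2L])),
            class = "cell_shape")
}

#' @export
print.cell_shape <- function(x, ...) {
  cat(sprintf("<cell_shape> width %.2f px, length %.2f px, axial ratio %.3f\n",
              x$width, x$length, x$axial_ratio))
  invisible(x)
}

#' Viability fraction
#'
#' Number of alive cells divided by the total number of cells (dead and
#' alive) in a well.
#'
#' @param alive,dead Non-negative counts; their sum must be > 0.
#' @return Fraction in `[0, 1]`.
#' @export
viability_fraction <- function(alive, dead) {
  if (alive < 0 || dead < 0) stop_bad("counts must be >= 0")
  if (alive + dead == 0) stop_bad("no cells counted")
  alive / (alive + dead)
}

#' Cells per well (proliferation readout)
#'
#' @param cell_table Data frame with a `well` column, one row per cell.
#' @param well Well label to count.
#' @param wells Known well labels; defaults to the factor levels of
#'   `cell_table$well` (or its unique values). A `well` outside this set
#'   is an error; a known well with no rows counts 0.
#' @return Integer cell count.
#' @export
proliferation_count <- function(cell_table, well, wells = NULL) {
  stopifnot(is.data.frame(cell_table), "well" %in% names(cell_table))
  known <- wells %||%
    (if (is.factor(cell_table$well)) levels(cell_table$well)
     else unique(as.character(cell_table$well)))
  if (!well %in% known) stop_bad("unknown well: ", well)
  sum(as.character(cell_table$well) == well)
}

#' Rough wound-area segmentation (auxiliary)
#'
#' Simple threshold heuristic for brightfield-like scratch images: pixels
#' below the threshold (cell-free) are candidate wound; the largest
#' connected low-intensity component is taken as the wound. This is an
#' auxiliary convenience for synthetic images — quantitative analyses
#' should supply measured wound areas as a table to [percent_healed()].
#'
#' @param image Numeric matrix (higher = cell-covered).
#' @param threshold Intensity cutoff; default is the midpoint between
#'   the 10th and 90th intensity percentiles.
#' @param pixel_size_um Optional pixel size for an area in um^2.
#' @return Wound area (pixels, or um^2 if `pixel_size_um` is given).
#' @export
wound_area_estimate <- function(image, threshold = NULL, pixel_size_um = NULL) {
  stopifnot(is.matrix(image))
  if (is.null(threshold)) {
    q <- quantile(image, c(0.1, 0.9), names = FALSE)
    threshold <- mean(q)
  }
  lab <- EBImage::bwlabel((image < threshold) * 1)
  if (max(lab) == 0L) return(0)
  area_px <- max(tabulate(lab[lab > 0]))
  if (is.null(pixel_size_um)) area_px else area_px * prod(rep(pixel_size_um, 2L)[1:2])
}
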