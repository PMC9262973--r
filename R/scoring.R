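# Implantation and invasion scoring.
#
# Implantation score: mean detected cells per 583 x 583 um field,
# multiplied by the number of such squares per explant (662 for a
# 1.5 x 1.5 cm sample), divided by the number of live cells in suspension
# on Day 1 — a dimensionless implantation efficiency.
#
# Invasion score: per field, the mean depth below the mesothelial surface
# of the k = 3 deepest cells; per sample, the mean over the 5 fields;
# replicate measurements ("observers") are averaged into the final score.

#' Depth of a detected cell below the mesothelial surface
#'
#' Depth is the axial (z) distance from the surface to the cell
#' mid-point: `z_um - surface_at(x, y)`. Negative values (cell above the
#' estimated surface) are clamped to 0: such a cell is surface-adherent,
#' and excluding it would bias counts.
#'
#' @param spots Spot data frame with `x_um`, `y_um`, `z_um` (3D
#'   detection; an `NA` z is an error).
#' @param surface_map A `surface_map` (estimated or ground truth).
#' @return Numeric vector of depths in um, >= 0.
#' @export
cell_depth <- function(spots, surface_map) {
  if (nrow(spots) == 0L) return(numeric(0))
  if (is.null(spots$z_um) || anyNA(spots$z_um))
    stop_bad("spots lack z positions: depth needs 3D detection")
  pmax(0, spots$z_um - surface_at(surface_map, spots$x_um, spots$y_um))
}

#' Field invasion statistic: mean depth of the k deepest cells
#'
#' @param depths_um Non-negative cell depths in one field (clamping
#'   happens upstream in [cell_depth()]; negatives here are an error).
#' @param k Number of deepest cells to average (default 3).
#' @return Mean of the `k` largest depths. With `0 < n < k` cells, the
#'   mean of all `n`, flagged via attribute `short_field = TRUE`. With no
#'   cells, `NA` (excluded downstream).
#' @export
field_invasion <- function(depths_um, k = 3L) {
  if (k < 1L) stop_bad("k must be >= 1")
  if (length(depths_um) == 0L) return(NA_real_)
  if (any(depths_um < 0)) stop_bad("negative depths: clamp upstream")
  if (length(depths_um) < k) {
    out <- mean(depths_um)
    attr(out, "short_field") <- TRUE
    return(out)
  }
  mean(sort(depths_um, decreasing = TRUE)[seq_len(k)])
}

#' Sample invasion score: mean over fields
#'
#' @param field_scores_um Per-field invasion values (typically 5);
#'   missing fields (`NA`) are dropped.
#' @return Mean over non-missing fields, with attribute `n_fields` (the
#'   number used) and `incomplete = TRUE` if any field was missing; `NA`
#'   if all fields are missing.
#' @export
sample_invasion <- function(field_scores_um) {
  ok <- !is.na(field_scores_um)
  if (!any(ok)) return(NA_real_)
  out <- mean(field_scores_um[ok])
  attr(out, "n_fields") <- sum(ok)
  if (any(!ok)) attr(out, "incomplete") <- TRUE
  out
}

#' Combine replicate measurements into a final score
#'
#' Generalizes the two-independent-observer averaging to any number of
#' measurement replicates >= 1 (the automated pipeline is one
#' "observer").
#'
#' @param scores Numeric vector of replicate scores (>= 1).
#' @return Their mean, with attribute `disagreement = max - min`.
#' @export
combine_observers <- function(scores) {
  scores <- as.numeric(scores)
  if (length(scores) == 0L) stop_bad("no scores to combine")
  out <- mean(scores)
  attr(out, "disagreement") <- max(scores) - min(scores)
  out
}

#' Normalized implantation score
#'
#' `mean_count_per_field * n_squares / live_suspension_count`: the mean
#' per-field cell count scaled to the whole explant and normalized by the
#' live cells available in suspension on Day 1.
#'
#' @param mean_count_per_field Mean detected cells per field, >= 0.
#' @param n_squares Squares per explant (default 662; see
#'   [squares_per_explant()]).
#' @param live_suspension_count Live suspended cells on Day 1, > 0.
#' @return Dimensionless implantation score.
#' @export
implantation_score <- function(mean_count_per_field, n_squares = 662,
                               live_suspension_count) {
  if (live_suspension_count <= 0)
    stop_bad("live_suspension_count must be > 0")
  if (mean_count_per_field < 0) stop_bad("mean count must be >= 0")
  mean_count_per_field * n_squares / live_suspension_count
}

#' Number of imaging squares per explant
#'
#' `round((explant_side / field_side)^2)`; the default explant (1.5 cm)
#' and field (583 um) give 662, making that constant reproducible rather
#' than magic.
#'
#' @param explant_side_um Explant side length, um (default 15000).
#' @param field_side_um Field side length, um (default 583).
#' @return Integer number of squares (>= 1; a field larger than the
#'   explant returns 1 with a warning).
#' @export
squares_per_explant <- function(explant_side_um = 15000, field_side_um = 583) {
  if (explant_side_um <= 0 || field_side_um <= 0)
    stop_bad("both side lengths must be > 0")
  if (field_side_um > explant_side_um) {
    warning("field larger than explant; using 1 square", call. = FALSE)
    return(1L)
  }
  as.integer(round((explant_side_um / field_side_um)^2))
}

#' Sample non-overlapping field positions within an explant
#'
#' `mode = "random"` rejection-samples `n` axis-aligned, pairwise
#' non-overlapping squares uniformly; `mode = "grid"` returns the full
#' disjoint floor-tiling (`floor(explant/field)^2` squares; `n` is then
#' ignored).
#'
#' @param field_size_um Field (square) side, um.
#' @param explant_side_um Explant side, um.
#' @param n Number of fields (default 5).
#' @param seed RNG seed (random mode).
#' @param mode `"random"` or `"grid"`.
#' @return Data frame of field origins `(x0_um, y0_um)` (lower corner).
#' @export
sample_fields <- function(field_size_um = 583, explant_side_um = 15000,
                          n = 5L, seed = 1L, mode = c("random", "grid")) {
  mode <- match.arg(mode)
  if (field_size_um <= 0 || explant_side_um <= 0)
    stop_bad("sizes must be > 0")
  if (field_size_um > explant_side_um)
    stop_bad("field does not fit inside the explant")
  if (mode == "grid") {
    g <- floor(explant_side_um / field_size_um)
    or <- expand.grid(x0_um = (seq_len(g) - 1) * field_size_um,
                      y0_um = (seq_len(g) - 1) * field_size_um)
    return(or[, c("x0_um", "y0_um")])
  }
  set.seed(seed)
  lim <- explant_side_um - field_size_um
  xs <- ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > 10000L * n)
      stop_bad(n, " non-overlapping fields do not fit in this explant")
    x <- runif(1L, 0, lim); y <- runif(1L, 0, lim)
    if (length(xs) == 0L ||
        all(abs(xs - x) >= field_size_um | abs(ys - y) >= field_size_um)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  data.frame(x0_um = xs, y0_um = ys)
}

#' Group comparison of implantation and invasion scores
#'
#' For each day and arm pair, per-arm means and SEMs with a two-sided
#' Welch t-test; Bonferroni adjustment (`p_adj = min(1, m * p)`) over the
#' family of all day-wise pairwise comparisons within each metric, plus a
#' per-metric one-way ANOVA across arms (all days pooled).
#'
#' @param score_records Data frame with columns `sample_id`, `day`,
#'   `arm`, and the metric columns `implantation_score` and/or
#'   `invasion_score_um`.
#' @param alpha Significance level for flags.
#' @param correction Multiple-testing correction (`"bonferroni"` or any
#'   [stats::p.adjust()] method).
#' @return Data frame with one row per (metric, day, arm pair):
#'   group sizes, means, SEMs, `p` (raw), `p_adj`, `significant`; the
#'   per-metric ANOVA p-values are attached as attribute `anova_p`.
#'   Days where either arm has fewer than two replicates are skipped
#'   with a warning (`p = NA`).
#' @export
compare_arms <- function(score_records, alpha = 0.05,
                         correction = "bonferroni") {
  stopifnot(is.data.frame(score_records))
  need <- c("sample_id", "day", "arm")
  if (!all(need %in% names(score_records)))
    stop_bad("score_records needs columns: ", paste(need, collapse = ", "))
  metrics <- intersect(c("implantation_score", "invasion_score_um"),
                       names(score_records))
  if (!length(metrics)) stop_bad("no metric columns found")
  arms <- unique(score_records$arm)
  if (length(arms) < 2L) stop_bad("need >= 2 arms to compare")
  rows <- list()
  anova_p <- setNames(numeric(0), character(0))
  for (met in metrics) {
    vals <- score_records[[met]]
    if (length(unique(score_records$day)) >= 1L && length(arms) >= 2L) {
      ok <- !is.na(vals)
      if (sum(ok) > length(arms)) {
        fit <- aov(vals[ok] ~ factor(score_records$arm[ok]))
        anova_p[met] <- summary(fit)[[1L]][["Pr(>F)"]][1L]
      }
    }
    for (d in sort(unique(score_records$day))) {
      for (i in seq_along(arms)) for (j in seq_along(arms)) {
        if (j <= i) next
        a1 <- vals[score_records$day == d & score_records$arm == arms[i]]
        a2 <- vals[score_records$day == d & score_records$arm == arms[j]]
        a1 <- a1[!is.na(a1)]; a2 <- a2[!is.na(a2)]
        p <- NA_real_
        if (length(a1) < 2L || length(a2) < 2L) {
          warning(sprintf("day %s, %s vs %s: fewer than 2 replicates; test skipped",
                          d, arms[i], arms[j]), call. = FALSE)
        } else if (sd(a1) == 0 && sd(a2) == 0 && mean(a1) == mean(a2)) {
          p <- 1          # identical constant groups: no evidence of difference
        } else {
          p <- tryCatch(t.test(a1, a2)$p.value, error = function(e) NA_real_)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          metric = met, day = d, arm1 = arms[i], arm2 = arms[j],
          n1 = length(a1), n2 = length(a2),
          mean1 = mean(a1), mean2 = mean(a2),
          sem1 = sem(a1), sem2 = sem(a2),
          p = p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (met in metrics) {
    sel <- out$metric == met & !is.na(out$p)
    out$p_adj[sel] <- p.adjust(out$p[sel], method = correction)
  }
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  attr(out, "anova_p") <- anova_p
  out
}

#' Ratio of implantation scores between two arms, with 95% CI
#'
#' Point estimate is the ratio of arm means over all sample-day score
#' records; the confidence interval uses the delta method on the log
#' ratio (`SE^2 = sem_num^2/mean_num^2 + sem_den^2/mean_den^2`).
#'
#' @param score_records As in [compare_arms()].
#' @param arm_num,arm_den Arm names for numerator and denominator.
#' @param level Confidence level (default 0.95).
#' @return List with `ratio`, `lo`, `hi`, `level`.
#' @export
implantation_ratio_ci <- function(score_records, arm_num, arm_den,
                                  level = 0.95) {
  v1 <- score_records$implantation_score[score_records$arm == arm_num]
  v2 <- score_records$implantation_score[score_records$arm == arm_den]
  v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
  if (length(v1) < 2L || length(v2) < 2L)
    stop_bad("need >= 2 score records per arm")
  m1 <- mean(v1); m2 <- mean(v2)
  if (m1 <= 0 || m2 <= 0) stop_bad("arm means must be positive for a ratio")
  se_log <- sqrt(sem(v1)^2 / m1^2 + sem(v2)^2 / m2^2)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(ratio = m1 / m2, lo = m1 / m2 * exp(-z * se_log),
       hi = m1 / m2 * exp(z * se_log), level = level)
}
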