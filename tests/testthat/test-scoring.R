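# Implantation/invasion scoring and group statistics.

flat_map <- function(z0) peritoscore:::new_surface_map(
  z = matrix(z0, 2L, 2L), x_um = c(0, 100), y_um = c(0, 100),
  coverage = 1, settings = list())

test_that("cell depth is the axial distance to the surface, clamped at zero", {
  sm <- flat_map(10)
  sp <- data.frame(x_um = c(20, 40), y_um = c(20, 40), z_um = c(25, 8))
  expect_equal(cell_depth(sp, sm), c(15, 0))
  sp2d <- data.frame(x_um = 20, y_um = 20, z_um = NA_real_)
  expect_error(cell_depth(sp2d, sm), "3D")
})

test_that("planted depth is recovered within one z-step through the full chain", {
  p <- small_params(n_cells = 1L, seed = 51L,
                    depth_distribution = list(type = "fixed", depth_um = 14))
  g <- generate_stack(p)
  sp <- detect_spots_3d(g$stack)
  expect_equal(nrow(sp), 1L)
  d <- cell_depth(sp, estimate_surface(g$stack))
  expect_lt(abs(d - 14), 2)
})

test_that("field invasion averages the k deepest cells with flagged edge cases", {
  expect_equal(field_invasion(c(5, 10, 20, 30, 40), k = 3), 30)
  short <- field_invasion(7, k = 3)
  expect_equal(as.numeric(short), 7)
  expect_true(attr(short, "short_field"))
  expect_true(is.na(field_invasion(numeric(0), k = 3)))
  expect_error(field_invasion(c(3, -1), k = 3), "negative")
  expect_error(field_invasion(c(3, 1), k = 0), "k must be")
})

test_that("sample invasion averages non-missing fields and flags gaps", {
  expect_equal(as.numeric(sample_invasion(c(30, 10, 20, 25, 15))), 20)
  partial <- sample_invasion(c(30, NA, 20, 25, 25))
  expect_equal(as.numeric(partial), 25)
  expect_equal(attr(partial, "n_fields"), 4L)
  expect_true(attr(partial, "incomplete"))
  expect_equal(as.numeric(sample_invasion(12)), 12)
  expect_true(is.na(sample_invasion(c(NA_real_, NA_real_))))
})

test_that("observer combination averages replicates and records disagreement", {
  two <- combine_observers(c(20, 24))
  expect_equal(as.numeric(two), 22)
  expect_equal(attr(two, "disagreement"), 4)
  one <- combine_observers(22)
  expect_equal(as.numeric(one), 22)
  expect_equal(attr(one, "disagreement"), 0)
  expect_error(combine_observers(numeric(0)), "no scores")
})

test_that("implantation score follows its normalization formula exactly", {
  expect_equal(implantation_score(10, 662, 1e5), 0.0662)
  expect_equal(implantation_score(0, 662, 12345), 0)
  expect_equal(implantation_score(10, 662, 5e4), 0.1324)
  expect_error(implantation_score(10, 662, 0), "live_suspension_count")
  # linear in count, inversely proportional to the live count
  set.seed(61)
  for (i in 1:20) {
    cnt <- runif(1, 0, 50); live <- runif(1, 1e4, 1e6); k <- runif(1, 0.5, 3)
    expect_equal(implantation_score(k * cnt, 662, live),
                 k * implantation_score(cnt, 662, live))
    expect_equal(implantation_score(cnt, 662, k * live),
                 implantation_score(cnt, 662, live) / k)
  }
})

test_that("squares per explant reproduces the design constant", {
  expect_equal(squares_per_explant(15000, 583), 662L)
  expect_equal(squares_per_explant(583, 583), 1L)
  expect_equal(squares_per_explant(1166, 583), 4L)
  expect_warning(sq <- squares_per_explant(400, 583), "larger")
  expect_equal(sq, 1L)
})

test_that("field sampling is non-overlapping, seeded, and tiles exactly in grid mode", {
  f1 <- sample_fields(583, 15000, n = 1L, seed = 3L)
  expect_true(f1$x0_um >= 0 && f1$x0_um <= 15000 - 583)

  f5a <- sample_fields(583, 15000, n = 5L, seed = 9L)
  f5b <- sample_fields(583, 15000, n = 5L, seed = 9L)
  expect_identical(f5a, f5b)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_true(abs(f5a$x0_um[i] - f5a$x0_um[j]) >= 583 ||
                abs(f5a$y0_um[i] - f5a$y0_um[j]) >= 583)
  }

  tiling <- sample_fields(583, 15000, mode = "grid")
  g <- floor(15000 / 583)
  expect_equal(nrow(tiling), g^2)
  # brute-force disjointness and full coverage of the tiled region
  ov <- 0L
  for (i in seq_len(nrow(tiling) - 1L)) {
    dx <- abs(tiling$x0_um[(i + 1):nrow(tiling)] - tiling$x0_um[i])
    dy <- abs(tiling$y0_um[(i + 1):nrow(tiling)] - tiling$y0_um[i])
    ov <- ov + sum(dx < 583 & dy < 583)
  }
  expect_equal(ov, 0L)
  expect_equal(nrow(unique(tiling)) * 583^2, g^2 * 583^2)

  expect_error(sample_fields(583, 1000, n = 5L), "do not fit")
})

test_that("arm comparison computes means, SEMs, t-tests and Bonferroni adjustment", {
  rec <- data.frame(
    sample_id = rep(1:4, 2), day = 1,
    arm = rep(c("a", "b"), each = 4),
    implantation_score = c(1, 1, 1, 1, 1, 1, 1, 1),
    invasion_score_um = c(10, 12, 11, 13, 30, 33, 29, 31))
  tab <- compare_arms(rec)
  imp <- tab[tab$metric == "implantation_score", ]
  expect_equal(imp$p, 1)              # identical groups: no difference
  inv <- tab[tab$metric == "invasion_score_um", ]
  expect_lt(inv$p, 0.01)
  expect_equal(inv$sem2, sd(c(30, 33, 29, 31)) / 2)

  # SEM closed form
  expect_equal(sem(c(2, 4, 6)), 2 / sqrt(3))

  # Bonferroni is min(1, m * p) over each metric's family
  rec5 <- do.call(rbind, lapply(1:5, function(d) {
    set.seed(100 + d)
    data.frame(sample_id = rep(1:3, 2), day = d,
               arm = rep(c("a", "b"), each = 3),
               invasion_score_um = rnorm(6, mean = rep(c(10, 20), each = 3)))
  }))
  tab5 <- compare_arms(rec5)
  expect_equal(nrow(tab5), 5L)
  expect_equal(tab5$p_adj, pmin(1, 5 * tab5$p))
  expect_equal(pmin(1, 5 * 0.01), 0.05)  # the adjustment at m = 5, p = 0.01

  # single replicate: skipped with a warning
  rec1 <- data.frame(sample_id = c(1, 1, 2), day = 1,
                     arm = c("a", "b", "b"),
                     invasion_score_um = c(5, 8, 9))
  expect_warning(t1 <- compare_arms(rec1), "fewer than 2")
  expect_true(is.na(t1$p))
})

test_that("scores are invariant to field and observer order", {
  depths <- list(c(4, 9, 2, 30), c(1, 2), numeric(0), c(8, 8, 8, 25, 40))
  f <- vapply(depths, function(d) as.numeric(field_invasion(d)), 0)
  for (i in 1:5) {
    perm <- sample(length(depths))
    fp <- vapply(depths[perm], function(d) as.numeric(field_invasion(d)), 0)
    expect_equal(as.numeric(sample_invasion(fp)), as.numeric(sample_invasion(f)))
  }
  expect_equal(as.numeric(combine_observers(c(24, 20))),
               as.numeric(combine_observers(c(20, 24))))
})

test_that("the implantation ratio CI is centred on the arm-mean ratio", {
  rec <- data.frame(sample_id = rep(1:4, 2), day = 1,
                    arm = rep(c("hi", "lo"), each = 4),
                    implantation_score = c(4.1, 3.9, 4.2, 3.8, 1.05, 0.95, 1.1, 0.9))
  ci <- implantation_ratio_ci(rec, "hi", "lo")
  expect_equal(ci$ratio, mean(c(4.1, 3.9, 4.2, 3.8)) / mean(c(1.05, 0.95, 1.1, 0.9)))
  expect_true(ci$lo < ci$ratio && ci$ratio < ci$hi)
  expect_true(ci$lo < 4 && 4 < ci$hi)
})
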