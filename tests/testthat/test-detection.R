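# LoG spot detection, 2D and 3D.

test_that("max projection is the per-pixel maximum over z", {
  # single-plane stack: the projection is that plane
  one <- image_stack(red = array(runif(1 * 8 * 8), c(1L, 8L, 8L)),
                     voxel_size_um = c(2, 1, 1))
  expect_equal(max_project(one), one$red[1L, , ], ignore_attr = TRUE)

  # a single voxel of value v projects to v at its (y, x)
  a <- array(0, c(5L, 8L, 8L))
  a[3L, 6L, 2L] <- 4.2
  st <- image_stack(red = a, voxel_size_um = c(2, 1, 1))
  proj <- max_project(st)
  expect_equal(proj[6L, 2L], 4.2)
  expect_equal(sum(proj), 4.2)

  stk <- st; stk$red <- NULL
  expect_error(max_project(stk), "red channel")
})

test_that("projection of a planted-blob field has exactly n_cells maxima above half-peak", {
  p <- small_params(n_cells = 6L, seed = 31L, noise = FALSE)
  g <- generate_stack(p)
  proj <- max_project(g$stack)
  amp <- max(proj) - p$red_baseline
  n_max <- brute_local_max_2d(proj, thr = p$red_baseline + amp / 2)
  expect_equal(n_max, 6L)
})

test_that("a matched blob is localized at the exhaustive LoG argmax", {
  # small clean image, blob off-center; oracle = brute-force LoG argmax
  n <- 48L; sigma <- 3
  ctr <- c(r = 29.3, c = 17.8)
  img <- outer(seq_len(n), seq_len(n), function(r, c)
    10 * exp(-((r - ctr[1L])^2 + (c - ctr[2L])^2) / (2 * sigma^2)))
  oracle <- brute_log_argmax(img, sigma)
  spots <- detect_spots_2d(img, pixel_size_um = c(1, 1),
                           radius_um = 2 * sigma, prefilter = FALSE)
  expect_equal(nrow(spots), 1L)
  # px index of the detected center (pixel centers at (i - 0.5) um here)
  det_px <- c(spots$y_um[1L] + 0.5, spots$x_um[1L] + 0.5)
  expect_lt(max(abs(det_px - oracle)), 1.01)

  expect_error(detect_spots_2d(img, pixel_size_um = c(1, 1), radius_um = 0),
               "radius_um")
})

test_that("blank images and stacks give zero spots", {
  blank <- matrix(0, 64L, 64L)
  expect_equal(nrow(detect_spots_2d(blank, pixel_size_um = c(1, 1))), 0L)
  st <- image_stack(red = array(0, c(8L, 32L, 32L)), voxel_size_um = c(2, 1, 1))
  expect_equal(nrow(detect_spots_3d(st)), 0L)
})

test_that("well-separated planted blobs are each found within one pixel", {
  p <- small_params(n_cells = 6L, seed = 13L)
  g <- generate_stack(p)
  spots <- detect_spots_2d(max_project(g$stack))
  expect_equal(nrow(spots), 6L)
  dxy <- 146 / 128
  expect_equal(match_spots(spots, g$truth$cells, tol_um = dxy), 6L)
})

test_that("3D detection localizes depth to within one z-step", {
  p <- small_params(n_cells = 1L, seed = 17L,
                    depth_distribution = list(type = "fixed", depth_um = 17))
  g <- generate_stack(p)   # z_mid = 8 + 17 = 25 um
  spots <- detect_spots_3d(g$stack)
  expect_equal(nrow(spots), 1L)
  expect_lt(abs(spots$z_um[1L] - g$truth$cells$z_mid_um[1L]), 2)

  # two blobs separated only in z by >= 4 sigma_z resolve as two spots
  cells <- data.frame(x_um = 70, y_um = 70, z_mid_um = c(9, 25))
  p2 <- small_params(n_cells = 2L, seed = 18L, cells = cells,
                     min_cell_separation_um = 0)
  g2 <- generate_stack(p2)
  s2 <- detect_spots_3d(g2$stack)
  expect_equal(nrow(s2), 2L)
  expect_equal(sort(round(s2$z_um)), c(9, 25), tolerance = 0.12)

  thin <- image_stack(red = array(0, c(2L, 16L, 16L)), voxel_size_um = c(2, 1, 1))
  expect_error(detect_spots_3d(thin), "fewer than 3 planes")
})

test_that("detection is translation-equivariant for whole-pixel shifts", {
  # cells planted away from the wrap seam so the roll moves whole blobs
  cells <- data.frame(x_um = c(45, 80, 110), y_um = c(50, 95, 70),
                      z_mid_um = c(12, 18, 24))
  p <- small_params(n_cells = 3L, seed = 23L, cells = cells)
  g <- generate_stack(p)
  proj <- max_project(g$stack)
  s0 <- detect_spots_2d(proj)
  shift <- 11L
  shifted <- proj[c((shift + 1):nrow(proj), seq_len(shift)), ]
  attr(shifted, "pixel_size_um") <- attr(proj, "pixel_size_um")
  s1 <- detect_spots_2d(shifted)
  expect_equal(nrow(s1), nrow(s0))
  dxy <- 146 / 128
  for (i in seq_len(nrow(s0))) {
    d <- sqrt((s1$x_um - s0$x_um[i])^2 +
              (s1$y_um - (s0$y_um[i] - shift * dxy))^2)
    expect_lt(min(d), 0.05)
  }
})

test_that("spot count is monotone non-increasing in the threshold", {
  p <- small_params(n_cells = 6L, seed = 29L)
  g <- generate_stack(p)
  proj <- max_project(g$stack)
  counts <- vapply(c(5, 10, 20, 30, 40),
                   function(t) nrow(detect_spots_2d(proj, threshold = t)), 0L)
  expect_true(all(diff(counts) <= 0L))
})

test_that("operating curve: perfect at SNR >= 10, precision holds at SNR 2", {
  n_cfg <- 100L
  rec10 <- prec10 <- prec2 <- numeric(0)
  for (i in seq_len(n_cfg)) {
    n_cells <- 2L + (i %% 5L)
    p_hi <- generator_params(field_size_um = 110, pixels_per_axis = 96L,
                             z_depth_um = 26,
                             surface = list(type = "plane", z0_um = 6,
                                            tilt_x = 0, tilt_y = 0),
                             n_cells = n_cells, min_cell_separation_um = 28,
                             snr = 10, seed = 7000L + i)
    g <- generate_stack(p_hi)
    sp <- detect_spots_2d(max_project(g$stack))
    hits <- match_spots(sp, g$truth$cells, tol_um = 3.5)
    rec10 <- c(rec10, hits / n_cells)
    prec10 <- c(prec10, if (nrow(sp)) hits / nrow(sp) else 1)

    p_lo <- p_hi; p_lo$snr <- 2
    g2 <- generate_stack(p_lo)
    sp2 <- detect_spots_2d(max_project(g2$stack))
    hits2 <- match_spots(sp2, g2$truth$cells, tol_um = 3.5)
    prec2 <- c(prec2, if (nrow(sp2)) hits2 / nrow(sp2) else 1)
  }
  expect_equal(mean(rec10), 1)
  expect_equal(mean(prec10), 1)
  expect_gte(min(prec2), 0.9)
})
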