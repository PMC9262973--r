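# Synthetic stack and experiment generation.

test_that("empty fields, determinism and the z-plane grid behave as specified", {
  p0 <- small_params(n_cells = 0L, seed = 3L)
  g0 <- generate_stack(p0)
  expect_equal(nrow(g0$truth$cells), 0L)

  p <- small_params(seed = 7L)
  g1 <- generate_stack(p)
  g2 <- generate_stack(p)
  expect_identical(g1$stack$red, g2$stack$red)
  expect_identical(g1$stack$green, g2$stack$green)
  expect_identical(g1$truth$cells, g2$truth$cells)

  # default geometry: planes at 0, 2, ..., 60 -> ceiling(60/2) + 1 = 31
  gdef <- generator_params()
  expect_equal(floor(gdef$z_depth_um / gdef$z_step_um) + 1L, 31L)
  expect_equal(dim(generate_stack(small_params(n_cells = 0L))$stack$red)[1L],
               floor(30 / 2) + 1L)
})

test_that("invalid generator geometry is rejected", {
  expect_error(generator_params(field_size_um = -1), "geometry")
  expect_error(generator_params(z_step_um = 0), "geometry")
  expect_error(generator_params(n_cells = -1), "n_cells")
  expect_error(generator_params(snr = 0), "snr")
})

test_that("ground-truth depth equals z_mid minus the true surface height", {
  for (surf in list(list(type = "plane", z0_um = 10, tilt_x = 0.02, tilt_y = -0.01),
                    list(type = "sheet", z0_um = 9, amplitude_um = 3))) {
    p <- small_params(n_cells = 8L, surface = surf, seed = 21L)
    g <- generate_stack(p)
    tr <- g$truth$cells
    zs <- surface_at(g$truth$surface, tr$x_um, tr$y_um)
    expect_lt(max(abs(tr$depth_um - (tr$z_mid_um - zs))), 0.05)
    expect_true(all(tr$depth_um >= 0))
  }
})

test_that("blob peak over background noise sd matches the requested snr", {
  p <- small_params(n_cells = 4L, snr = 12, seed = 5L)
  pn <- p; pn$noise <- FALSE
  noisy <- generate_stack(p)$stack$red
  clean <- generate_stack(pn)$stack$red
  bg <- abs(clean - p$red_baseline) < 1e-9     # voxels with no blob signal
  noise_sd <- sd((noisy - clean)[bg])
  amp <- max(clean) - p$red_baseline
  expect_lt(abs(amp / noise_sd - p$snr) / p$snr, 0.10)
})

test_that("green reflectance is confined to at/below the surface", {
  p <- small_params(n_cells = 0L, seed = 9L)
  g <- generate_stack(p)
  zg <- seq(0, by = p$z_step_um, length.out = dim(g$stack$green)[1L])
  above <- zg < (8 - p$z_step_um)   # strictly above the z0 = 8 um plane
  below <- zg >= 8
  m_above <- mean(g$stack$green[above, , ])
  m_below <- mean(g$stack$green[below, , ])
  expect_lt(m_above, 0.10 * m_below)
})

test_that("experiment generation honours arm design and effect sizes", {
  # degenerate probability: every field gets the full budget
  a1 <- arm_spec("all", implant_prob = 1, depth_mean_um = 10,
                 n_samples = 1L, n_fields_per_sample = 4L,
                 seeded_per_field = 10L)
  e1 <- generate_experiment(list(a1), seed = 2L,
                            params_template = small_params())
  expect_true(all(e1$manifest$n_planted == 10L))

  # 4:1 implantation probability ratio recovered within binomial error
  a_hi <- arm_spec("hi", 0.4, 10, n_samples = 10L, n_fields_per_sample = 5L,
                   seeded_per_field = 40L)
  a_lo <- arm_spec("lo", 0.1, 10, n_samples = 10L, n_fields_per_sample = 5L,
                   seeded_per_field = 40L)
  e2 <- generate_experiment(list(a_hi, a_lo), seed = 11L,
                            params_template = generator_params())
  mhi <- mean(e2$manifest$n_planted[e2$manifest$arm == "hi"])
  mlo <- mean(e2$manifest$n_planted[e2$manifest$arm == "lo"])
  # exact binomial sds: sqrt(n p q / m) for m fields of budget n
  m <- 50
  se_ratio <- (0.4 / 0.1) * sqrt(0.4 * 0.6 / (40 * m) / 0.4^2 +
                                 0.1 * 0.9 / (40 * m) / 0.1^2)
  expect_lt(abs(mhi / mlo - 4), 4 * se_ratio)

  expect_error(generate_experiment(list(), seed = 1L), "at least one arm")
  expect_error(generate_experiment(list(a1, a1), seed = 1L), "duplicate")
  expect_error(arm_spec("x", implant_prob = 1.4, depth_mean_um = 5),
               "implant_prob")
})

test_that("every stack in a disk dataset is mapped by the manifest", {
  dir <- withr::local_tempdir()
  a <- arm_spec("v", 0.8, 6, n_samples = 1L, n_fields_per_sample = 2L,
                seeded_per_field = 6L)
  e <- generate_experiment(list(a), seed = 4L, days = c(1L, 2L),
                           params_template = small_params(),
                           stacks = "disk", dir = dir)
  expect_true(all(file.exists(e$manifest$path)))
  expect_equal(nrow(e$manifest), 4L)  # 1 sample x 2 days x 2 fields
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "suspension.csv")))
})

test_that("wound series follow the closure model and reject bad baselines", {
  w0 <- generate_wound_series(100, closure_rate = 0, noise_sd = 0)
  expect_equal(w0$area, rep(100, 4))
  w1 <- generate_wound_series(80, closure_rate = 1 / 24,
                              times_h = c(0, 12, 24), noise_sd = 0)
  expect_equal(w1$area, c(80, 40, 0))
  expect_error(generate_wound_series(100, 0.1, times_h = c(8, 16)), "t = 0")
  expect_error(generate_wound_series(-5, 0.1), "initial_area")
  # reproducible for a fixed seed
  expect_identical(generate_wound_series(50, 0.02, noise_sd = 3, seed = 8L),
                   generate_wound_series(50, 0.02, noise_sd = 3, seed = 8L))
})
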