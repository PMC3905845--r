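# Synthetic-data generator: geometry, imaging model, FRAP traces, N&B stacks.

test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(pixel_size_um = 0), "positive")
  expect_error(sim_config(image_shape = c(8, 64)), ">= 16")
  expect_error(sim_config(foci_per_cell_mean = -1), ">= 0")
  expect_error(sim_config(focus_brightness_multiple = 0.5), ">= 1")
})

test_that("make_cell_geometry: empty case and single calibrated cell", {
  cfg <- small_field_config()
  g0 <- make_cell_geometry(cfg, 0)
  expect_true(all(g0$labels == 0))
  expect_equal(nrow(g0$truth), 0)

  # single cell, fixed area, sd 0: pixel area matches 45 um^2 within 1 px
  cfg1 <- small_field_config(mean_cell_area_um2 = 45, cell_area_sd_um2 = 0,
                             foci_per_cell_mean = 0)
  g1 <- make_cell_geometry(cfg1, 1, seed = 3)
  px_area <- sum(g1$labels == 1) * cfg1$pixel_size_um^2
  expect_equal(nrow(g1$truth), 1)
  expect_equal(px_area, g1$truth$area_um2)          # truth records raster area
  expect_lte(abs(px_area - 45), cfg1$pixel_size_um^2)
})

test_that("make_cell_geometry: cell population reproduces the target area distribution", {
  cfg <- sim_config(image_shape = c(480, 480))
  areas <- numeric(0)
  for (s in 1:4) {
    g <- suppressWarnings(make_cell_geometry(cfg, 50, seed = 100 + s))
    areas <- c(areas, g$truth$area_um2)
  }
  expect_gte(length(areas), 150)
  se <- 6 / sqrt(length(areas))
  expect_lt(abs(mean(areas) - 28), 2 * se + 0.5)    # raster quantisation slack
})

test_that("make_cell_geometry: cells are disjoint, connected, foci inside cells", {
  cfg <- small_field_config()
  g <- make_cell_geometry(cfg, 8, seed = 7)
  for (ci in g$truth$cell) {
    mask <- g$labels == ci
    expect_equal(max(halodyn:::label_components(mask)), 1)  # simply connected
  }
  if (nrow(g$foci) > 0) {
    expect_true(all(g$labels[cbind(g$foci$row, g$foci$col)] == g$foci$cell))
  }
  # crowding: tiny field cannot hold many cells
  cfg_tiny <- sim_config(image_shape = c(40, 40), mean_cell_area_um2 = 28)
  expect_warning(make_cell_geometry(cfg_tiny, 30, seed = 1), "too crowded")
})

test_that("simulate_timelapse: pure shot noise when no molecules or foci", {
  cfg <- sim_config(image_shape = c(48, 48), pool_molecules_per_cell = 0,
                    foci_per_cell_mean = 0, background_counts = 7)
  g <- make_cell_geometry(cfg, 1, seed = 2)
  sim <- simulate_timelapse(g, cfg, n_frames = 60, seed = 2)
  v <- as.numeric(unclass(sim$stack))
  expect_true(all(v >= 0 & v == round(v)))
  expect_lt(abs(mean(v) - 7), 0.1)
  expect_lt(abs(stats::var(v) - 7), 0.3)
})

test_that("simulate_timelapse: photon conservation in a noiseless frame", {
  cfg <- sim_config(image_shape = c(128, 128), pool_molecules_per_cell = 150,
                    molecular_brightness_counts = 4, background_counts = 3,
                    foci_per_cell_mean = 2)
  g <- make_cell_geometry(cfg, 2, seed = 9)
  sim <- simulate_timelapse(g, cfg, n_frames = 1, noise = FALSE, seed = 9)
  total <- sum(unclass(sim$stack)[, , 1])
  expected <- 3 * 128^2 + nrow(g$truth) * 150 * 4 + sum(g$truth$n_foci) *
    cfg$focus_brightness_multiple * 4
  expect_equal(total, expected, tolerance = 1e-12)
})

test_that("simulate_timelapse: total photon count matches analytic expectation", {
  cfg <- sim_config(image_shape = c(96, 96), pool_molecules_per_cell = 200,
                    molecular_brightness_counts = 5, background_counts = 10,
                    foci_per_cell_mean = 0)
  g <- make_cell_geometry(cfg, 1, seed = 21)
  sim <- simulate_timelapse(g, cfg, n_frames = 1, seed = 21)
  N_exp <- 10 * 96^2 + 200 * 5
  expect_lt(abs(sum(unclass(sim$stack)) - N_exp), 3 * sqrt(N_exp))
})

test_that("simulate_timelapse: brightest blob sits at an isolated focus", {
  cfg <- sim_config(image_shape = c(64, 64), pool_molecules_per_cell = 0,
                    background_counts = 1, foci_per_cell_mean = 1,
                    focus_brightness_multiple = 200)
  for (s in 4:6) {
    g <- make_cell_geometry(cfg, 1, seed = s)
    if (nrow(g$foci) == 1) break
  }
  expect_equal(nrow(g$foci), 1)
  sim <- simulate_timelapse(g, cfg, n_frames = 1, noise = FALSE, seed = 1)
  peak <- which(unclass(sim$stack)[, , 1] == max(unclass(sim$stack)), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(peak - c(g$foci$row, g$foci$col))), 1)
})

test_that("seed determinism: identical config and seed give identical output", {
  cfg <- sim_config(image_shape = c(64, 64))
  g1 <- suppressWarnings(make_cell_geometry(cfg, 4, seed = 5))
  g2 <- suppressWarnings(make_cell_geometry(cfg, 4, seed = 5))
  expect_identical(g1$labels, g2$labels)
  expect_identical(g1$foci, g2$foci)
  s1 <- simulate_timelapse(g1, cfg, n_frames = 3, seed = 5)
  s2 <- simulate_timelapse(g2, cfg, n_frames = 3, seed = 5)
  expect_identical(unclass(s1$stack), unclass(s2$stack))
  n1 <- simulate_nandb_stack(10, 0.3, 20, config = cfg, seed = 5)
  n2 <- simulate_nandb_stack(10, 0.3, 20, config = cfg, seed = 5)
  expect_identical(unclass(n1$stack), unclass(n2$stack))
})

test_that("simulate_frap_traces: closed forms and input validation", {
  cfg <- sim_config()
  expect_error(simulate_frap_traces(-1, 0.3), "k_values")
  expect_error(simulate_frap_traces(1, -0.3), "amplitudes")

  # full bleach, single k = 1, no immobile: F(t) = 1 - exp(-t)
  sim <- simulate_frap_traces(1, 1, immobile_fraction = 0, noise_sd = 0,
                              config = cfg, seed = 1)
  tr <- sim$traces[[1]]
  post <- (tr$n_prebleach + 1):length(tr$t)
  tp <- tr$t[post] - tr$t[post[1]]
  expect_equal(tr$I_norm[post], 1 - exp(-tp), tolerance = 1e-12)
  expect_equal(tr$I_norm[seq_len(tr$n_prebleach)], rep(1, 50))

  # k = 1.15, plateau 0.35 (maximal recovery of a full bleach):
  # F(5 s) = 0.35 * (1 - exp(-5.75)) ~ 0.349
  sim2 <- simulate_frap_traces(1.15, 0.35, immobile_fraction = 0.65,
                               noise_sd = 0, config = cfg, seed = 1)
  tr2 <- sim2$traces[[1]]
  i5 <- which.min(abs((tr2$t - tr2$t[51]) - 5))
  expect_equal(tr2$I_norm[i5], 0.35 * (1 - exp(-1.15 * 5)), tolerance = 1e-3)
  expect_equal(sim2$truth$bleach_depth, 1)
})

test_that("simulate_nandb_stack: degenerate inputs and compound-Poisson moments", {
  cfg <- sim_config(image_shape = c(24, 24))
  expect_error(simulate_nandb_stack(10, 0.3, n_frames = 1, config = cfg),
               "n_frames")
  # no fluorophores: pure Poisson background, molecular brightness ~ 0
  s0 <- simulate_nandb_stack(10, 0, n_frames = 2000, config = cfg,
                             background = 4, seed = 11)
  mom <- pixel_moments(s0$stack)
  expect_lt(abs(mean(mom$variance_map / mom$mean_map) - 1), 0.05)

  # compound Poisson at zero background: mean -> n*eps, var/mean -> 1+eps
  s1 <- simulate_nandb_stack(27, 0.5, n_frames = 10000, config = cfg,
                             background = 0, seed = 12)
  mom1 <- pixel_moments(s1$stack)
  expect_lt(abs(mean(mom1$mean_map) / (27 * 0.5) - 1), 0.05)
  expect_lt(abs(mean(mom1$variance_map / mom1$mean_map) / 1.5 - 1), 0.05)
})
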