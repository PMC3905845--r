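# FRAP normalization and kinetic fitting.

test_that("normalize_trace: constant and degenerate traces", {
  t <- seq(0, 40, by = 0.272)
  tr <- normalize_trace(t, rep(500, length(t)), rep(0, length(t)))
  expect_equal(tr$I_norm, rep(1, length(t)), tolerance = 1e-9)
  # ROI equal to background: zero reference, rejected
  expect_error(normalize_trace(t, rep(100, length(t)), rep(100, length(t))),
               "reference")
  expect_error(normalize_trace(t[1:60], rep(1, 60), rep(0, 60),
                               n_prebleach = 2), ">= 3")
})

test_that("normalization corrects acquisition bleaching and restores the plateau", {
  cfg <- sim_config(n_frames = 150)
  # ~5% decay over the 50 pre-bleach frames
  rate <- -log(0.95) / (50 * cfg$frame_interval_s)
  sim <- simulate_frap_traces(1.15, 0.35, immobile_fraction = 0.65,
                              noise_sd = 0, config = cfg,
                              acq_bleach_rate = rate, seed = 2)
  raw <- sim$traces[[1]]
  tr <- normalize_trace(raw$t, raw$I_raw, raw$I_b)
  expect_lt(abs(mean(tr$I_norm[1:50]) - 1), 0.02)
  fit <- fit_recovery(tr, "mono")
  expect_equal(fit$plateau, 0.35, tolerance = 0.01)
  expect_equal(fit$k, 1.15, tolerance = 0.02)
})

test_that("scale invariance: rescaling raw intensities leaves the fit unchanged", {
  cfg <- sim_config()
  sim <- simulate_frap_traces(1.15, 0.35, 0.65, noise_sd = 0.02,
                              config = cfg, seed = 3)
  raw <- sim$traces[[1]]
  f1 <- fit_recovery(normalize_trace(raw$t, raw$I_raw, raw$I_b), "mono")
  f2 <- fit_recovery(normalize_trace(raw$t, raw$I_raw * 37.5, raw$I_b * 37.5),
                     "mono")
  expect_equal(f1$k, f2$k, tolerance = 1e-6)
  expect_equal(f1$plateau, f2$plateau, tolerance = 1e-6)
})

test_that("average_traces: identity, symmetry and noise reduction", {
  cfg <- sim_config()
  sim <- simulate_frap_traces(1, 0.5, 0.5, noise_sd = 0, config = cfg, seed = 1)
  tr <- sim$traces[[1]]
  expect_equal(average_traces(list(tr, tr))$I_norm, tr$I_norm)
  up <- tr; up$I_norm <- tr$I_norm + 0.1
  dn <- tr; dn$I_norm <- tr$I_norm - 0.1
  expect_equal(average_traces(list(up, dn))$I_norm, tr$I_norm)
  bad <- tr; bad$t <- tr$t + 1
  expect_error(average_traces(list(tr, bad)), "common time grid")

  # averaging 26 noisy traces shrinks the residual sd by ~ sqrt(26)
  simn <- simulate_frap_traces(1, 0.5, 0.5, noise_sd = 0.05, n_traces = 26,
                               config = cfg, seed = 4)
  clean <- sim$traces[[1]]$I_norm
  avg <- average_traces(simn$traces)
  sd_one <- stats::sd(simn$traces[[1]]$I_norm - clean)
  sd_avg <- stats::sd(avg$I_norm - clean)
  expect_equal(sd_one / sd_avg, sqrt(26), tolerance = 0.35)
})

test_that("fit_recovery: exact recovery of a noiseless mono-exponential", {
  cfg <- sim_config()
  sim <- simulate_frap_traces(1.15, 0.35, 0.65, noise_sd = 0, config = cfg,
                              seed = 1)
  f <- fit_recovery(sim$traces[[1]], "mono")
  expect_equal(f$k, 1.15, tolerance = 1e-6)
  expect_lt(f$rmse, 1e-8)
  expect_equal(f$tau_half, log(2) / 1.15, tolerance = 1e-6)
})

test_that("mono fit bias is small across the physiological rate range", {
  cfg <- sim_config()
  rel_bias <- vapply(c(0.1, 0.5, 1, 2, 5), function(k_true) {
    khat <- vapply(1:25, function(r) {
      sim <- simulate_frap_traces(k_true, 0.4, 0.2, noise_sd = 0.03,
                                  config = cfg, seed = 1000 * r + round(100 * k_true))
      fit_recovery(sim$traces[[1]], "mono")$k
    }, numeric(1))
    stats::median(khat / k_true - 1)
  }, numeric(1))
  expect_lt(abs(stats::median(rel_bias)), 0.02)
  expect_true(all(abs(rel_bias) < 0.1))
})

test_that("bi-exponential components with close rates are flagged and CIs overlap", {
  cfg <- sim_config()
  sim <- simulate_frap_traces(c(1, 0.5), c(0.2, 0.2), immobile_fraction = 0.2,
                              noise_sd = 0.03, n_traces = 10, config = cfg,
                              seed = 17)
  f <- fit_recovery(average_traces(sim$traces), "bi")
  expect_true(f$ambiguous)
  expect_gt(f$k_ci[1, 2], f$k_ci[2, 1])   # fast lower CI below slow upper CI
})

test_that("half_time and diffusion_coefficient arithmetic", {
  expect_equal(half_time(log(2)), 1)
  expect_equal(half_time(1.15), 0.6027, tolerance = 1e-4)
  expect_equal(half_time(0.24), 2.888, tolerance = 1e-3)
  expect_error(half_time(0), "> 0")
  expect_equal(diffusion_coefficient(1, 4 * log(2)), 1)
  # D is linear in k and in A
  expect_equal(diffusion_coefficient(2, 3.72), 2 * diffusion_coefficient(1, 3.72))
  expect_equal(diffusion_coefficient(1, 1.86), diffusion_coefficient(1, 3.72) / 2)
  expect_error(diffusion_coefficient(-1, 3.72), "> 0")
})

test_that("bootstrap CIs broadly agree with asymptotic ones", {
  cfg <- sim_config()
  sim <- simulate_frap_traces(1.15, 0.35, 0.65, noise_sd = 0.03, n_traces = 17,
                              config = cfg, seed = 23)
  f <- fit_recovery(average_traces(sim$traces), "mono", bootstrap = 100,
                    bootstrap_seed = 1)
  expect_false(is.null(f$bootstrap_k_ci))
  # both intervals contain the true rate
  expect_true(f$k_ci[1, 1] < 1.15 && 1.15 < f$k_ci[1, 2])
  expect_true(f$bootstrap_k_ci[1, 1] < 1.15 && 1.15 < f$bootstrap_k_ci[2, 1])
})

test_that("FRAP trace CSV round-trip", {
  cfg <- sim_config()
  sim <- simulate_frap_traces(1, 0.5, 0.3, noise_sd = 0.01, config = cfg,
                              seed = 6)
  path <- tempfile(fileext = ".csv")
  write_frap_csv(path, sim$traces[[1]])
  df <- read_frap_csv(path)
  expect_equal(df$roi, sim$traces[[1]]$I_raw, tolerance = 1e-9)
  expect_equal(df$time_s, sim$traces[[1]]$t, tolerance = 1e-9)
  expect_error(read_frap_csv({
    p <- tempfile(fileext = ".csv")
    utils::write.csv(data.frame(a = 1), p, row.names = FALSE)
    p
  }), "columns")
})
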