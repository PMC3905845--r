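# Segmentation, focus detection and per-cell/population quantification.

test_that("max_project matches a brute-force per-pixel loop", {
  set.seed(42)
  a <- array(rnorm(12 * 10 * 5), c(12, 10, 5))
  st <- image_stack(a, 0.2, 1)
  # single slice: identity
  expect_equal(max_project(st, 2), a[, , 2])
  # dominant slice
  b <- a; b[, , 3] <- 100
  expect_equal(max_project(image_stack(b, 0.2, 1), 1:5), b[, , 3])
  # brute force oracle
  oracle <- matrix(0, 12, 10)
  for (i in 1:12) for (j in 1:10) oracle[i, j] <- max(a[i, j, 1:4])
  expect_equal(max_project(st, 1:4), oracle)
  expect_error(max_project(st, integer(0)), "empty")
  expect_error(max_project(st, 9), "depth")
})

test_that("segment_cells requires calibration and handles blank images", {
  img <- matrix(5, 64, 64)
  expect_error(segment_cells(img), "pixel_size_um")
  expect_equal(max(segment_cells(img, pixel_size_um = 0.2)), 0)
})

test_that("segment_cells recovers two separated synthetic cells", {
  cfg <- small_field_config(foci_per_cell_mean = 0)
  g <- make_cell_geometry(cfg, 2, seed = 31)
  sim <- simulate_timelapse(g, cfg, n_frames = 1, seed = 31)
  img <- get_frame(sim$stack, 1)
  lab <- segment_cells(img, pixel_size_um = cfg$pixel_size_um)
  expect_equal(max(lab), 2)
  areas <- sort(tabulate(lab[lab > 0]) * cfg$pixel_size_um^2)
  expect_equal(areas, sort(g$truth$area_um2), tolerance = 0.1)
})

test_that("split_by_seeds separates touching cells with distinct maxima", {
  img <- two_blob_image(centres = list(c(48, 45), c(48, 80)))
  expect_equal(max(segment_cells(img, pixel_size_um = 0.207,
                                 split_by_seeds = TRUE)), 2)
  expect_equal(max(segment_cells(img, pixel_size_um = 0.207,
                                 split_by_seeds = FALSE)), 1)
})

test_that("segmentation label count is invariant under intensity scaling", {
  cfg <- small_field_config()
  g <- make_cell_geometry(cfg, 4, seed = 13)
  img <- get_frame(simulate_timelapse(g, cfg, n_frames = 1, seed = 13)$stack, 1)
  l1 <- segment_cells(img, pixel_size_um = cfg$pixel_size_um)
  l2 <- segment_cells(img * 17.3, pixel_size_um = cfg$pixel_size_um)
  expect_equal(max(l1), max(l2))
})

test_that("detect_foci: mandatory threshold, assignment and dominance", {
  cfg <- small_field_config(foci_per_cell_mean = 3)
  g <- make_cell_geometry(cfg, 1, seed = 44)
  expect_gte(sum(g$truth$n_foci), 1)
  img <- get_frame(simulate_timelapse(g, cfg, n_frames = 1, seed = 44)$stack, 1)
  lab <- segment_cells(img, pixel_size_um = cfg$pixel_size_um)
  expect_error(detect_foci(img, lab, pixel_size_um = cfg$pixel_size_um),
               "quality threshold required")
  f <- detect_foci(img, lab, pixel_size_um = cfg$pixel_size_um,
                   quality_threshold = 10)
  expect_equal(nrow(f), sum(g$truth$n_foci))
  expect_true(all(f$cell_id == 1))
  # threshold above every response: nothing retained
  f_hi <- detect_foci(img, lab, pixel_size_um = cfg$pixel_size_um,
                      quality_threshold = max(f$quality) * 10)
  expect_equal(nrow(f_hi), 0)
})

test_that("raising the quality threshold never increases focus counts", {
  cfg <- small_field_config()
  g <- make_cell_geometry(cfg, 5, seed = 55)
  img <- get_frame(simulate_timelapse(g, cfg, n_frames = 1, seed = 55)$stack, 1)
  lab <- segment_cells(img, pixel_size_um = cfg$pixel_size_um)
  thresholds <- c(1, 5, 10, 20, 40, 80)
  counts <- vapply(thresholds, function(q) {
    nrow(detect_foci(img, lab, pixel_size_um = cfg$pixel_size_um,
                     quality_threshold = q))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection recovers Poisson foci statistics with good precision/recall", {
  cfg <- sim_config(image_shape = c(300, 300))
  tp <- fp <- fn <- 0L; n_true <- n_det <- 0L; n_cells <- 0L
  # calibrate the quality threshold on a held-out field
  g0 <- make_cell_geometry(cfg, 12, seed = 900)
  img0 <- get_frame(simulate_timelapse(g0, cfg, n_frames = 1, seed = 900)$stack, 1)
  thr <- calibrate_quality_threshold(img0, g0$foci,
                                     pixel_size_um = cfg$pixel_size_um)
  for (s in 1:4) {
    g <- make_cell_geometry(cfg, 12, seed = 200 + s)
    img <- get_frame(simulate_timelapse(g, cfg, n_frames = 1,
                                        seed = 200 + s)$stack, 1)
    lab <- segment_cells(img, pixel_size_um = cfg$pixel_size_um)
    f <- detect_foci(img, lab, pixel_size_um = cfg$pixel_size_um,
                     quality_threshold = thr)
    m <- match_foci(f, g$foci, radius_px = 0.5 / cfg$pixel_size_um)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    n_true <- n_true + sum(g$truth$n_foci); n_det <- n_det + nrow(f)
    n_cells <- n_cells + nrow(g$truth)
  }
  expect_gte(tp / (tp + fp), 0.9)                     # precision
  expect_gte(tp / (tp + fn), 0.9)                     # recall
  expect_lt(abs(n_det / n_cells - n_true / n_cells) / (n_true / n_cells), 0.1)
})

test_that("per_cell_metrics: exact sums and focus fractions", {
  # uniform square cell, no foci: total intensity is exact
  lab <- matrix(0L, 40, 40); lab[10:29, 10:29] <- 1L
  attr(lab, "pixel_size_um") <- 0.5
  img <- matrix(2, 40, 40)
  no_foci <- detect_foci(img * 0, lab, pixel_size_um = 0.5,
                         quality_threshold = 1)
  cells <- per_cell_metrics(img, lab, no_foci, pixel_size_um = 0.5)
  expect_equal(cells$total_intensity, 2 * 400)
  expect_equal(cells$surface_um2, 400 * 0.25)
  expect_equal(cells$n_foci, 0L)

  # one focus holding a known fraction of cell intensity
  img2 <- img
  img2[20, 20] <- img2[20, 20] + 200
  foci <- data.frame(cell_id = 1L, x_um = 19 * 0.5, y_um = 19 * 0.5,
                     row = 20L, col = 20L, diameter_um = 0.75,
                     intensity = 200, quality = 10)
  cells2 <- per_cell_metrics(img2, lab, foci, pixel_size_um = 0.5)
  f_true <- (200 + 2) / (2 * 400 + 200)
  expect_equal(cells2$foci_total_intensity / cells2$total_intensity, f_true,
               tolerance = 1e-12)

  # focus outside all labels is excluded
  foci_out <- foci; foci_out$cell_id <- 0L
  cells3 <- per_cell_metrics(img2, lab, foci_out, pixel_size_um = 0.5)
  expect_equal(cells3$n_foci, 0L)
  expect_equal(cells3$foci_total_intensity, 0)

  # empty label set
  expect_equal(nrow(per_cell_metrics(img, matrix(0L, 40, 40), no_foci,
                                     pixel_size_um = 0.5)), 0)
})

test_that("population_summary: totals-ratio statistics and histogram", {
  cells <- data.frame(cell_id = 1:2, surface_um2 = c(20, 40),
                      total_intensity = c(100, 300), n_foci = c(1L, 3L),
                      foci_total_intensity = c(50, 150))
  s <- population_summary(cells)
  expect_equal(s$mean_foci_per_cell, 2.0)
  expect_equal(s$average_cell_surface, 30)
  expect_equal(s$mean_intensity_per_cell, 200)
  expect_equal(s$fraction_intensity_in_foci, 0.5)
  expect_equal(sum(s$foci_count_histogram), 2)
  # totals-ratio identity holds exactly by construction
  expect_equal(s$mean_intensity_per_surface * s$average_cell_surface,
               s$mean_intensity_per_cell)
  # all intensity in foci
  cells$foci_total_intensity <- cells$total_intensity
  expect_equal(population_summary(cells)$fraction_intensity_in_foci, 1)
  # histogram clamps at 20
  cells$n_foci <- c(25L, 1L)
  h <- population_summary(cells)$foci_count_histogram
  expect_equal(unname(h["20"]), 1)
  expect_error(population_summary(cells[0, ]), "at least one cell")
})

test_that("control-like population has its modal class at 1-2 foci", {
  cfg <- sim_config(image_shape = c(300, 300))
  nf <- integer(0)
  for (s in 1:6) {
    g <- make_cell_geometry(cfg, 12, seed = 700 + s)
    nf <- c(nf, g$truth$n_foci)
  }
  h <- tabulate(nf + 1L, nbins = 21)
  expect_true(which.max(h) %in% c(2L, 3L))            # classes 1 and 2 foci
  # about half the cells carry one or two foci under Poisson(2)
  expect_gt(mean(nf %in% c(1L, 2L)), 0.4)
})
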