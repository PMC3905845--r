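# Synthetic-data generator: pleiomorphic cells, wide-field time-lapses with
# diffusing pool + immobile sub-resolution foci, FRAP traces and
# photon-counting N&B stacks, all with recorded ground truth.

#' Simulation configuration
#'
#' Holds every physical parameter of the synthetic acquisitions. Defaults
#' mirror the experimental setup being emulated: 207 nm pixels
#' (photon-counting confocal scans), 0.272 s frame interval and 150-frame
#' FRAP acquisitions, cell surfaces of 28 +/- 6 um^2 and on average 2
#' fluorescence foci per cell under control conditions.
#'
#' @param pixel_size_um pixel edge length (um/px).
#' @param frame_interval_s frame interval (s).
#' @param n_frames frames per acquisition.
#' @param image_shape integer (rows, cols) of the simulated field.
#' @param mean_cell_area_um2,cell_area_sd_um2 Gaussian cell-surface
#'   distribution (um^2).
#' @param foci_per_cell_mean Poisson mean of foci per cell.
#' @param focus_brightness_multiple brightness of one focus in units of one
#'   pool molecule (>= 1); a focus is rendered as a single sub-resolution
#'   point source of this many molecule-equivalents.
#' @param pool_molecules_per_cell diffusing molecules per cell.
#' @param molecular_brightness_counts detected photons per molecule per
#'   frame (dwell).
#' @param background_counts background photons per pixel per frame.
#' @param psf_sigma_um Gaussian point-spread-function sigma (um).
#' @param rng_seed integer seed recorded in every ground truth.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(pixel_size_um = 0.207,
                       frame_interval_s = 0.272,
                       n_frames = 150L,
                       image_shape = c(256L, 256L),
                       mean_cell_area_um2 = 28,
                       cell_area_sd_um2 = 6,
                       foci_per_cell_mean = 2,
                       focus_brightness_multiple = 100,
                       pool_molecules_per_cell = 2000,
                       molecular_brightness_counts = 5,
                       background_counts = 10,
                       psf_sigma_um = 0.15,
                       rng_seed = 1L) {
  cfg <- list(pixel_size_um = pixel_size_um,
              frame_interval_s = frame_interval_s,
              n_frames = as.integer(n_frames),
              image_shape = as.integer(image_shape),
              mean_cell_area_um2 = mean_cell_area_um2,
              cell_area_sd_um2 = cell_area_sd_um2,
              foci_per_cell_mean = foci_per_cell_mean,
              focus_brightness_multiple = focus_brightness_multiple,
              pool_molecules_per_cell = pool_molecules_per_cell,
              molecular_brightness_counts = molecular_brightness_counts,
              background_counts = background_counts,
              psf_sigma_um = psf_sigma_um,
              rng_seed = as.integer(rng_seed))
  pos <- c("pixel_size_um", "frame_interval_s", "n_frames",
           "mean_cell_area_um2", "focus_brightness_multiple",
           "molecular_brightness_counts", "psf_sigma_um")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      stop("sim_config: ", f, " must be a positive scalar")
    }
  }
  if (cfg$cell_area_sd_um2 < 0) stop("sim_config: cell_area_sd_um2 must be >= 0")
  if (cfg$foci_per_cell_mean < 0) stop("sim_config: foci_per_cell_mean must be >= 0")
  if (cfg$background_counts < 0) stop("sim_config: background_counts must be >= 0")
  if (cfg$pool_molecules_per_cell < 0) stop("sim_config: pool_molecules_per_cell must be >= 0")
  if (cfg$focus_brightness_multiple < 1) stop("sim_config: focus_brightness_multiple must be >= 1")
  if (length(cfg$image_shape) != 2 || any(cfg$image_shape < 16)) {
    stop("sim_config: image_shape must be two dimensions each >= 16")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Rasterise one pleiomorphic cell: a randomly deformed ellipse whose
# boundary radius is r(theta) = R * (1 + sum of low-order Fourier
# harmonics), evaluated in ellipse-scaled coordinates. The shape is
# star-shaped about its centre, so pixel membership reduces to a radial
# comparison. R is calibrated so the pixel area matches the target area
# within one pixel.
.rasterise_cell <- function(target_area_px, aspect, phi, harm_amp, harm_phase) {
  n_h <- length(harm_amp)
  radial <- function(theta) {
    d <- rep(1, length(theta))
    for (h in seq_len(n_h)) {
      d <- d + harm_amp[h] * cos((h + 1) * theta + harm_phase[h])
    }
    pmax(d, 0.2)
  }
  # initial R from the unperturbed ellipse area pi*R^2 (aspect preserves area)
  R <- sqrt(target_area_px / pi)
  for (iter in 1:8) {
    rmax <- R * max(aspect, 1 / aspect) * 1.6
    half <- ceiling(rmax)
    xs <- -half:half
    g <- expand.grid(y = xs, x = xs)
    # rotate by phi, scale axes by sqrt(aspect)
    xr <- cos(phi) * g$x + sin(phi) * g$y
    yr <- -sin(phi) * g$x + cos(phi) * g$y
    u <- xr / sqrt(aspect)
    v <- yr * sqrt(aspect)
    rr <- sqrt(u^2 + v^2)
    th <- atan2(v, u)
    inside <- rr <= R * radial(th)
    area <- sum(inside)
    if (abs(area - target_area_px) <= 1 || iter == 8) {
      m <- matrix(inside, nrow = length(xs))
      # trim to bounding box
      rws <- range(which(rowSums(m) > 0)); cls <- range(which(colSums(m) > 0))
      return(list(mask = m[rws[1]:rws[2], cls[1]:cls[2], drop = FALSE],
                  area_px = area))
    }
    R <- R * sqrt(target_area_px / max(area, 1))
  }
}

#' Generate a field of synthetic pleiomorphic cells
#'
#' Places non-overlapping, irregularly shaped cells (Fourier-perturbed
#' ellipses) in an image and records the ground truth: per-cell pixel-exact
#' area, the number and sub-pixel centroids of simulated fluorescence foci
#' (Poisson-distributed per cell, placed uniformly inside the cell with a
#' minimum mutual separation of one spot diameter so that counts refer to
#' optically resolvable spots).
#'
#' If the field cannot hold all requested cells, as many as fit are placed
#' and a warning reports the shortfall; a field that cannot hold a single
#' requested cell is an error.
#'
#' @param config a \code{\link{sim_config}}.
#' @param n_cells number of cells to place (>= 0).
#' @param seed optional integer overriding \code{config$rng_seed}.
#' @return list with \code{labels} (integer matrix), \code{truth}
#'   (data frame: cell, area_um2, n_foci), \code{foci} (data frame: cell,
#'   x_um, y_um, row, col) and \code{config}.
#' @export
make_cell_geometry <- function(config, n_cells, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), n_cells >= 0)
  seed <- if (is.null(seed)) config$rng_seed else as.integer(seed)
  set.seed(seed)
  p <- config$pixel_size_um
  ny <- config$image_shape[1]; nx <- config$image_shape[2]
  labels <- matrix(0L, ny, nx)
  margin <- ceiling(3 * config$psf_sigma_um / p) + 2L
  truth <- data.frame(cell = integer(0), area_um2 = numeric(0),
                      n_foci = integer(0))
  foci <- data.frame(cell = integer(0), x_um = numeric(0), y_um = numeric(0),
                     row = integer(0), col = integer(0))
  if (n_cells == 0) {
    return(list(labels = labels, truth = truth, foci = foci, config = config,
                seed = seed))
  }
  occupied <- matrix(FALSE, ny, nx)
  placed <- 0L
  min_sep_px <- 0.75 / p  # resolvable-focus separation: one spot diameter
  for (ci in seq_len(n_cells)) {
    target_um2 <- max(p^2, stats::rnorm(1, config$mean_cell_area_um2,
                                        config$cell_area_sd_um2))
    cell <- .rasterise_cell(target_um2 / p^2,
                            aspect = stats::runif(1, 1, 2.2),
                            phi = stats::runif(1, 0, pi),
                            harm_amp = stats::rnorm(4, 0, 0.06),
                            harm_phase = stats::runif(4, 0, 2 * pi))
    mh <- nrow(cell$mask); mw <- ncol(cell$mask)
    ok <- FALSE
    for (try in 1:60) {
      if (ny - mh - 2 * margin < 0 || nx - mw - 2 * margin < 0) break
      r0 <- sample.int(ny - mh - 2 * margin + 1L, 1) + margin - 1L
      c0 <- sample.int(nx - mw - 2 * margin + 1L, 1) + margin - 1L
      sub <- occupied[(r0 + 1):(r0 + mh), (c0 + 1):(c0 + mw)]
      if (!any(sub & cell$mask)) { ok <- TRUE; break }
    }
    if (!ok) next
    placed <- placed + 1L
    idx <- which(cell$mask)
    rows <- (idx - 1L) %% mh + 1L + r0
    cols <- (idx - 1L) %/% mh + 1L + c0
    labels[cbind(rows, cols)] <- placed
    # 1-px exclusion halo keeps neighbouring cells separable
    occupied[(max(1, r0)):(min(ny, r0 + mh + 1)),
             (max(1, c0)):(min(nx, c0 + mw + 1))] <- TRUE
    nf <- stats::rpois(1, config$foci_per_cell_mean)
    frows <- integer(0); fcols <- integer(0)
    for (k in seq_len(nf)) {
      for (try in 1:40) {
        j <- sample(length(idx), 1)
        rr <- rows[j]; cc <- cols[j]
        if (length(frows) == 0 ||
            all((frows - rr)^2 + (fcols - cc)^2 >= min_sep_px^2)) {
          frows <- c(frows, rr); fcols <- c(fcols, cc)
          break
        }
      }
    }
    nf <- length(frows)
    truth <- rbind(truth, data.frame(cell = placed,
                                     area_um2 = cell$area_px * p^2,
                                     n_foci = nf))
    if (nf > 0) {
      jit <- matrix(stats::runif(2 * nf, -0.5, 0.5), ncol = 2)
      foci <- rbind(foci, data.frame(
        cell = placed,
        x_um = (fcols - 1 + jit[, 1]) * p,
        y_um = (frows - 1 + jit[, 2]) * p,
        row = frows, col = fcols))
    }
  }
  if (placed == 0L) stop("field too crowded: no cell could be placed")
  if (placed < n_cells) {
    warning(sprintf("field too crowded: placed %d of %d cells", placed, n_cells))
  }
  list(labels = labels, truth = truth, foci = foci, config = config,
       seed = seed)
}

# Render one noiseless frame: background + PSF-blurred point sources.
# Sources are binned to their nearest pixel and convolved with a normalised
# truncated Gaussian, so the total photon count is conserved exactly as long
# as sources keep a kernel radius away from the border (the geometry
# generator enforces this margin).
.render_frame <- function(rows, cols, weights, config) {
  ny <- config$image_shape[1]; nx <- config$image_shape[2]
  img <- matrix(0, ny, nx)
  if (length(rows)) {
    keep <- rows >= 1 & rows <= ny & cols >= 1 & cols <= nx
    acc <- rowsum(weights[keep], group = (cols[keep] - 1L) * ny + rows[keep])
    img[as.integer(rownames(acc))] <- acc[, 1]
    img <- conv2_sep(img, gaussian_kernel_1d(config$psf_sigma_um /
                                               config$pixel_size_um),
                     boundary = "zero")
  }
  img + config$background_counts
}

#' Simulate a wide-field fluorescence time-lapse
#'
#' Renders the imaging model the downstream analyses assume: each frame is a
#' Poisson draw of background + PSF-blurred point sources. Pool molecules
#' perform Brownian steps of per-axis variance \code{2 D dt}, reflected at
#' their cell boundary; foci are immobile point sources of
#' \code{focus_brightness_multiple} molecule-equivalents.
#'
#' @param geometry output of \code{\link{make_cell_geometry}}.
#' @param config a \code{\link{sim_config}}.
#' @param n_frames number of frames (default \code{config$n_frames}).
#' @param pool_D_um2_s diffusion coefficient of pool molecules (um^2/s).
#' @param noise if \code{FALSE}, return the noiseless expected image
#'   (photon-conservation checks).
#' @param seed optional integer overriding \code{config$rng_seed}.
#' @return list with \code{stack} (an \code{\link{image_stack}}),
#'   \code{truth} (the geometry truth augmented with intensity fractions),
#'   and \code{config}.
#' @export
simulate_timelapse <- function(geometry, config = geometry$config,
                               n_frames = config$n_frames,
                               pool_D_um2_s = 1.0, noise = TRUE,
                               seed = NULL) {
  stopifnot(!is.null(geometry$labels))
  seed <- if (is.null(seed)) config$rng_seed else as.integer(seed)
  set.seed(seed)
  p <- config$pixel_size_um
  labels <- geometry$labels
  ny <- nrow(labels); nx <- ncol(labels)
  step_sd_px <- sqrt(2 * pool_D_um2_s * config$frame_interval_s) / p
  cell_ids <- if (nrow(geometry$truth)) geometry$truth$cell else integer(0)
  # expected diffusion step vs cell extent: warn on undersampling
  if (length(cell_ids)) {
    diam_px <- 2 * sqrt(max(geometry$truth$area_um2) / pi) / p
    if (step_sd_px > diam_px) {
      warning("diffusion step exceeds cell diameter per frame (undersampled motion)")
    }
  }
  # initial molecule positions: uniform over each cell's pixels
  mol_row <- numeric(0); mol_col <- numeric(0); mol_cell <- integer(0)
  for (ci in cell_ids) {
    idx <- which(labels == ci)
    n_mol <- config$pool_molecules_per_cell
    if (n_mol == 0 || length(idx) == 0) next
    j <- sample(length(idx), n_mol, replace = TRUE)
    mol_row <- c(mol_row, (idx[j] - 1L) %% ny + 1L + stats::runif(n_mol, -0.5, 0.5))
    mol_col <- c(mol_col, (idx[j] - 1L) %/% ny + 1L + stats::runif(n_mol, -0.5, 0.5))
    mol_cell <- c(mol_cell, rep(ci, n_mol))
  }
  eps <- config$molecular_brightness_counts
  f_w <- config$focus_brightness_multiple * eps
  frames <- array(0, c(ny, nx, n_frames))
  inside <- function(r, c, id) {
    ri <- pmax(1L, pmin(ny, round(r))); ci <- pmax(1L, pmin(nx, round(c)))
    labels[cbind(ri, ci)] == id
  }
  for (t in seq_len(n_frames)) {
    if (t > 1 && length(mol_row)) {
      pr <- mol_row + stats::rnorm(length(mol_row), 0, step_sd_px)
      pc <- mol_col + stats::rnorm(length(mol_col), 0, step_sd_px)
      ok <- inside(pr, pc, mol_cell)
      # reflect rejected steps back across the current position; if the
      # mirrored point is also outside, the molecule stays put this frame
      mr <- 2 * mol_row - pr; mc <- 2 * mol_col - pc
      ok2 <- !ok & inside(mr, mc, mol_cell)
      mol_row <- ifelse(ok, pr, ifelse(ok2, mr, mol_row))
      mol_col <- ifelse(ok, pc, ifelse(ok2, mc, mol_col))
    }
    rows <- c(round(mol_row), geometry$foci$row)
    cols <- c(round(mol_col), geometry$foci$col)
    w <- c(rep(eps, length(mol_row)), rep(f_w, nrow(geometry$foci)))
    expected <- .render_frame(rows, cols, w, config)
    frames[, , t] <- if (noise) {
      matrix(stats::rpois(ny * nx, expected), ny, nx)
    } else expected
  }
  truth <- geometry$truth
  if (nrow(truth)) {
    pool_photons <- config$pool_molecules_per_cell * eps
    foci_photons <- truth$n_foci * f_w
    truth$focus_intensity_fraction <-
      ifelse(pool_photons + foci_photons > 0,
             foci_photons / (pool_photons + foci_photons), 0)
  }
  list(stack = image_stack(frames, p, config$frame_interval_s),
       truth = truth, foci = geometry$foci, config = config, seed = seed,
       pool_D_um2_s = pool_D_um2_s)
}

#' Simulate FRAP traces with known kinetics
#'
#' Trace-level simulation of fluorescence recovery after photobleaching:
#' \code{n_prebleach} frames at unity (optionally decaying by a slow
#' acquisition-bleaching exponential), then
#' \code{F(t) = F_inf - sum_i a_i exp(-k_i t)} with t = 0 at the first
#' post-bleach frame, plus i.i.d. Gaussian noise. The bleach depth is
#' \code{sum(amplitudes) / (1 - immobile_fraction)}: amplitudes are the
#' recovering (mobile) part and the immobile fraction stays bleached.
#'
#' @param k_values recovery rate constants (s^-1), all > 0.
#' @param amplitudes recovery amplitudes, one per rate, all >= 0.
#' @param immobile_fraction fraction of the bleached signal that never
#'   recovers (0..1).
#' @param noise_sd Gaussian noise standard deviation on the normalized scale.
#' @param n_traces number of traces.
#' @param config a \code{\link{sim_config}} (frame interval, n_frames).
#' @param n_prebleach pre-bleach frames (default 50).
#' @param acq_bleach_rate acquisition-bleaching rate (s^-1) applied to the
#'   raw trace envelope; 0 disables it.
#' @param raw_scale,background constant factors to convert the normalized
#'   model into raw-count traces (I_raw, I_b) so that the normalization
#'   stage can be exercised; the emitted normalized trace is unaffected.
#' @param seed optional integer overriding \code{config$rng_seed}.
#' @return list with \code{traces} (list of \code{frap_trace}) and
#'   \code{truth}.
#' @export
simulate_frap_traces <- function(k_values, amplitudes, immobile_fraction = 0,
                                 noise_sd = 0, n_traces = 1,
                                 config = sim_config(),
                                 n_prebleach = 50L,
                                 acq_bleach_rate = 0,
                                 raw_scale = 1000, background = 100,
                                 seed = NULL) {
  if (any(k_values <= 0)) stop("k_values must be > 0")
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0")
  if (length(k_values) != length(amplitudes)) {
    stop("k_values and amplitudes must have the same length")
  }
  if (immobile_fraction < 0 || immobile_fraction >= 1) {
    stop("immobile_fraction must be in [0, 1)")
  }
  seed <- if (is.null(seed)) config$rng_seed else as.integer(seed)
  set.seed(seed)
  dt <- config$frame_interval_s
  n <- config$n_frames
  n_pre <- as.integer(n_prebleach)
  stopifnot(n > n_pre + 10)
  depth <- sum(amplitudes) / (1 - immobile_fraction)
  if (depth > 1 + 1e-9) stop("bleach depth exceeds 1: reduce amplitudes")
  t_abs <- (seq_len(n) - 1) * dt
  t_post <- t_abs[(n_pre + 1):n] - t_abs[n_pre + 1]
  plateau <- 1 - depth + sum(amplitudes)
  model <- c(rep(1, n_pre),
             plateau - colSums(amplitudes * exp(-outer(k_values, t_post))))
  envelope <- exp(-acq_bleach_rate * t_abs)
  traces <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    noisy <- model + stats::rnorm(n, 0, noise_sd)
    I_raw <- noisy * envelope * raw_scale + background
    traces[[i]] <- list(t = t_abs, I_raw = I_raw,
                        I_b = rep(background, n),
                        I_norm = noisy, n_prebleach = n_pre,
                        bleach_area_um2 = 3.72)
    class(traces[[i]]) <- "frap_trace"
  }
  list(traces = traces,
       truth = list(k = k_values, amplitudes = amplitudes,
                    immobile_fraction = immobile_fraction,
                    mobile_fraction = 1 - immobile_fraction,
                    bleach_depth = depth, plateau = plateau,
                    slow_fraction = if (length(amplitudes) > 1) {
                      amplitudes[which.min(k_values)] / sum(amplitudes)
                    } else NA_real_,
                    noise_sd = noise_sd, seed = seed))
}

#' Simulate a photon-counting stack for number-and-brightness analysis
#'
#' Fast-diffusion-limit fluctuation model: in every frame each pixel holds
#' \code{Poisson(n_true)} molecules and the detector records
#' \code{Poisson(occupancy * epsilon_true + background)} photons, frames
#' independent. With zero background the apparent brightness (variance over
#' mean) is \code{1 + epsilon_true}.
#'
#' @param n_true mean molecules per pixel: scalar or matrix matching
#'   \code{config$image_shape}.
#' @param epsilon_true molecular brightness (counts/molecule/frame).
#' @param n_frames frames (>= 2).
#' @param config a \code{\link{sim_config}} (image shape, background,
#'   calibration).
#' @param background photons/px/frame (default \code{config$background_counts}).
#' @param seed optional integer overriding \code{config$rng_seed}.
#' @return list with \code{stack} and \code{truth}.
#' @export
simulate_nandb_stack <- function(n_true, epsilon_true, n_frames = 100L,
                                 config = sim_config(),
                                 background = config$background_counts,
                                 seed = NULL) {
  if (any(n_true < 0) || epsilon_true < 0) stop("n_true and epsilon_true must be >= 0")
  n_frames <- as.integer(n_frames)
  if (n_frames < 2) stop("n_frames must be >= 2 (variance undefined otherwise)")
  seed <- if (is.null(seed)) config$rng_seed else as.integer(seed)
  set.seed(seed)
  ny <- config$image_shape[1]; nx <- config$image_shape[2]
  n_map <- if (is.matrix(n_true)) n_true else matrix(n_true, ny, nx)
  stopifnot(nrow(n_map) == ny, ncol(n_map) == nx)
  npx <- ny * nx
  frames <- array(0, c(ny, nx, n_frames))
  for (t in seq_len(n_frames)) {
    occ <- stats::rpois(npx, as.numeric(n_map))
    frames[, , t] <- matrix(stats::rpois(npx, occ * epsilon_true + background),
                            ny, nx)
  }
  list(stack = image_stack(frames, config$pixel_size_um,
                           config$frame_interval_s),
       truth = list(n_true = n_map, epsilon_true = epsilon_true,
                    background = background, seed = seed))
}
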