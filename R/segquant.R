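# Cell segmentation, focus detection and per-cell quantification of
# wide-field fluorescence images, mirroring a parameterised automated
# workflow: smoothing, rolling-ball background subtraction, thresholding,
# seeded watershed splitting, then band-pass spot detection with a manual
# quality threshold.

#' Maximum-intensity projection
#'
#' Pixelwise maximum over a range of slices of a stack (for z-stacks the
#' third axis holds slices).
#'
#' @param stack an \code{\link{image_stack}}.
#' @param slice_range integer indices of the slices to project (1-based).
#' @return a numeric matrix.
#' @export
max_project <- function(stack, slice_range = seq_len(dim(stack)[3])) {
  d <- dim(stack)
  if (length(slice_range) == 0) stop("empty slice range")
  if (any(slice_range < 1) || any(slice_range > d[3])) {
    stop("slice_range outside stack depth")
  }
  a <- unclass(stack)[, , slice_range, drop = FALSE]
  apply(a, c(1, 2), max)
}

#' Segment cells in a calibrated fluorescence image
#'
#' Pipeline: Gaussian smoothing (sigma = smooth_width / 2, converted by the
#' pixel size), rolling-ball background subtraction with the stated sphere
#' diameter, Otsu thresholding of the corrected image, connected-component
#' labelling, and (optionally) seeded watershed splitting using local maxima
#' found at the cell-seed scale. Labels touching the image border are
#' retained.
#'
#' @param image numeric matrix, or an \code{\link{image_stack}} whose first
#'   frame is used.
#' @param pixel_size_um pixel size (um); taken from the stack if supplied.
#' @param smooth_width_um Gaussian smoothing width (um), default 1.5.
#' @param background_sphere_um rolling-ball diameter (um), default 1.
#' @param seed_diameter_um expected cell-seed diameter (um), default 2; use
#'   4 for enlarged (replication-arrested) cells.
#' @param split_by_seeds split touching cells at seed points (default TRUE).
#' @param min_area_um2 discard labels smaller than this area (noise specks).
#' @return integer label matrix with attribute \code{pixel_size_um}.
#' @export
segment_cells <- function(image, pixel_size_um = attr(image, "pixel_size_um"),
                          smooth_width_um = 1.5, background_sphere_um = 1.0,
                          seed_diameter_um = 2.0, split_by_seeds = TRUE,
                          min_area_um2 = 2) {
  if (inherits(image, "image_stack")) image <- get_frame(image, 1)
  if (is.null(pixel_size_um) || !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("calibrated image required: supply pixel_size_um")
  }
  stopifnot(smooth_width_um > 0, background_sphere_um > 0, seed_diameter_um > 0)
  p <- pixel_size_um
  sm <- gaussian_smooth(image, (smooth_width_um / 2) / p)
  # The background ball is smaller than a cell, so the classic rolling-ball
  # residual (image minus opening) would remove the cell bodies themselves.
  # The ball is instead used to strip structure smaller than the sphere --
  # the morphological opening -- before thresholding: bright sub-sphere
  # specks are treated as background for cell detection.
  corr <- gray_morph(gray_morph(sm, background_sphere_um / (2 * p), "erode"),
                     background_sphere_um / (2 * p), "dilate")
  thr <- otsu_threshold(corr)
  mask <- corr > thr
  labels <- label_components(mask)
  if (split_by_seeds && max(labels) > 0) {
    seed_sigma <- (seed_diameter_um / 2) / p
    seed_img <- gaussian_smooth(corr, seed_sigma)
    # distinct seeds must be at least one seed diameter apart
    mx <- local_maxima(seed_img, radius_px = seed_diameter_um / p,
                       min_value = thr)
    if (nrow(mx) > 0) {
      seeds <- matrix(0L, nrow(image), ncol(image))
      seeds[mx] <- seq_len(nrow(mx))
      split <- watershed_seeded(seed_img, seeds, mask)
      # components that received no seed keep their original label
      split[split == 0 & mask] <- max(split) + labels[split == 0 & mask]
      labels <- split
    }
  }
  # drop specks and renumber consecutively
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes * p^2 >= min_area_um2)
  out <- matrix(0L, nrow(image), ncol(image))
  out[labels > 0 & labels %in% keep] <-
    match(labels[labels > 0 & labels %in% keep], keep)
  # Per-cell boundary refinement: the global threshold misplaces the edge of
  # cells whose interior brightness differs from the population, so each
  # cell is re-thresholded at the half-maximum between the background level
  # and its own interior level, within its own territory.
  out <- .refine_labels(op = corr, labels = out, pixel_size_um = p)
  attr(out, "pixel_size_um") <- p
  out
}

# Re-threshold each label at (background + interior)/2 inside a dilated
# bounding box, claiming only pixels not already owned by another label.
.refine_labels <- function(op, labels, pixel_size_um, grow_px = 6L) {
  n_lab <- max(labels)
  if (n_lab == 0) return(labels)
  bg <- stats::median(op[labels == 0])
  ny <- nrow(op); nx <- ncol(op)
  out <- matrix(0L, ny, nx)
  for (ci in seq_len(n_lab)) {
    comp <- labels == ci
    if (!any(comp)) next
    rs <- range(which(rowSums(comp) > 0)); cs <- range(which(colSums(comp) > 0))
    r0 <- max(1, rs[1] - grow_px); r1 <- min(ny, rs[2] + grow_px)
    c0 <- max(1, cs[1] - grow_px); c1 <- min(nx, cs[2] + grow_px)
    sub_op <- op[r0:r1, c0:c1]
    sub_comp <- comp[r0:r1, c0:c1]
    sub_lab <- labels[r0:r1, c0:c1]
    interior <- stats::quantile(sub_op[sub_comp], 0.75, names = FALSE)
    thr_i <- (bg + interior) / 2
    territory <- sub_lab == ci | sub_lab == 0   # never annex another cell
    ref <- territory & sub_op > thr_i
    rl <- label_components(ref)
    core <- setdiff(unique(rl[sub_comp & ref]), 0L)
    if (length(core) == 0) { out[comp] <- ci; next }
    sel <- matrix(FALSE, ny, nx)
    sel[r0:r1, c0:c1] <- rl %in% core
    out[sel & out == 0] <- ci
  }
  out
}

#' Detect fluorescence foci
#'
#' Band-pass (scale-normalised difference-of-Gaussians at the spot scale)
#' local-maximum detection. The quality of a focus is the band-pass response
#' at its maximum; maxima below the quality threshold are discarded. There
#' is deliberately no automatic threshold: the workflow being emulated uses
#' a manually chosen quality cutoff, so \code{quality_threshold} is a
#' required argument (see \code{\link{calibrate_quality_threshold}}).
#'
#' @param image numeric matrix (no background subtraction is applied).
#' @param labels integer label matrix from \code{\link{segment_cells}};
#'   foci outside every cell get \code{cell_id = 0}.
#' @param pixel_size_um pixel size (um).
#' @param spot_diameter_um estimated focus diameter (um), default 0.75.
#' @param quality_threshold minimum detector response; mandatory.
#' @return data frame of focus records: \code{cell_id, x_um, y_um, row, col,
#'   diameter_um, intensity, quality}.
#' @export
detect_foci <- function(image, labels = NULL,
                        pixel_size_um = attr(image, "pixel_size_um"),
                        spot_diameter_um = 0.75, quality_threshold = NULL) {
  if (inherits(image, "image_stack")) image <- get_frame(image, 1)
  if (is.null(quality_threshold)) {
    stop("manual quality threshold required: supply quality_threshold")
  }
  if (is.null(pixel_size_um)) {
    if (!is.null(labels)) pixel_size_um <- attr(labels, "pixel_size_um")
    if (is.null(pixel_size_um)) stop("calibrated image required: supply pixel_size_um")
  }
  p <- pixel_size_um
  d_px <- spot_diameter_um / p
  resp <- dog_response(image, d_px)
  mx <- local_maxima(resp, radius_px = max(1, d_px / 2),
                     min_value = quality_threshold)
  empty <- data.frame(cell_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), row = integer(0), col = integer(0),
                      diameter_um = numeric(0), intensity = numeric(0),
                      quality = numeric(0))
  if (nrow(mx) == 0) return(empty)
  off <- disc_offsets(d_px / 2)
  off_search <- disc_offsets(max(1, d_px))
  intensity <- vapply(seq_len(nrow(mx)), function(i) {
    rr <- mx[i, 1] + off$dy; cc <- mx[i, 2] + off$dx
    keep <- rr >= 1 & rr <= nrow(image) & cc >= 1 & cc <= ncol(image)
    sum(image[cbind(rr[keep], cc[keep])])
  }, numeric(1))
  cell_id <- if (is.null(labels)) rep(0L, nrow(mx)) else labels[mx]
  if (!is.null(labels)) {
    # a focus peaking just outside the segmented boundary still belongs to
    # the adjacent cell: search a spot radius around unassigned peaks
    for (i in which(cell_id == 0)) {
      rr <- mx[i, 1] + off_search$dy; cc <- mx[i, 2] + off_search$dx
      keep <- rr >= 1 & rr <= nrow(image) & cc >= 1 & cc <= ncol(image)
      nb <- labels[cbind(rr[keep], cc[keep])]
      nb <- nb[nb > 0]
      if (length(nb)) cell_id[i] <- as.integer(names(which.max(table(nb))))
    }
  }
  data.frame(cell_id = as.integer(cell_id),
             x_um = (mx[, 2] - 1) * p, y_um = (mx[, 1] - 1) * p,
             row = mx[, 1], col = mx[, 2],
             diameter_um = spot_diameter_um,
             intensity = intensity,
             quality = resp[mx])
}

#' Calibrate the focus quality threshold on ground truth
#'
#' Runs thresholdless detection on a field with known focus positions and
#' places the cutoff at the geometric midpoint between the weakest true-spot
#' responses and the strongest spurious responses. Intended for calibrating
#' on a held-out synthetic field before analysing the field of interest,
#' mimicking the manual threshold choice of the emulated workflow.
#'
#' @param image numeric matrix of the calibration field.
#' @param truth_foci data frame with \code{row}, \code{col} of true foci.
#' @param pixel_size_um pixel size (um).
#' @param spot_diameter_um focus diameter (um).
#' @param match_radius_um maximum distance between a detection and a true
#'   focus to count as a match.
#' @return numeric quality threshold.
#' @export
calibrate_quality_threshold <- function(image, truth_foci,
                                        pixel_size_um = attr(image, "pixel_size_um"),
                                        spot_diameter_um = 0.75,
                                        match_radius_um = 0.5) {
  if (inherits(image, "image_stack")) image <- get_frame(image, 1)
  stopifnot(nrow(truth_foci) > 0)
  p <- pixel_size_um
  cand <- detect_foci(image, labels = NULL, pixel_size_um = p,
                      spot_diameter_um = spot_diameter_um,
                      quality_threshold = -Inf)
  d2 <- outer(cand$row, truth_foci$row, "-")^2 +
        outer(cand$col, truth_foci$col, "-")^2
  matched <- apply(d2, 1, min) <= (match_radius_um / p)^2
  q_true <- cand$quality[matched]
  q_false <- cand$quality[!matched & cand$quality > 0]
  if (length(q_true) == 0) stop("calibration failed: no true focus detected")
  lo <- stats::quantile(q_true, 0.05, names = FALSE)
  hi <- if (length(q_false)) stats::quantile(q_false, 0.95, names = FALSE) else lo / 10
  sqrt(pmax(lo, 1e-12) * pmax(min(hi, lo), 1e-12))
}

#' Per-cell quantification
#'
#' For each labelled cell: surface area, total fluorescence intensity,
#' number of detected foci and their total intensity (each focus summed over
#' a disc of the spot diameter, clipped to the cell). Foci with
#' \code{cell_id = 0} (outside all cells) are excluded from per-cell sums.
#'
#' @param image numeric matrix.
#' @param labels integer label matrix.
#' @param foci data frame from \code{\link{detect_foci}}.
#' @param pixel_size_um pixel size (um).
#' @return data frame of cell records: \code{cell_id, surface_um2,
#'   total_intensity, n_foci, foci_total_intensity}.
#' @export
per_cell_metrics <- function(image, labels, foci,
                             pixel_size_um = attr(labels, "pixel_size_um")) {
  if (inherits(image, "image_stack")) image <- get_frame(image, 1)
  p <- pixel_size_um
  stopifnot(!is.null(p))
  n_lab <- max(labels)
  if (n_lab == 0) {
    return(data.frame(cell_id = integer(0), surface_um2 = numeric(0),
                      total_intensity = numeric(0), n_foci = integer(0),
                      foci_total_intensity = numeric(0)))
  }
  areas <- tabulate(labels[labels > 0], nbins = n_lab) * p^2
  tot <- vapply(seq_len(n_lab), function(k) sum(image[labels == k]), numeric(1))
  nf <- tabulate(foci$cell_id[foci$cell_id > 0], nbins = n_lab)
  fint <- numeric(n_lab)
  if (nrow(foci) > 0) {
    for (i in which(foci$cell_id > 0)) {
      cid <- foci$cell_id[i]
      off <- disc_offsets(foci$diameter_um[i] / (2 * p))
      rr <- foci$row[i] + off$dy; cc <- foci$col[i] + off$dx
      keep <- rr >= 1 & rr <= nrow(image) & cc >= 1 & cc <= ncol(image)
      px <- cbind(rr[keep], cc[keep])
      px <- px[labels[px] == cid, , drop = FALSE]   # clip to the cell
      fint[cid] <- fint[cid] + sum(image[px])
    }
  }
  data.frame(cell_id = seq_len(n_lab), surface_um2 = areas,
             total_intensity = tot, n_foci = nf,
             foci_total_intensity = pmin(fint, tot))
}

#' Population summary statistics
#'
#' All ratios are computed as totals over totals (not means of per-cell
#' ratios): average cell surface = total surface / n cells, mean foci per
#' cell = total foci / n cells, mean focus intensity = total focus intensity
#' / total focus count, fraction of intensity in foci = total focus
#' intensity / total cell intensity. The foci histogram covers 0..20
#' foci/cell, with counts above 20 clamped into the last class.
#'
#' @param cells data frame from \code{\link{per_cell_metrics}}.
#' @return list of class \code{population_summary}.
#' @export
population_summary <- function(cells) {
  if (nrow(cells) == 0) stop("population summary requires at least one cell")
  n <- nrow(cells)
  tot_surface <- sum(cells$surface_um2)
  tot_int <- sum(cells$total_intensity)
  tot_foci <- sum(cells$n_foci)
  tot_fint <- sum(cells$foci_total_intensity)
  h <- tabulate(pmin(cells$n_foci, 20L) + 1L, nbins = 21L)
  structure(list(
    n_cells = n,
    average_cell_surface = tot_surface / n,
    mean_intensity_per_cell = tot_int / n,
    mean_intensity_per_surface = tot_int / tot_surface,
    mean_foci_per_cell = tot_foci / n,
    mean_focus_intensity = if (tot_foci > 0) tot_fint / tot_foci else NA_real_,
    fraction_intensity_in_foci = if (tot_int > 0) tot_fint / tot_int else NA_real_,
    foci_count_histogram = stats::setNames(h, 0:20)
  ), class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("population of %d cells\n", x$n_cells))
  cat(sprintf("  average cell surface      %.2f um^2\n", x$average_cell_surface))
  cat(sprintf("  mean intensity per cell   %.4g\n", x$mean_intensity_per_cell))
  cat(sprintf("  mean intensity / surface  %.4g per um^2\n",
              x$mean_intensity_per_surface))
  cat(sprintf("  mean foci per cell        %.2f\n", x$mean_foci_per_cell))
  cat(sprintf("  mean focus intensity      %.4g\n", x$mean_focus_intensity))
  cat(sprintf("  intensity fraction in foci %.3f\n",
              x$fraction_intensity_in_foci))
  invisible(x)
}
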