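# Per-pixel number-and-brightness (N&B) fluctuation analysis of
# photon-counting image time-series. For a photon-counting detector the
# apparent brightness B = sigma^2/<I> of an immobile or empty pixel is 1
# (shot noise); mobile fluorophores add occupation-number fluctuations, so
# the molecular brightness is epsilon = B - 1 and the molecular number
# n = <I>/epsilon.

#' Per-pixel temporal moments of an image stack
#'
#' Temporal mean and population variance (divide by M, the
#' fluctuation-spectroscopy convention) of every pixel.
#'
#' @param stack an \code{\link{image_stack}} or 3-D array with >= 2 frames.
#' @return list with \code{mean_map} and \code{variance_map} matrices.
#' @export
pixel_moments <- function(stack) {
  a <- unclass(stack)
  stopifnot(length(dim(a)) == 3)
  if (dim(a)[3] < 2) stop("at least 2 frames are required for a variance")
  m <- apply(a, c(1, 2), mean)
  # two-pass population variance for numerical stability
  v <- apply(sweep(a, c(1, 2), m)^2, c(1, 2), mean)
  list(mean_map = m, variance_map = v)
}

#' Number-and-brightness maps
#'
#' From per-pixel temporal mean and variance:
#' apparent number \code{N = <I>^2/sigma^2}, apparent brightness
#' \code{B = sigma^2/<I>}, molecular number \code{n = <I>^2/(sigma^2 - <I>)}
#' and molecular brightness \code{epsilon = (sigma^2 - <I>)/<I>}
#' (photon-counting formulation: shot noise contributes exactly \code{<I>}
#' to the variance and there is no detector offset term). Pixels where the
#' variance does not exceed the shot-noise floor (\code{sigma^2 <= <I>}) or
#' where \code{<I> <= 0} carry no molecular signal; their molecular maps are
#' set to \code{NA} and excluded from \code{valid_mask}.
#'
#' @param mean_map,variance_map matrices from \code{\link{pixel_moments}}.
#' @param background optional constant background (counts/px/frame)
#'   subtracted from \code{<I>} before the molecular maps; off by default.
#' @return list of class \code{nb_map}: \code{mean_map, variance_map,
#'   apparent_number, apparent_brightness, molecular_number,
#'   molecular_brightness, valid_mask}.
#' @export
nb_maps <- function(mean_map, variance_map, background = 0) {
  stopifnot(all(dim(mean_map) == dim(variance_map)))
  m <- mean_map - background
  v <- variance_map
  pos <- m > 0
  N <- B <- n <- eps <- matrix(NA_real_, nrow(m), ncol(m))
  N[pos] <- m[pos]^2 / v[pos]
  B[pos] <- v[pos] / m[pos]
  valid <- pos & v > m
  n[valid] <- m[valid]^2 / (v[valid] - m[valid])
  eps[valid] <- (v[valid] - m[valid]) / m[valid]
  structure(list(mean_map = mean_map, variance_map = variance_map,
                 apparent_number = N, apparent_brightness = B,
                 molecular_number = n, molecular_brightness = eps,
                 valid_mask = valid, background = background),
            class = "nb_map")
}

#' ROI statistics of an N&B map
#'
#' Mean +/- SEM of molecular number and brightness over the valid pixels of
#' each ROI, plus the brightness normalized to a reference ROI (typically a
#' cytoplasmic region excluding foci). ROIs with fewer than 4 valid pixels
#' are flagged and excluded from the normalization.
#'
#' @param nbmap an \code{nb_map}.
#' @param rois integer label matrix of regions of interest.
#' @param reference_roi label of the reference ROI.
#' @return data frame: \code{roi_id, n_pixels, mean_n, sem_n, mean_eps,
#'   sem_eps, normalized_brightness, excluded}.
#' @export
roi_stats <- function(nbmap, rois, reference_roi) {
  stopifnot(inherits(nbmap, "nb_map"),
            all(dim(rois) == dim(nbmap$mean_map)))
  ids <- sort(unique(rois[rois > 0]))
  if (!reference_roi %in% ids) stop("reference ROI ", reference_roi, " not present")
  one <- function(id) {
    sel <- rois == id & nbmap$valid_mask
    np <- sum(sel)
    if (np < 4) {
      return(data.frame(roi_id = id, n_pixels = np, mean_n = NA_real_,
                        sem_n = NA_real_, mean_eps = NA_real_,
                        sem_eps = NA_real_, excluded = TRUE))
    }
    nn <- nbmap$molecular_number[sel]
    ee <- nbmap$molecular_brightness[sel]
    data.frame(roi_id = id, n_pixels = np,
               mean_n = mean(nn), sem_n = stats::sd(nn) / sqrt(np),
               mean_eps = mean(ee), sem_eps = stats::sd(ee) / sqrt(np),
               excluded = FALSE)
  }
  out <- do.call(rbind, lapply(ids, one))
  ref <- out$mean_eps[out$roi_id == reference_roi]
  if (is.na(ref)) stop("reference ROI has fewer than 4 valid pixels")
  out$normalized_brightness <- out$mean_eps / ref
  out
}

#' Screen a stack for sample drift
#'
#' Estimates the global shift between the averages of the first and last
#' quartiles of frames by 2-D cross-correlation (FFT phase peak) and fails
#' stacks whose shift exceeds \code{max_shift_px} — the automated analogue
#' of excluding visibly moving cells. Featureless stacks pass with shift 0
#' and a low-confidence flag.
#'
#' @param stack an \code{\link{image_stack}} (>= 2 frames).
#' @param max_shift_px maximum tolerated shift in pixels.
#' @return list: \code{pass}, \code{shift_px} (dy, dx), \code{shift_norm},
#'   \code{low_confidence}.
#' @export
motion_filter <- function(stack, max_shift_px = 1) {
  a <- unclass(stack)
  nt <- dim(a)[3]
  if (nt < 2) stop("at least 2 frames are required")
  q <- max(1L, nt %/% 4L)
  first <- apply(a[, , seq_len(q), drop = FALSE], c(1, 2), mean)
  last <- apply(a[, , (nt - q + 1):nt, drop = FALSE], c(1, 2), mean)
  f1 <- first - mean(first)
  f2 <- last - mean(last)
  denom <- sqrt(sum(f1^2) * sum(f2^2))
  if (denom < 1e-12 || stats::sd(first) < 1e-12) {
    return(list(pass = TRUE, shift_px = c(0, 0), shift_norm = 0,
                low_confidence = TRUE))
  }
  cc <- Re(stats::fft(stats::fft(f1) * Conj(stats::fft(f2)), inverse = TRUE))
  peak <- which.max(cc)
  ny <- nrow(f1); nx <- ncol(f1)
  dy <- (peak - 1) %% ny
  dx <- (peak - 1) %/% ny
  if (dy > ny / 2) dy <- dy - ny
  if (dx > nx / 2) dx <- dx - nx
  # confidence: correlation peak prominence
  r <- max(cc) / denom
  shift <- c(dy = -dy, dx = -dx)
  nrm <- sqrt(sum(shift^2))
  list(pass = nrm <= max_shift_px, shift_px = shift, shift_norm = nrm,
       low_confidence = r < 0.1)
}
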