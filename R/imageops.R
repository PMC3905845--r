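# Low-level image operations shared by segmentation, focus detection and the
# simulator. All operate on plain numeric matrices indexed [row, col]
# (row = y, col = x). Pure R, vectorised over pixel shifts; image sizes in
# this domain (<= 512 px per side) keep every operation well under a second.

#' Discrete Gaussian kernel
#'
#' One-dimensional normalised Gaussian kernel truncated at \code{3*sigma}.
#'
#' @param sigma standard deviation in pixels.
#' @return numeric vector of odd length summing to 1.
#' @keywords internal
gaussian_kernel_1d <- function(sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Shift a matrix by (dy, dx), padding with `fill`.
shift_matrix <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dy):min(nr, nr + dy)
  cs <- max(1, 1 + dx):min(nc, nc + dx)
  if (length(rs) == 0 || length(cs) == 0) return(out)
  out[rs, cs] <- m[rs - dy, cs - dx]
  out
}

#' Separable 2-D convolution
#'
#' Convolves a matrix with an outer product of two 1-D kernels.
#' \code{boundary = "replicate"} extends edge pixels (filtering),
#' \code{boundary = "zero"} pads with zeros (photon-conserving rendering,
#' provided sources stay a kernel radius away from the border).
#'
#' @keywords internal
conv2_sep <- function(m, k, boundary = c("replicate", "zero")) {
  boundary <- match.arg(boundary)
  r <- (length(k) - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  pad <- function(mm) {
    if (boundary == "zero") {
      out <- matrix(0, nr + 2 * r, nc + 2 * r)
      out[(r + 1):(r + nr), (r + 1):(r + nc)] <- mm
      out
    } else {
      ri <- c(rep(1L, r), seq_len(nr), rep(nr, r))
      ci <- c(rep(1L, r), seq_len(nc), rep(nc, r))
      mm[ri, ci]
    }
  }
  p <- pad(m)
  # rows then columns; kernel is symmetric in use so no flip needed
  tmp <- matrix(0, nr, ncol(p))
  for (i in seq_along(k)) {
    tmp <- tmp + k[i] * p[(i):(i + nr - 1L), , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (j in seq_along(k)) {
    out <- out + k[j] * tmp[, (j):(j + nc - 1L), drop = FALSE]
  }
  out
}

#' Gaussian smoothing of an image matrix
#' @param m numeric matrix.
#' @param sigma_px Gaussian sigma in pixels.
#' @keywords internal
gaussian_smooth <- function(m, sigma_px, boundary = "replicate") {
  conv2_sep(m, gaussian_kernel_1d(sigma_px), boundary = boundary)
}

# Integer offsets covering a disc of the given radius (pixels).
disc_offsets <- function(radius_px) {
  r <- max(0L, floor(radius_px + 1e-9))
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= radius_px^2 + 1e-9, , drop = FALSE]
}

# Grayscale erosion / dilation with a disc structuring element.
gray_morph <- function(m, radius_px, op = c("erode", "dilate")) {
  op <- match.arg(op)
  off <- disc_offsets(radius_px)
  fill <- if (op == "erode") Inf else -Inf
  acc <- matrix(if (op == "erode") Inf else -Inf, nrow(m), ncol(m))
  for (i in seq_len(nrow(off))) {
    s <- shift_matrix(m, off$dy[i], off$dx[i], fill = fill)
    acc <- if (op == "erode") pmin(acc, s) else pmax(acc, s)
  }
  acc
}

#' Rolling-ball background subtraction
#'
#' Morphological opening (erosion then dilation) with a disc whose diameter
#' matches the stated background sphere; the opening is the background
#' estimate and is subtracted from the image.
#'
#' @param m numeric matrix.
#' @param sphere_diameter_px ball diameter in pixels.
#' @return list with \code{corrected} and \code{background} matrices.
#' @keywords internal
rolling_ball <- function(m, sphere_diameter_px) {
  r <- sphere_diameter_px / 2
  bg <- gray_morph(gray_morph(m, r, "erode"), r, "dilate")
  list(corrected = m - bg, background = bg)
}

#' Otsu threshold
#'
#' Maximises between-class variance on a 256-bin histogram of the image
#' range. Returns a threshold on the image's own intensity scale, so the
#' resulting mask is invariant under uniform intensity scaling.
#'
#' @keywords internal
otsu_threshold <- function(m, n_bins = 256L) {
  v <- as.numeric(m)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(hi)  # flat image: nothing above threshold
  h <- tabulate(pmin(n_bins, 1L + floor((v - lo) / (hi - lo) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- lo + (seq_len(n_bins) - 0.5) / n_bins * (hi - lo)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu0)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' Connected-component labelling (4-connectivity)
#'
#' Iterative minimum-label propagation: each foreground pixel starts with its
#' linear index and repeatedly takes the minimum over its 4-neighbourhood
#' until stable, then labels are renumbered 1..K in raster order.
#'
#' @param mask logical matrix.
#' @return integer matrix, 0 = background.
#' @keywords internal
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0, nr, nc)
  lab[mask] <- which(mask)
  nz <- function(m) { m[m == 0] <- Inf; m }  # background does not propagate
  repeat {
    nb <- pmin(nz(shift_matrix(lab, 1, 0, Inf)),
               nz(shift_matrix(lab, -1, 0, Inf)),
               nz(shift_matrix(lab, 0, 1, Inf)),
               nz(shift_matrix(lab, 0, -1, Inf)))
    new <- lab
    upd <- mask & nb < lab
    new[upd] <- nb[upd]
    if (all(new == lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, nr, nc)
  out[lab > 0] <- match(lab[lab > 0], ids)
  out
}

#' Local maxima of an image
#'
#' Pixels equal to the maximum of their \code{(2r+1)^2} neighbourhood and
#' strictly above \code{min_value}. Plateaus keep their first pixel in raster
#' order.
#'
#' @keywords internal
local_maxima <- function(m, radius_px = 1, min_value = -Inf) {
  dil <- gray_morph(m, max(1, radius_px), "dilate")
  cand <- which(m >= dil & m > min_value)
  if (length(cand) == 0) return(cbind(row = integer(0), col = integer(0)))
  # collapse plateaus: keep one representative per connected plateau
  mask <- matrix(FALSE, nrow(m), ncol(m)); mask[cand] <- TRUE
  lab <- label_components(mask)
  reps <- vapply(seq_len(max(lab)), function(k) which(lab == k)[1], integer(1))
  cbind(row = (reps - 1L) %% nrow(m) + 1L,
        col = (reps - 1L) %/% nrow(m) + 1L)
}

#' Seeded watershed by ordered label propagation
#'
#' Assigns every pixel of \code{mask} to one of the seed labels by flooding
#' from the seeds in descending intensity order: at each quantised intensity
#' level, labels grow into unlabelled mask pixels whose intensity is at or
#' above the level. This splits touching objects along intensity valleys.
#'
#' @param intensity numeric matrix guiding the flood (higher = object core).
#' @param seeds integer matrix of seed labels (0 elsewhere).
#' @param mask logical matrix restricting the flood.
#' @param n_levels number of quantised flooding levels.
#' @return integer label matrix.
#' @keywords internal
watershed_seeded <- function(intensity, seeds, mask, n_levels = 64L) {
  lab <- seeds
  lab[!mask] <- 0L
  vals <- intensity[mask]
  if (length(vals) == 0 || max(seeds) == 0) return(lab)
  levels <- rev(seq(min(vals), max(vals), length.out = n_levels))
  for (lev in levels) {
    active <- mask & intensity >= lev
    repeat {
      nb <- pmax(shift_matrix(lab, 1, 0), shift_matrix(lab, -1, 0),
                 shift_matrix(lab, 0, 1), shift_matrix(lab, 0, -1))
      upd <- active & lab == 0 & nb > 0
      if (!any(upd)) break
      lab[upd] <- nb[upd]
    }
  }
  # mask pixels unreachable at any level (below the lowest seed basin)
  repeat {
    nb <- pmax(shift_matrix(lab, 1, 0), shift_matrix(lab, -1, 0),
               shift_matrix(lab, 0, 1), shift_matrix(lab, 0, -1))
    upd <- mask & lab == 0 & nb > 0
    if (!any(upd)) break
    lab[upd] <- nb[upd]
  }
  lab
}

#' Scale-normalised difference-of-Gaussians band-pass
#'
#' Blob detector response tuned to spots of the given diameter: the image is
#' smoothed at \code{sigma} and \code{1.6 sigma} (the classic DoG
#' approximation to the Laplacian of Gaussian) and the difference is scaled
#' by \code{sigma^2} so the response peaks for blobs of the target size.
#'
#' @param m numeric matrix.
#' @param spot_diameter_px expected blob diameter in pixels.
#' @keywords internal
dog_response <- function(m, spot_diameter_px) {
  sigma <- spot_diameter_px / (2 * sqrt(2))
  sigma <- max(sigma, 0.5)
  g1 <- gaussian_smooth(m, sigma)
  g2 <- gaussian_smooth(m, 1.6 * sigma)
  (g1 - g2) * sigma^2
}
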