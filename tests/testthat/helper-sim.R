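# Shared fixture builders: small, fast synthetic inputs built in code.

# A small field configuration for segmentation tests.
small_field_config <- function(...) {
  sim_config(image_shape = c(200, 200), ...)
}

# Two Gaussian "cells" on a flat baseline; centres/radii in pixels.
two_blob_image <- function(ny = 96, nx = 128, centres, radius = 24,
                           amplitude = 100, baseline = 5) {
  g <- expand.grid(y = seq_len(ny), x = seq_len(nx))
  img <- matrix(baseline, ny, nx)
  for (ct in centres) {
    img <- img + matrix(amplitude * exp(-((g$y - ct[1])^2 + (g$x - ct[2])^2) /
                                          (2 * (radius / 2)^2)), ny, nx)
  }
  img
}

# Match detected foci to true focus positions within a pixel radius;
# returns counts for precision/recall.
match_foci <- function(detected, truth, radius_px) {
  if (nrow(detected) == 0 || nrow(truth) == 0) {
    return(list(tp = 0L, fp = nrow(detected), fn = nrow(truth)))
  }
  d2 <- outer(detected$row, truth$row, "-")^2 +
        outer(detected$col, truth$col, "-")^2
  used <- rep(FALSE, nrow(truth))
  tp <- 0L
  for (i in order(apply(d2, 1, min))) {
    j <- which.min(ifelse(used, Inf, d2[i, ]))
    if (is.finite(d2[i, j]) && d2[i, j] <= radius_px^2 && !used[j]) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fp = nrow(detected) - tp, fn = nrow(truth) - tp)
}
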