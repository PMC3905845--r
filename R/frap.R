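# FRAP normalization and kinetic fitting: reference-trace normalization
# from the pre-bleach frames, mono-/bi-exponential recovery fits with 95%
# confidence intervals, recovery half-times and apparent diffusion
# coefficients.

#' Construct a FRAP trace object
#' @keywords internal
new_frap_trace <- function(t, I_raw, I_b, I_norm, I_sb, n_prebleach,
                           bleach_area_um2, normalization_fallback = FALSE) {
  structure(list(t = t, I_raw = I_raw, I_b = I_b, I_sb = I_sb,
                 I_norm = I_norm, n_prebleach = as.integer(n_prebleach),
                 bleach_area_um2 = bleach_area_um2,
                 normalization_fallback = normalization_fallback),
            class = "frap_trace")
}

#' Normalize a raw FRAP trace
#'
#' Background-corrects the ROI trace and divides by a reference trace
#' I_sb(t), constructed from an exponential fit (offset + amplitude *
#' exp(-lambda t)) of the background-corrected pre-bleach frames and
#' extrapolated over the whole acquisition; this also removes slow
#' acquisition bleaching. The resulting pre-bleach intensity equals unity.
#' If the exponential fit fails (e.g. the pre-bleach segment is flat), the
#' pre-bleach mean is used instead and the trace is flagged.
#'
#' @param t time grid (s).
#' @param I_raw ROI intensity trace.
#' @param I_b background intensity trace (ROI outside the cell).
#' @param n_prebleach number of pre-bleach frames (default 50, >= 3).
#' @param bleach_area_um2 bleached area (um^2), stored for the diffusion
#'   coefficient; default 3.72.
#' @return a \code{frap_trace}.
#' @export
normalize_trace <- function(t, I_raw, I_b, n_prebleach = 50L,
                            bleach_area_um2 = 3.72) {
  n_pre <- as.integer(n_prebleach)
  stopifnot(length(t) == length(I_raw), length(I_raw) == length(I_b))
  if (n_pre < 3) stop("n_prebleach must be >= 3")
  if (n_pre >= length(t)) stop("n_prebleach must leave post-bleach frames")
  corr <- I_raw - I_b
  pre_t <- t[seq_len(n_pre)]
  pre_v <- corr[seq_len(n_pre)]
  if (mean(pre_v) <= 0) stop("non-positive pre-bleach reference: cannot normalize")
  fallback <- FALSE
  I_sb <- tryCatch({
    # a nearly flat pre-bleach segment leaves (c0, a, l) weakly identified;
    # warnOnly accepts the fit and the unity check below guards the result
    fit <- suppressWarnings(
      stats::nls(v ~ c0 + a * exp(-l * tt),
                 data = list(v = pre_v, tt = pre_t),
                 start = list(c0 = min(pre_v), a = max(pre_v) - min(pre_v) + 1e-6,
                              l = 0.01),
                 lower = c(c0 = 0, a = 0, l = 0),
                 algorithm = "port",
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE)))
    cf <- stats::coef(fit)
    ref <- cf["c0"] + cf["a"] * exp(-cf["l"] * t)
    if (any(ref <= 0)) stop("non-positive reference")
    ref
  }, error = function(e) {
    fallback <<- TRUE
    rep(mean(pre_v), length(t))
  })
  if (any(I_sb <= 0)) stop("non-positive reference trace: cannot normalize")
  I_norm <- corr / I_sb
  pre_mean <- mean(I_norm[seq_len(n_pre)])
  if (abs(pre_mean - 1) > 0.02) {
    # a systematically mis-fit reference defeats the point of normalization
    I_norm <- I_norm / pre_mean
    fallback <- TRUE
  }
  new_frap_trace(t, I_raw, I_b, I_norm, I_sb, n_pre, bleach_area_um2,
                 normalization_fallback = fallback)
}

#' Average normalized FRAP traces
#'
#' Pointwise mean of the normalized intensities of several traces sharing a
#' common time grid (the averaging step applied to the per-cell experiments
#' before fitting).
#'
#' @param traces list of \code{frap_trace} objects.
#' @return a \code{frap_trace} whose \code{I_norm} is the pointwise mean.
#' @export
average_traces <- function(traces) {
  stopifnot(length(traces) >= 1)
  t0 <- traces[[1]]$t
  for (tr in traces) {
    if (length(tr$t) != length(t0) || any(abs(tr$t - t0) > 1e-9)) {
      stop("traces must share a common time grid")
    }
  }
  norm <- rowMeans(vapply(traces, function(tr) tr$I_norm,
                          numeric(length(t0))))
  new_frap_trace(t0, norm, rep(0, length(t0)), norm, rep(1, length(t0)),
                 traces[[1]]$n_prebleach, traces[[1]]$bleach_area_um2)
}

#' Recovery half-time
#'
#' \code{tau_1/2 = ln(2) / k} for an exponential recovery constant.
#'
#' @param k recovery rate constant (s^-1), > 0.
#' @return half-time in seconds.
#' @export
half_time <- function(k) {
  if (any(k <= 0)) stop("k must be > 0")
  log(2) / k
}

#' Apparent diffusion coefficient from FRAP geometry
#'
#' \code{D = beta * A / (4 * tau_1/2) = beta * A * k / (4 ln 2)} for a
#' bleached area A, with beta = 1 for a confocal microscope.
#'
#' @param k recovery rate constant (s^-1).
#' @param bleach_area_um2 bleached area (um^2).
#' @param beta geometry factor (default 1).
#' @return apparent diffusion coefficient (um^2/s).
#' @export
diffusion_coefficient <- function(k, bleach_area_um2, beta = 1) {
  if (any(k <= 0) || any(bleach_area_um2 <= 0) || beta <= 0) {
    stop("k, bleach_area_um2 and beta must be > 0")
  }
  beta * bleach_area_um2 * k / (4 * log(2))
}

# Least-squares exponential recovery fit on the post-bleach segment.
.fit_exponential <- function(t_post, y, n_comp) {
  plateau0 <- mean(utils::tail(y, max(5, length(y) %/% 10)))
  depth0 <- max(plateau0 - y[1], 0.05)
  if (n_comp == 1) {
    # log-linear start for k
    resid <- plateau0 - y
    pos <- resid > 0.01 * depth0
    k0 <- if (sum(pos) > 3) {
      max(1e-3, -stats::coef(stats::lm(log(resid[pos]) ~ t_post[pos]))[2])
    } else 1
    start <- list(p = plateau0, a1 = depth0, k1 = k0)
    lower <- c(p = -Inf, a1 = 0, k1 = 1e-6)
    form <- y ~ p - a1 * exp(-k1 * tt)
  } else {
    start <- list(p = plateau0, a1 = depth0 * 0.6, k1 = 2,
                  a2 = depth0 * 0.4, k2 = 0.2)
    lower <- c(p = -Inf, a1 = 0, k1 = 1e-6, a2 = 0, k2 = 1e-6)
    form <- y ~ p - a1 * exp(-k1 * tt) - a2 * exp(-k2 * tt)
  }
  fit <- stats::nls(form, data = list(y = y, tt = t_post), start = start,
                    lower = lower, algorithm = "port",
                    control = stats::nls.control(maxiter = 200))
  fit
}

#' Fit mono- or bi-exponential FRAP recovery
#'
#' Fits \code{F(t) = plateau - sum_i a_i exp(-k_i t)} to the post-bleach
#' segment of a normalized trace (t = 0 at the first post-bleach frame) by
#' nonlinear least squares. 95\% confidence intervals come from the
#' asymptotic fit covariance; a seeded residual bootstrap is available as a
#' cross-check. For the bi-exponential model components are ordered fast
#' then slow and the slow fraction \code{a_slow / (a_fast + a_slow)} (the
#' slow share of the mobile, i.e. recovering, amplitudes) is reported with
#' its CI by the delta method.
#'
#' @param trace a \code{frap_trace} (from \code{\link{normalize_trace}},
#'   \code{\link{average_traces}} or the simulator).
#' @param model \code{"mono"} or \code{"bi"}.
#' @param beta FRAP geometry factor for D (default 1).
#' @param bootstrap number of residual-bootstrap resamples for CIs
#'   (0 = asymptotic only).
#' @param bootstrap_seed seed for the bootstrap resampling.
#' @return an object of class \code{frap_fit}: rate constants with CIs,
#'   amplitudes, plateau, slow fraction (bi model), half-times, diffusion
#'   coefficients and RMSE.
#' @export
fit_recovery <- function(trace, model = c("mono", "bi"), beta = 1,
                         bootstrap = 0, bootstrap_seed = 1L) {
  model <- match.arg(model)
  n_comp <- if (model == "mono") 1L else 2L
  n_pre <- trace$n_prebleach
  post <- (n_pre + 1):length(trace$t)
  if (length(post) < 10) stop("post-bleach segment must have >= 10 samples")
  t_post <- trace$t[post] - trace$t[post[1]]
  y <- trace$I_norm[post]
  fit <- tryCatch(.fit_exponential(t_post, y, n_comp),
                  error = function(e) {
    stop("recovery fit did not converge (", conditionMessage(e),
         "); check the trace and model choice")
  })
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) {
    matrix(NA_real_, length(cf), length(cf),
           dimnames = list(names(cf), names(cf)))
  })
  z <- stats::qnorm(0.975)
  ci <- function(name) {
    se <- sqrt(vc[name, name])
    cf[[name]] + c(-1, 1) * z * se
  }
  ks <- cf[grep("^k", names(cf))]
  as_ <- cf[grep("^a", names(cf))]
  ord <- order(ks, decreasing = TRUE)   # fast first
  k_names <- names(ks)[ord]; a_names <- names(as_)[ord]
  k <- unname(ks[ord]); a <- unname(as_[ord])
  k_ci <- t(vapply(k_names, ci, numeric(2)))
  a_ci <- t(vapply(a_names, ci, numeric(2)))
  resid <- y - stats::fitted(fit)
  rmse <- sqrt(mean(resid^2))
  slow_fraction <- NA_real_; slow_fraction_ci <- c(NA_real_, NA_real_)
  ambiguous <- FALSE
  if (n_comp == 2) {
    sf <- a[2] / (a[1] + a[2])
    # delta method on f = a2/(a1+a2)
    gnames <- c(a_names[1], a_names[2])
    s <- a[1] + a[2]
    grad <- c(-a[2] / s^2, a[1] / s^2)
    v <- vc[gnames, gnames]
    se <- sqrt(drop(t(grad) %*% v %*% grad))
    slow_fraction <- sf
    slow_fraction_ci <- sf + c(-1, 1) * z * se
    ambiguous <- any(a_ci[, 1] < 0)    # an amplitude CI crossing zero
    if (k[1] / k[2] < 3 && !any(is.na(k_ci))) ambiguous <- TRUE
  }
  boot <- NULL
  if (bootstrap > 0) {
    set.seed(as.integer(bootstrap_seed))
    fitted_y <- stats::fitted(fit)
    bk <- matrix(NA_real_, bootstrap, n_comp)
    for (b in seq_len(bootstrap)) {
      yb <- fitted_y + sample(resid, replace = TRUE)
      fb <- tryCatch(.fit_exponential(t_post, yb, n_comp),
                     error = function(e) NULL)
      if (!is.null(fb)) {
        kb <- stats::coef(fb)[grep("^k", names(stats::coef(fb)))]
        bk[b, ] <- sort(unname(kb), decreasing = TRUE)
      }
    }
    boot <- apply(bk, 2, stats::quantile, c(0.025, 0.975), na.rm = TRUE)
  }
  A <- trace$bleach_area_um2
  structure(list(
    model = model,
    k = k, k_ci = k_ci, a = a, a_ci = a_ci,
    plateau = unname(cf["p"]),
    slow_fraction = slow_fraction, slow_fraction_ci = slow_fraction_ci,
    tau_half = half_time(k),
    D = diffusion_coefficient(k, A, beta),
    beta = beta, bleach_area_um2 = A,
    rmse = rmse, ambiguous = ambiguous,
    bootstrap_k_ci = boot,
    n_post = length(post)
  ), class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("%s-exponential FRAP fit (%d post-bleach samples, rmse %.4f)\n",
              x$model, x$n_post, x$rmse))
  lab <- if (x$model == "bi") c("fast", "slow") else "k"
  for (i in seq_along(x$k)) {
    cat(sprintf("  %-4s k = %.3f s^-1 [95%% CI %.3f-%.3f], a = %.3f, tau1/2 = %.3f s, D = %.2f um^2/s\n",
                lab[i], x$k[i], x$k_ci[i, 1], x$k_ci[i, 2], x$a[i],
                x$tau_half[i], x$D[i]))
  }
  cat(sprintf("  plateau = %.3f\n", x$plateau))
  if (!is.na(x$slow_fraction)) {
    cat(sprintf("  slow fraction of mobile pool = %.1f%% [95%% CI %.1f-%.1f]\n",
                100 * x$slow_fraction, 100 * x$slow_fraction_ci[1],
                100 * x$slow_fraction_ci[2]))
  }
  if (x$ambiguous) cat("  note: bi-exponential components poorly identified\n")
  invisible(x)
}

#' Read FRAP traces from a CSV file
#'
#' Expected columns: \code{time_s}, \code{roi}, \code{background}.
#'
#' @param path CSV path.
#' @return data frame with those columns.
#' @export
read_frap_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "roi", "background")
  if (!all(need %in% names(df))) {
    stop("FRAP CSV must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Write a FRAP trace to CSV
#' @param trace a \code{frap_trace}.
#' @param path output path.
#' @export
write_frap_csv <- function(path, trace) {
  utils::write.csv(data.frame(time_s = trace$t, roi = trace$I_raw,
                              background = trace$I_b,
                              normalized = trace$I_norm),
                   path, row.names = FALSE)
  invisible(path)
}
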