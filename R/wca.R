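# Wavelet coherence analysis: continuous Morlet transform, time/scale
# smoothing, wavelet transform coherence with phase, cone of influence, and
# Monte Carlo red-noise significance.
#
# Conventions follow the standard Torrence-Compo formulation: analytic
# Morlet psi(eta) = pi^(-1/4) exp(i omega0 eta) exp(-eta^2/2), scales
# s_j = s0 * 2^(j dj), Fourier period = 4 pi s / (omega0 + sqrt(2 + omega0^2)),
# zero padding to the next power of two, and an e-folding time sqrt(2) s for
# the cone of influence.
#
# Phase sign convention (documented and fixed): the cross-spectrum is
# conj(Wx) * Wy, so the reported phase equals the phase advance of y relative
# to x. Positive phase = y leads = x lags y; -pi/2 means x leads y by a
# quarter cycle.

#' Wavelet coherence parameters
#'
#' @param omega0 Morlet central frequency (dimensionless, >= 5 for the
#'   analytic approximation; default 6).
#' @param dj scale resolution in octave fractions (default 1/12).
#' @param s0 smallest scale in seconds (default `2 * dt`, resolved when the
#'   transform is computed).
#' @param mc_n Monte Carlo surrogate pair count (default 1000, minimum 100).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed for the Monte Carlo surrogates.
#' @param guard seam guard band, in samples, excluded around concatenation
#'   boundaries in segment summaries (default 5).
#' @param dj0 width, in octaves, of the boxcar scale smoothing (default 0.6).
#' @return an object of class `wca_params`.
#' @export
wca_params <- function(omega0 = 6, dj = 1 / 12, s0 = NULL, mc_n = 1000,
                       alpha = 0.05, seed = NULL, guard = 5, dj0 = 0.6) {
  if (omega0 < 5)
    stop_mod("wca_params", "omega0 must be >= 5 (analytic admissibility)")
  if (dj <= 0) stop_mod("wca_params", "dj must be > 0")
  if (mc_n < 100) stop_mod("wca_params", "mc_n must be >= 100")
  if (alpha <= 0 || alpha >= 1) stop_mod("wca_params", "alpha in (0,1)")
  structure(list(omega0 = omega0, dj = dj, s0 = s0, mc_n = as.integer(mc_n),
                 alpha = alpha, seed = seed, guard = as.integer(guard),
                 dj0 = dj0), class = "wca_params")
}

#' Fourier period per unit scale for the Morlet wavelet
#'
#' `4 pi / (omega0 + sqrt(2 + omega0^2))`; about 1.033 for `omega0 = 6`.
#'
#' @param omega0 Morlet central frequency.
#' @return the period/scale conversion factor.
#' @export
fourier_factor <- function(omega0 = 6) 4 * pi / (omega0 + sqrt(2 + omega0^2))

# Precomputed transform geometry shared by cwt/wtc/surrogates.
cwt_grid <- function(n, dt, params) {
  s0 <- params$s0 %||% (2 * dt)
  ff <- fourier_factor(params$omega0)
  s_max <- (n * dt / 2) / ff          # largest period <= half the record
  J <- max(0L, floor(log2(s_max / s0) / params$dj))
  scales <- s0 * 2^(params$dj * (0:J))
  npad <- nextn(n, 2)
  omega <- 2 * pi * c(0:(npad / 2), -((npad / 2 - 1):1)) / (npad * dt)
  psihat <- matrix(0, J + 1L, npad)
  posw <- omega > 0
  for (j in 0:J) {
    s <- scales[j + 1L]
    psihat[j + 1L, posw] <- sqrt(2 * pi * s / dt) * pi^(-1 / 4) *
      exp(-(s * omega[posw] - params$omega0)^2 / 2)
  }
  list(n = n, dt = dt, npad = npad, scales = scales,
       periods = ff * scales, psihat = psihat, params = params,
       coi = cone_of_influence(n, dt, params$omega0))
}

#' Continuous Morlet wavelet transform
#'
#' Computed by frequency-domain multiplication after zero padding to the next
#' power of two (padding removed on return). The series is demeaned first.
#'
#' @param tc a `timecourse` of length >= 8 with finite values.
#' @param params a `wca_params`.
#' @return an object of class `cwt_result`: complex coefficient matrix `W`
#'   (scales x times), `scales` and `fourier_periods` in seconds, `times`,
#'   `coi`, and `dt_s`.
#' @export
morlet_cwt <- function(tc, params = wca_params()) {
  x <- as.numeric(tc)
  if (length(x) < 8) stop_mod("cwt", "need at least 8 samples")
  if (any(!is.finite(x))) stop_mod("cwt", "non-finite values in input")
  grid <- cwt_grid(length(x), tc_dt(tc), params)
  W <- cwt_core(x, grid)
  structure(list(W = W, scales = grid$scales,
                 fourier_periods = grid$periods,
                 times = (0:(grid$n - 1)) * grid$dt, coi = grid$coi,
                 dt_s = grid$dt, params = params), class = "cwt_result")
}

cwt_core <- function(x, grid) {
  xhat <- fft(c(x - mean(x), rep(0, grid$npad - grid$n)))
  nsc <- nrow(grid$psihat)
  W <- matrix(0i, nsc, grid$n)
  for (j in seq_len(nsc)) {
    w <- fft(xhat * grid$psihat[j, ], inverse = TRUE) / grid$npad
    W[j, ] <- w[seq_len(grid$n)]
  }
  W
}

#' @export
print.cwt_result <- function(x, ...) {
  cat(sprintf("<cwt_result> %d scales x %d times, periods %.3g-%.3g s\n",
              nrow(x$W), ncol(x$W), min(x$fourier_periods),
              max(x$fourier_periods)))
  invisible(x)
}

#' Cone of influence
#'
#' Per-time maximum Fourier period not contaminated by edge effects. The
#' Morlet e-folding time is `sqrt(2) * s`, so at distance `d` (seconds) from
#' the nearer record edge the largest uncontaminated scale is `d / sqrt(2)`
#' and the returned period is `fourier_factor * d / sqrt(2)`. The value is 0
#' at the first and last sample by this convention, and symmetric about the
#' record midpoint.
#'
#' @param n series length (>= 2).
#' @param dt sampling interval (seconds).
#' @param omega0 Morlet central frequency (default 6).
#' @return numeric vector of length `n` (seconds of Fourier period).
#' @export
cone_of_influence <- function(n, dt, omega0 = 6) {
  if (n < 2) stop_mod("coi", "n must be >= 2")
  idx <- 0:(n - 1)
  fourier_factor(omega0) * dt * pmin(idx, n - 1 - idx) / sqrt(2)
}

# Normalized convolution of (possibly complex) x with kernel k (odd length),
# FFT-based, edge-renormalized so constants are preserved exactly.
conv_norm <- function(x, k) {
  n <- length(x)
  m <- length(k)
  half <- (m - 1L) / 2L
  N <- nextn(n + m, 2)
  K <- fft(c(k, rep(0, N - m)))
  num <- fft(fft(c(x, rep(0, N - n))) * K, inverse = TRUE) / N
  den <- Re(fft(fft(c(rep(1, n), rep(0, N - n))) * K, inverse = TRUE) / N)
  y <- num[(half + 1L):(half + n)] / den[(half + 1L):(half + n)]
  if (is.complex(x)) y else Re(y)
}

#' Smooth a time-scale field
#'
#' The smoothing operator that makes wavelet coherence non-trivial:
#' convolution in time with a Gaussian whose SD equals the scale `s` at each
#' row, followed by a boxcar across scales of fixed octave width `dj0`. The
#' operator is linear and preserves constant fields exactly (kernels are
#' renormalized at the boundaries).
#'
#' @param field numeric or complex matrix (scales x times).
#' @param scales scale vector in seconds (one per row).
#' @param dt sampling interval in seconds.
#' @param dj scale resolution (octave fraction).
#' @param dj0 boxcar width in octaves (default 0.6).
#' @return smoothed field, same dimensions and mode.
#' @export
smooth_time_scale <- function(field, scales, dt, dj, dj0 = 0.6) {
  field <- as.matrix(field)
  if (nrow(field) != length(scales))
    stop_mod("smooth", "rows (%d) != scales (%d)", nrow(field),
             length(scales))
  n <- ncol(field)
  out <- field
  for (j in seq_along(scales)) {
    sdv <- scales[j] / dt                 # Gaussian SD in samples
    half <- min(max(1L, ceiling(4 * sdv)), n)
    kern <- exp(-((-half:half)^2) / (2 * sdv^2))
    out[j, ] <- conv_norm(field[j, ], kern / sum(kern))
  }
  span <- max(0L, round(dj0 / (2 * dj)))
  if (span > 0L) {
    sm <- out
    J <- length(scales)
    for (j in seq_len(J)) {
      rows <- max(1L, j - span):min(J, j + span)
      sm[j, ] <- colMeans(out[rows, , drop = FALSE])
    }
    out <- sm
  }
  out
}

#' Fit an AR(1) red-noise model to a time course
#'
#' `phi` is the lag-1 sample autocorrelation of the demeaned series and
#' `sigma` the innovation SD estimated from the lag-1 residuals — the red
#' noise null used by the Monte Carlo coherence test.
#'
#' @param tc a `timecourse` (length >= 10, non-constant).
#' @return an object of class `ar1_fit` with `phi`, `sigma`, `n`.
#' @export
fit_ar1 <- function(tc) {
  x <- as.numeric(tc)
  n <- length(x)
  if (n < 10) stop_mod("fit_ar1", "need at least 10 samples")
  xc <- x - mean(x)
  if (sd(xc) == 0) stop_mod("fit_ar1", "constant series")
  phi <- sum(xc[-1] * xc[-n]) / sum(xc^2)
  if (phi >= 0.95)
    warning(sprintf(paste0("phi estimate %.3f is near the unit root; a ",
                           "deterministic trend may masquerade as red noise"),
                    phi), call. = FALSE)
  e <- xc[-1] - phi * xc[-n]
  sigma <- sd(e)
  if (sigma <= 0) stop_mod("fit_ar1", "degenerate innovation variance")
  structure(list(phi = phi, sigma = sigma, n = n), class = "ar1_fit")
}

#' @export
print.ar1_fit <- function(x, ...) {
  cat(sprintf("<ar1_fit> phi = %.3f, sigma = %.3g (n = %d)\n", x$phi,
              x$sigma, x$n))
  invisible(x)
}

# Shared coherence computation on a precomputed grid; returns rsq and the
# smoothed cross-spectrum.
wtc_core <- function(x, y, grid) {
  p <- grid$params
  Wx <- cwt_core(x, grid)
  Wy <- cwt_core(y, grid)
  sinv <- 1 / grid$scales
  Sxx <- smooth_time_scale(sinv * abs(Wx)^2, grid$scales, grid$dt, p$dj,
                           p$dj0)
  Syy <- smooth_time_scale(sinv * abs(Wy)^2, grid$scales, grid$dt, p$dj,
                           p$dj0)
  Sxy <- smooth_time_scale(sinv * (Conj(Wx) * Wy), grid$scales, grid$dt,
                           p$dj, p$dj0)
  den <- pmax(Sxx * Syy, .Machine$double.xmin)
  rsq <- Mod(Sxy)^2 / den
  rsq <- pmin(pmax(rsq, 0), 1)          # floating-point overshoot only
  list(rsq = rsq, Sxy = Sxy)
}

in_coi_matrix <- function(periods, coi) {
  outer(periods, coi, `<=`)
}

#' Wavelet transform coherence between two time courses
#'
#' Squared coherence `R^2(s, tau) = |S(s^-1 Wx* Wy)|^2 /
#' (S(s^-1 |Wx|^2) S(s^-1 |Wy|^2))` and phase `arg S(s^-1 Wx* Wy)`, where `S`
#' is [smooth_time_scale()]. With `significance = TRUE`, each input is fitted
#' as AR(1) red noise and cell-wise significance at `1 - alpha` is assessed
#' against Monte Carlo surrogate thresholds ([mc_significance()]); the
#' significance mask is always FALSE outside the cone of influence.
#'
#' The reported phase is the advance of `y` relative to `x`: positive phase
#' means `x` lags `y`; `-pi/2` means `x` leads by a quarter cycle.
#'
#' @param x,y `timecourse` objects of equal length and sampling interval.
#' @param params a `wca_params`.
#' @param significance run the Monte Carlo red-noise test (default TRUE).
#' @return an object of class `wtc`: `rsq` and `phase` matrices (scales x
#'   times), `scales`, `fourier_periods`, `times`, `coi`, `sig_mask`,
#'   per-scale `thresholds` (or NULL), AR(1) fits, segments inherited from
#'   `x`, and the parameters.
#' @export
wtc <- function(x, y, params = wca_params(), significance = TRUE) {
  xs <- as.numeric(x)
  ys <- as.numeric(y)
  if (length(xs) != length(ys))
    stop_mod("wtc", "series lengths differ (%d vs %d)", length(xs),
             length(ys))
  if (abs(tc_dt(x) - tc_dt(y)) > 1e-12)
    stop_mod("wtc", "sampling intervals differ")
  if (sd(xs) == 0 || sd(ys) == 0)
    stop_mod("wtc", "constant input series; coherence undefined")
  grid <- cwt_grid(length(xs), tc_dt(x), params)
  core <- wtc_core(xs, ys, grid)
  incoi <- in_coi_matrix(grid$periods, grid$coi)
  thresholds <- NULL
  fits <- NULL
  sig <- matrix(FALSE, nrow(core$rsq), ncol(core$rsq))
  if (significance) {
    fits <- list(x = fit_ar1(x), y = fit_ar1(y))
    thresholds <- mc_significance(fits$x, fits$y, params, n = grid$n,
                                  dt = grid$dt)
    sig <- core$rsq > thresholds & incoi
    sig[is.na(sig)] <- FALSE            # NA-threshold scales are out of COI
  }
  structure(list(rsq = core$rsq, phase = Arg(core$Sxy),
                 scales = grid$scales, fourier_periods = grid$periods,
                 times = (0:(grid$n - 1)) * grid$dt, coi = grid$coi,
                 in_coi = incoi, sig_mask = sig, thresholds = thresholds,
                 ar1_fits = fits, segments = tc_segments(x),
                 dt_s = grid$dt, params = params,
                 provenance = c(x = attr(x, "provenance"),
                                y = attr(y, "provenance"))),
            class = "wtc")
}

#' @export
print.wtc <- function(x, ...) {
  cat(sprintf("<wtc> %d scales x %d times (periods %.3g-%.3g s)\n",
              nrow(x$rsq), ncol(x$rsq), min(x$fourier_periods),
              max(x$fourier_periods)))
  if (!is.null(x$thresholds))
    cat(sprintf("  significant in-COI cells: %.1f%% at alpha = %.2g\n",
                100 * sum(x$sig_mask) / max(1, sum(x$in_coi)),
                x$params$alpha))
  invisible(x)
}

#' @export
summary.wtc <- function(object, ...) {
  s <- segment_phase_summary(object)
  cat("Per-segment phase summary:\n")
  print(s, row.names = FALSE)
  invisible(s)
}

#' Scalogram plot of a wavelet coherence result
#'
#' Coherence as an image over time and (log2) Fourier period, with the cone
#' of influence and, when available, the significance contour.
#'
#' @param x a `wtc` object.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.wtc <- function(x, ...) {
  lp <- log2(x$fourier_periods)
  graphics::image(x$times, lp, t(x$rsq), ylim = rev(range(lp)),
                  xlab = "time (s)", ylab = "log2 Fourier period (s)",
                  main = "wavelet coherence", zlim = c(0, 1),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  keep <- x$coi > 0
  graphics::lines(x$times[keep], log2(pmax(x$coi[keep],
                                           min(x$fourier_periods))),
                  lwd = 2)
  if (!is.null(x$thresholds) && any(x$sig_mask))
    graphics::contour(x$times, lp, t(x$sig_mask * 1), levels = 0.5,
                      add = TRUE, drawlabels = FALSE, lwd = 1.5)
  if (!is.null(x$segments) && nrow(x$segments) > 1)
    graphics::abline(v = x$segments$start[-1] * x$dt_s, lty = 2)
  invisible(x)
}

#' Monte Carlo red-noise significance thresholds for coherence
#'
#' Generates `mc_n` independent AR(1) surrogate pairs with the fitted
#' `(phi, sigma)` of each input, computes the wavelet coherence of every
#' pair, pools the in-COI coherence values per scale over time and
#' surrogates, and returns the `1 - alpha` quantile per scale. Scales whose
#' period exceeds the cone of influence everywhere have no valid cells and
#' get an `NA` threshold (they can never be significant). Deterministic
#' given `params$seed`.
#'
#' @param fit_x,fit_y `ar1_fit` objects for the two series.
#' @param params a `wca_params` (uses `mc_n`, `alpha`, `seed`).
#' @param n series length of the analysed data (defaults to `fit_x$n`).
#' @param dt sampling interval (seconds; default 1).
#' @return numeric vector of per-scale coherence thresholds, with the scale
#'   vector as the `scales` attribute.
#' @export
mc_significance <- function(fit_x, fit_y, params = wca_params(), n = NULL,
                            dt = 1) {
  stopifnot(inherits(fit_x, "ar1_fit"), inherits(fit_y, "ar1_fit"))
  n <- n %||% fit_x$n
  grid <- cwt_grid(n, dt, params)
  incoi <- in_coi_matrix(grid$periods, grid$coi)
  counts <- rowSums(incoi)
  vals <- lapply(counts, function(cn) numeric(cn * params$mc_n))
  with_seed(params$seed, {
    for (i in seq_len(params$mc_n)) {
      xs <- ar1_matrix(n, 1L, fit_x$phi, fit_x$sigma)[, 1]
      ys <- ar1_matrix(n, 1L, fit_y$phi, fit_y$sigma)[, 1]
      rsq <- wtc_core(xs, ys, grid)$rsq
      for (j in which(counts > 0))
        vals[[j]][((i - 1) * counts[j] + 1):(i * counts[j])] <-
          rsq[j, incoi[j, ]]
    }
  })
  thr <- vapply(seq_along(vals), function(j) {
    if (length(vals[[j]]) == 0) NA_real_ else
      as.numeric(quantile(vals[[j]], 1 - params$alpha, names = FALSE))
  }, numeric(1))
  structure(thr, scales = grid$scales)
}

#' Classify a phase angle into the four cardinal coupling classes
#'
#' Quadrant binning with boundaries at `+-pi/4` and `+-3pi/4`, matching the
#' scalogram arrow legend: right = in phase, left = antiphase, and the two
#' lateral quadrants = one signal leading/lagging by a quarter cycle. Under
#' the package's sign convention (positive phase = x lags y), angles in
#' `(-3pi/4, -pi/4)` classify as `x_leads` and angles in `(pi/4, 3pi/4)` as
#' `x_lags`; boundary angles fall into the lead/lag classes.
#'
#' @param angle numeric vector of angles (radians; normalized into
#'   `(-pi, pi]` first).
#' @return character vector over `{in_phase, antiphase, x_leads, x_lags}`.
#' @export
phase_classify <- function(angle) {
  a <- wrap_angle(angle)
  out <- character(length(a))
  out[abs(a) < pi / 4] <- "in_phase"
  out[abs(a) > 3 * pi / 4] <- "antiphase"
  out[a >= pi / 4 & a <= 3 * pi / 4] <- "x_lags"
  out[a <= -pi / 4 & a >= -3 * pi / 4] <- "x_leads"
  out
}

#' Per-segment phase summary of a coherence result
#'
#' For each concatenated phase segment: the circular mean phase over
#' significant in-COI cells, the fraction of in-COI cells that are
#' significant, and the dominant coupling class by majority vote of the
#' classified significant cells. A segment whose significant fraction does
#' not exceed the chance floor (`none_floor`, default twice the significance
#' level) is classed `"none"`: at the tested cell counts a calibrated test
#' always flags a few cells by chance, so "no coherence" must mean
#' "no more than chance", not literally zero. Cells within `guard` samples
#' of a concatenation seam are excluded, since the artificial discontinuity
#' there is not part of either phase.
#'
#' @param w a `wtc` computed on a concatenated series with segments (or pass
#'   `segments` explicitly).
#' @param segments optional data.frame `phase`/`start`/`end` (0-based
#'   half-open sample ranges) overriding the segments stored in `w`.
#' @param guard seam guard band in samples (default from `w$params`).
#' @param none_floor significant-fraction threshold at or below which the
#'   dominant class is `"none"` (default `2 * alpha`).
#' @return a `phase_summary` data.frame with one row per segment: `phase`,
#'   `n_in_coi`, `n_significant`, `sig_fraction`, `mean_phase`,
#'   `dominant_class`.
#' @export
segment_phase_summary <- function(w, segments = NULL, guard = NULL,
                                  none_floor = NULL) {
  stopifnot(inherits(w, "wtc"))
  segments <- segments %||% w$segments %||%
    data.frame(phase = "all", start = 0L, end = ncol(w$rsq))
  guard <- guard %||% w$params$guard
  none_floor <- none_floor %||% (2 * w$params$alpha)
  n <- ncol(w$rsq)
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    a <- segments$start[i]
    b <- segments$end[i]
    lo <- if (a > 0) a + guard else a
    hi <- if (b < n) b - guard else b
    cols <- if (lo < hi) (lo + 1):hi else integer(0)   # 1-based columns
    incoi <- w$in_coi[, cols, drop = FALSE]
    sig <- w$sig_mask[, cols, drop = FALSE]
    ph <- w$phase[, cols, drop = FALSE][sig]
    n_sig <- sum(sig)
    frac <- if (sum(incoi)) n_sig / sum(incoi) else 0
    cls <- if (n_sig == 0 || frac <= none_floor) "none" else {
      cl <- phase_classify(ph)
      names(which.max(table(cl)))
    }
    data.frame(phase = segments$phase[i], n_in_coi = sum(incoi),
               n_significant = n_sig,
               sig_fraction = if (sum(incoi)) n_sig / sum(incoi) else NA_real_,
               mean_phase = if (n_sig) circular_mean(ph) else NA_real_,
               dominant_class = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("phase_summary", "data.frame")
  out
}
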