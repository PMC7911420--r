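# Morlet transform, cone of influence, smoothing operator, wavelet
# coherence, AR(1) fitting, Monte Carlo significance, and phase summaries.

test_that("Morlet transform finds the oscillation ridge", {
  n <- 256; dt <- 1; P <- 50
  tc <- timecourse(sin(2 * pi * (0:(n - 1)) * dt / P), dt)
  cw <- morlet_cwt(tc, wca_params())
  power <- rowMeans(abs(cw$W)^2)
  ridge_period <- cw$fourier_periods[which.max(power)]
  expect_lt(abs(log2(ridge_period / P)), 1 / 12 + 1e-9)

  zero <- timecourse(rep(0, 64), 1)
  expect_equal(max(abs(morlet_cwt(zero)$W)), 0)

  bad <- timecourse(c(rnorm(63), NaN), 1)
  expect_error(morlet_cwt(bad), "non-finite")
})

test_that("Fourier period factor matches the closed form", {
  omega0 <- 6
  expect_equal(fourier_factor(omega0), 4 * pi / (omega0 + sqrt(2 + omega0^2)),
               tolerance = 1e-15)
  # periods of the transform are scales times the factor
  tc <- timecourse(rnorm(64), 2)
  cw <- morlet_cwt(tc, wca_params())
  expect_equal(cw$fourier_periods, fourier_factor(6) * cw$scales,
               tolerance = 1e-12)
})

test_that("cone of influence is symmetric with e-folding growth", {
  n <- 101; dt <- 2
  coi <- cone_of_influence(n, dt)
  expect_equal(coi, rev(coi))
  expect_equal(coi[1], 0)
  expect_equal(coi[n], 0)
  mid <- (n - 1) / 2
  expect_equal(coi[mid + 1], fourier_factor(6) * mid * dt / sqrt(2),
               tolerance = 1e-12)
  # strictly increasing toward the midpoint
  expect_true(all(diff(coi[1:(mid + 1)]) > 0))
})

test_that("time-scale smoothing is linear and constant-preserving", {
  scales <- 2 * 2^((0:20) / 12)
  n <- 80
  const <- matrix(3.5, length(scales), n)
  expect_lt(max(abs(smooth_time_scale(const, scales, 1, 1 / 12) - 3.5)),
            1e-10)

  set.seed(40)
  F1 <- matrix(rnorm(length(scales) * n), length(scales), n)
  F2 <- matrix(rnorm(length(scales) * n), length(scales), n)
  lhs <- smooth_time_scale(2 * F1 - 3 * F2, scales, 1, 1 / 12)
  rhs <- 2 * smooth_time_scale(F1, scales, 1, 1 / 12) -
    3 * smooth_time_scale(F2, scales, 1, 1 / 12)
  expect_lt(max(abs(lhs - rhs)), 1e-10)

  # impulse response: per-scale spread proportional to the scale
  imp <- matrix(0, length(scales), 401)
  imp[, 201] <- 1
  sm <- smooth_time_scale(imp, scales, 1, 1 / 12, dj0 = 0)  # time only
  spread <- vapply(c(1, 13), function(j) {
    w <- sm[j, ] / sum(sm[j, ])
    sqrt(sum(w * ((1:401) - 201)^2))
  }, numeric(1))
  ratio <- spread[2] / spread[1]
  expect_equal(ratio, scales[13] / scales[1], tolerance = 0.05)
})

test_that("coherence satisfies its defining bounds and symmetries", {
  set.seed(41)
  x <- gen_ar1_series(300, 0.5, 1, seed = 41, dt_s = 2)
  y <- gen_ar1_series(300, 0.5, 1, seed = 42, dt_s = 2)
  w <- wtc(x, y, significance = FALSE)
  expect_true(all(w$rsq >= 0 & w$rsq <= 1))

  # self-coherence
  ws <- wtc(x, x, significance = FALSE)
  expect_gte(min(ws$rsq[ws$in_coi]), 0.999)

  # symmetry of R^2 and antisymmetry of phase under argument swap
  wr <- wtc(y, x, significance = FALSE)
  expect_equal(w$rsq, wr$rsq, tolerance = 1e-10)
  expect_lt(max(abs(wrap_angle(w$phase + wr$phase))), 1e-8)

  # amplitude invariance
  ax <- timecourse(5 * as.numeric(x), 2)
  by <- timecourse(0.2 * as.numeric(y), 2)
  wa <- wtc(ax, by, significance = FALSE)
  expect_lt(max(abs(wa$rsq - w$rsq)), 1e-8)
  expect_lt(max(abs(wrap_angle(wa$phase - w$phase))), 1e-8)

  expect_error(wtc(timecourse(rep(1, 300), 2), y), "constant")
})

test_that("pure sinusoid pairs give the documented phase convention", {
  # y advanced by pi/2 (y leads): positive phase +pi/2 at the ridge
  q <- gen_oscillatory_pair(200, 3.01, 0.05, pi / 2, snr = Inf)
  w <- wtc(q$x, q$y, significance = FALSE)
  ridge <- which.min(abs(w$fourier_periods - 1 / 0.05))
  ph <- w$phase[ridge, w$in_coi[ridge, ]]
  expect_lt(abs(circular_diff(circular_mean(ph), pi / 2)), pi / 16)

  a <- gen_oscillatory_pair(200, 3.01, 0.05, pi, snr = Inf)
  wa <- wtc(a$x, a$y, significance = FALSE)
  pha <- wa$phase[ridge, wa$in_coi[ridge, ]]
  expect_lt(abs(abs(circular_mean(pha)) - pi), pi / 16)
})

test_that("AR(1) fitting tracks the generating parameters", {
  hits <- vapply(1:100, function(i) {
    f <- fit_ar1(gen_ar1_series(800, 0.5, 1, seed = 500 + i))
    f$phi > 0.4 && f$phi < 0.6
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  fw <- fit_ar1(gen_ar1_series(1000, 0, 1, seed = 43))
  expect_lt(abs(fw$phi), 0.1)

  trend <- timecourse(seq(0, 10, length.out = 200), 1)
  expect_warning(ft <- fit_ar1(trend), "unit root")
  expect_gt(ft$phi, 0.95)

  expect_error(fit_ar1(timecourse(rep(2, 50), 1)), "constant")
  expect_error(fit_ar1(timecourse(rnorm(5), 1)), "10 samples")
})

test_that("Monte Carlo thresholds are valid quantiles and deterministic", {
  f <- structure(list(phi = 0.4, sigma = 1, n = 64), class = "ar1_fit")
  p <- wca_params(mc_n = 100, seed = 44)
  thr1 <- mc_significance(f, f, p, n = 64, dt = 2)
  thr2 <- mc_significance(f, f, p, n = 64, dt = 2)
  expect_identical(thr1, thr2)
  # valid quantiles wherever the scale has in-COI cells; NA beyond the cone
  coi <- cone_of_influence(64, 2)
  has_cells <- vapply(fourier_factor(6) * attr(thr1, "scales"),
                      function(pp) any(pp <= coi), logical(1))
  expect_true(all(thr1[has_cells] > 0 & thr1[has_cells] < 1))
  expect_true(all(is.na(thr1[!has_cells])))

  p2 <- wca_params(mc_n = 100, seed = 45)
  thr3 <- mc_significance(f, f, p2, n = 64, dt = 2)
  expect_false(identical(as.numeric(thr1), as.numeric(thr3)))
})

test_that("phase classification matches the arrow legend", {
  expect_identical(phase_classify(0), "in_phase")
  expect_identical(phase_classify(pi), "antiphase")
  expect_identical(phase_classify(-pi / 2), "x_leads")
  expect_identical(phase_classify(pi / 2), "x_lags")
  # out-of-range angles are normalized first
  expect_identical(phase_classify(2 * pi + 0.1), "in_phase")
  expect_identical(phase_classify(-3 * pi), "antiphase")
  # vectorized
  expect_identical(phase_classify(c(0.1, 3, -1.3, 1.8)),
                   c("in_phase", "antiphase", "x_leads", "x_lags"))
})

test_that("segment summaries honor guard bands and the none class", {
  seg <- data.frame(phase = c("a", "b"), start = c(0L, 100L),
                    end = c(100L, 200L))
  q <- gen_oscillatory_pair(200, 3.01, 0.05, 0, snr = Inf)
  x <- timecourse(as.numeric(q$x), 3.01, segments = seg)
  w <- wtc(x, q$y, wca_params(guard = 5), significance = FALSE)
  s <- segment_phase_summary(w)
  expect_identical(nrow(s), 2L)
  # without a significance run, no cell is significant: class none, NA phase
  expect_true(all(s$dominant_class == "none"))
  expect_true(all(is.na(s$mean_phase)))
  expect_true(all(s$n_significant == 0))

  # in-COI counts differ between guarded (seam side) and unguarded edges
  full <- segment_phase_summary(w, guard = 0)
  expect_gt(full$n_in_coi[1], s$n_in_coi[1])
})

test_that("circular means and wrapping behave on the circle", {
  expect_equal(circular_mean(c(pi - 0.1, -pi + 0.1)), pi, tolerance = 1e-9)
  expect_equal(circular_mean(c(-0.2, 0.2)), 0, tolerance = 1e-12)
  expect_equal(wrap_angle(3 * pi), pi)
  expect_equal(wrap_angle(-pi), pi)
  expect_equal(circular_diff(0.1, -0.1), 0.2, tolerance = 1e-12)
  expect_true(is.na(circular_mean(numeric(0))))
})
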