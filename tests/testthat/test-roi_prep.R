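# ROI rasterization, high-pass filtering, spatial smoothing, nuisance
# regression, time-course extraction and concatenation.

test_that("sphere masks equal the exhaustive distance oracle", {
  ref <- mni_reference()
  dims <- dim(ref$labels)

  # 1 mm radius centered exactly on a voxel center: only that voxel
  m1 <- make_sphere_roi(sphere_roi("pt", c(0, 0, -5), 1), ref)
  expect_identical(sum(m1), 1L)

  for (roi in list(sphere_roi("hypothalamus", c(0, 2, -6), 3),
                   sphere_roi("left_dorsal_pons", c(-8, -24, -32), 5))) {
    m <- make_sphere_roi(roi, ref)
    expect_identical(sum(m),
                     brute_force_sphere_count(dims, ref$affine,
                                              roi$center_mni, roi$radius_mm))
  }

  # random centers/radii on a shifted grid
  set.seed(14)
  ref2 <- blank_reference(c(9, 8, 7), make_affine(3, c(-12, -10, -9)))
  for (i in 1:5) {
    ctr <- runif(3, -8, 8)
    r <- runif(1, 2, 6)
    m <- make_sphere_roi(sphere_roi("rand", ctr, r), ref2)
    expect_identical(sum(m),
                     brute_force_sphere_count(dim(ref2$labels), ref2$affine,
                                              ctr, r))
  }

  expect_error(make_sphere_roi(sphere_roi("far", c(500, 500, 500), 2), ref),
               "no voxel")
})

test_that("high-pass filter removes DC and preserves the pass band", {
  n <- 200; dt <- 3.01
  const <- timecourse(rep(5, n), dt)
  expect_lt(max(abs(highpass(const, 0.007))), 1e-10)

  # 0.05 Hz sinusoid is far above the 0.007 Hz cutoff: amplitude preserved
  t <- (0:(n - 1)) * dt
  s <- timecourse(sin(2 * pi * 0.05 * t), dt)
  out <- highpass(s, 0.007)
  amp <- (max(out) - min(out)) / 2
  expect_gte(amp, 0.95)
  expect_lte(amp, 1.05)
  expect_lt(abs(mean(out)), 1e-10)

  # 0.001 Hz sinusoid sits in the documented stop band [0, cutoff/2];
  # oracle: apply the documented response to the DFT independently
  slow <- sin(2 * pi * 0.001 * t)
  out2 <- highpass(timecourse(slow, dt), 0.007)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) / (n * dt)
  oracle <- Re(fft(fft(slow) * highpass_response(f, 0.007),
                   inverse = TRUE)) / n
  expect_lt(max(abs(as.numeric(out2) - oracle)), 1e-10)
  # sub-cycle trend leakage stays under the documented half-excursion bound
  expect_lt(max(abs(oracle)), 0.5)

  # a stop-band sinusoid aligned with a DFT bin is removed completely
  aligned <- sin(2 * pi * (1 / (n * dt)) * t)          # bin 1, ~0.0017 Hz
  expect_lt(max(abs(highpass(timecourse(aligned, dt), 0.007))), 1e-10)

  expect_error(highpass(s, 1), "Nyquist")
})

test_that("high-pass filtering is idempotent on band-limited input", {
  n <- 256; dt <- 2
  t <- (0:(n - 1)) * dt
  # bin-aligned pass-band frequencies (band-limited in the DFT sense)
  f1 <- 26 / (n * dt); f2 <- 51 / (n * dt)
  x <- timecourse(sin(2 * pi * f1 * t) + 0.5 * sin(2 * pi * f2 * t), dt)
  once <- highpass(x, 0.01)
  twice <- highpass(once, 0.01)
  expect_lt(max(abs(as.numeric(twice) - as.numeric(once))), 1e-6)
})

test_that("high-pass on a scan filters every voxel like the 1D path", {
  scan <- tiny_scan(c(3, 3, 2), nt = 64, tr = 2, seed = 3)
  hp <- highpass(scan, 0.02)
  v <- scan$data[2, 3, 1, ]
  ref <- highpass(timecourse(v, 2), 0.02)
  expect_lt(max(abs(hp$data[2, 3, 1, ] - as.numeric(ref))), 1e-10)
})

test_that("spatial smoothing preserves constants and interior mass", {
  scan <- tiny_scan(c(9, 9, 7), nt = 2, tr = 2, seed = 4)
  expect_identical(spatial_smooth(scan, 0), scan)

  uni <- bold_scan(array(3, c(9, 9, 7, 2)), make_affine(2.5), 2)
  sm <- spatial_smooth(uni, 5)
  expect_lt(max(abs(sm$data - 3)), 1e-10)

  imp <- array(0, c(9, 9, 7, 2))
  imp[5, 5, 4, ] <- 1
  smi <- spatial_smooth(bold_scan(imp, make_affine(2.5), 2), 5)
  expect_lt(abs(sum(smi$data[, , , 1]) - 1), 0.01)
  # impulse actually spread
  expect_lt(smi$data[5, 5, 4, 1], 1)

  shear <- make_affine(2.5)
  shear[1, 2] <- 1
  bad <- bold_scan(array(rnorm(9 * 9 * 7 * 2), c(9, 9, 7, 2)), shear, 2)
  expect_error(spatial_smooth(bad, 5), "affine")
})

test_that("nuisance regression matches the normal-equations oracle", {
  dims <- c(5, 5, 4); nt <- 40
  scan <- tiny_scan(dims, nt, tr = 2, seed = 5)
  wm <- array(FALSE, dims); wm[1:2, , 1] <- TRUE
  csf <- array(FALSE, dims); csf[5, 5, ] <- TRUE
  res <- regress_nuisance(scan, list(wm, csf))

  Y <- t(array(scan$data, c(prod(dims), nt)))
  X <- cbind(1, rowMeans(Y[, as.vector(wm)]), rowMeans(Y[, as.vector(csf)]))
  R_oracle <- Y - X %*% solve(crossprod(X), crossprod(X, Y))
  expect_lt(max(abs(t(array(res$data, c(prod(dims), nt))) - R_oracle)), 1e-8)

  # residuals orthogonal to every regressor at every voxel
  Rm <- t(array(res$data, c(prod(dims), nt)))
  ip <- crossprod(X[, 2:3], Rm)
  norms <- outer(sqrt(colSums(X[, 2:3]^2)), sqrt(colSums(Rm^2)))
  expect_lt(max(abs(ip) / pmax(norms, 1e-12)), 1e-6)
})

test_that("nuisance regression handles special series as specified", {
  dims <- c(4, 4, 3); nt <- 30
  scan <- tiny_scan(dims, nt, tr = 2, seed = 6)
  wm <- array(FALSE, dims); wm[1, 1:2, 1] <- TRUE
  # make one voxel exactly the WM mean
  wm_mean <- apply(scan$data[1, 1:2, 1, , drop = FALSE], 4, mean)
  scan$data[4, 4, 3, ] <- wm_mean
  res <- regress_nuisance(scan, list(wm))
  expect_lt(max(abs(res$data[4, 4, 3, ])), 1e-8)

  # duplicate masks are linearly dependent: warn, still residualize
  expect_warning(regress_nuisance(scan, list(wm, wm)), "dependent")
  expect_error(regress_nuisance(scan, list(array(FALSE, dims))), "empty")
})

test_that("mean time-course extraction is exact and linear", {
  dims <- c(5, 4, 3); nt <- 25
  scan <- tiny_scan(dims, nt, tr = 1.5, seed = 7)
  one <- array(FALSE, dims); one[2, 3, 1] <- TRUE
  expect_equal(as.numeric(extract_mean_timecourse(scan, one)),
               scan$data[2, 3, 1, ])

  set.seed(8)
  mask <- array(FALSE, dims)
  mask[sample(prod(dims), 10)] <- TRUE
  tc <- extract_mean_timecourse(scan, mask)
  oracle <- vapply(seq_len(nt), function(t)
    mean(scan$data[, , , t][mask]), numeric(1))
  expect_equal(as.numeric(tc), oracle, tolerance = 1e-12)
  expect_equal(attr(tc, "dt_s"), 1.5)

  # linearity in the scan intensities
  scan2 <- scan; scan2$data <- 2 * scan$data + 1
  tc2 <- extract_mean_timecourse(scan2, mask)
  expect_equal(as.numeric(tc2), 2 * oracle + 1, tolerance = 1e-12)

  empty <- array(FALSE, dims)
  expect_error(extract_mean_timecourse(scan, empty, "my_roi"), "my_roi")
})

test_that("concatenation records segment bounds and validates dt", {
  mk <- function(n, dt = 3.01) timecourse(rnorm(n), dt)
  set.seed(9)
  big <- concatenate_timecourses(list(mk(200), mk(200), mk(200), mk(200)),
                                 c("baseline", "prodrome", "full_blown",
                                   "recovery"))
  expect_length(big, 800L)
  seg <- attr(big, "segments")
  expect_equal(seg$start, c(0L, 200L, 400L, 600L))
  expect_equal(seg$end, c(200L, 400L, 600L, 800L))

  single <- mk(50)
  out <- concatenate_timecourses(list(single), "only")
  expect_equal(as.numeric(out), as.numeric(single))

  ab <- concatenate_timecourses(list(mk(3), mk(5)), c("a", "b"))
  expect_length(ab, 8L)
  expect_equal(attr(ab, "segments")$start, c(0L, 3L))
  expect_equal(attr(ab, "segments")$end, c(3L, 8L))

  expect_error(concatenate_timecourses(list(mk(10, 1), mk(10, 2))),
               "sampling")
})
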