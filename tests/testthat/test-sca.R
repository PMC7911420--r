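# Seed correlation maps, TFCE, sign-flip permutation inference, and the
# rcFC index with its repeated-measures comparison.

test_that("seed correlation maps equal the brute-force Pearson oracle", {
  dims <- c(5, 5, 4); nt <- 40
  scan <- tiny_scan(dims, nt, tr = 2, seed = 21)
  seed_tc <- timecourse(rnorm(nt), 2)
  scan$data[1, 1, 1, ] <- as.numeric(seed_tc)            # r = +1
  scan$data[2, 1, 1, ] <- -as.numeric(seed_tc)           # r = -1
  scan$data[3, 1, 1, ] <- 7                              # zero variance
  m <- seed_correlation_map(scan, seed_tc, "s")
  expect_lt(abs(m$r[1, 1, 1] - 1), 1e-10)
  expect_lt(abs(m$r[2, 1, 1] + 1), 1e-10)
  expect_identical(m$r[3, 1, 1], 0)
  expect_true(m$zero_variance[3, 1, 1])

  set.seed(22)
  idx <- cbind(sample(dims[1], 50, TRUE), sample(dims[2], 50, TRUE),
               sample(dims[3], 50, TRUE))
  for (i in seq_len(50)) {
    v <- scan$data[idx[i, 1], idx[i, 2], idx[i, 3], ]
    if (sd(v) == 0) next
    expect_lt(abs(m$r[idx[i, 1], idx[i, 2], idx[i, 3]] -
                    cor(v, as.numeric(seed_tc))), 1e-10)
  }
  expect_error(seed_correlation_map(scan, timecourse(rnorm(10), 2)),
               "length")
})

test_that("Fisher z transform is atanh with clipping", {
  m <- as_sca_map(array(c(0, 0.5, -0.3, 0.9), c(2, 2, 1)), fisher = FALSE)
  z <- fisher_z(m)
  expect_equal(z$r[1, 1, 1], 0)
  expect_equal(z$r[2, 1, 1], atanh(0.5), tolerance = 1e-12)
  expect_equal(z$r[1, 2, 1], atanh(-0.3), tolerance = 1e-12)
  # monotone
  rs <- sort(runif(10, -0.95, 0.95))
  zs <- atanh(rs)
  expect_true(all(diff(zs) > 0))
  m$r[1, 1, 1] <- 1
  expect_warning(fisher_z(m), "clipped")
})

test_that("TFCE matches the discrete-sum and locality oracles", {
  dims <- c(6, 6, 4)
  zero <- array(0, dims)
  expect_equal(tfce_enhance(zero, dh = 0.1), zero)

  # isolated single voxel of height 1
  v <- zero; v[2, 2, 2] <- 1
  enh <- tfce_enhance(v, E = 0.5, H = 2, dh = 0.1)
  expect_equal(enh[2, 2, 2], tfce_single_voxel_oracle(1, 0.5, 2, 0.1),
               tolerance = 1e-10)
  expect_equal(sum(enh != 0), 1L)

  # two disjoint blobs: each enhanced as if alone
  blob_a <- zero; blob_a[1:2, 1:2, 1] <- c(0.8, 1, 0.6, 0.9)
  blob_b <- zero; blob_b[5:6, 5:6, 4] <- c(0.5, 0.7, 1.2, 0.4)
  both <- blob_a + blob_b
  dh <- max(both) / 100
  e_both <- tfce_enhance(both, dh = dh)
  e_a <- tfce_enhance(blob_a, dh = dh)
  e_b <- tfce_enhance(blob_b, dh = dh)
  expect_equal(e_both[blob_a > 0], e_a[blob_a > 0], tolerance = 1e-10)
  expect_equal(e_both[blob_b > 0], e_b[blob_b > 0], tolerance = 1e-10)

  # monotonicity: pointwise-larger stat gives pointwise >= enhancement
  set.seed(23)
  base <- array(abs(rnorm(prod(dims))), dims)
  bigger <- base + 0.3
  dh2 <- max(bigger) / 100
  expect_true(all(tfce_enhance(bigger, dh = dh2) -
                    tfce_enhance(base, dh = dh2) >= -1e-10))

  # negative lobes: antisymmetric handling
  expect_equal(tfce_enhance(-v, dh = 0.1), -enh, tolerance = 1e-10)
  bad <- zero; bad[1, 1, 1] <- NaN
  expect_error(tfce_enhance(bad), "finite")
})

test_that("exhaustive sign-flip FWE attains 1/32 with 5 identical maps", {
  dims <- c(4, 4, 3)
  set.seed(24)
  base <- array(abs(rnorm(prod(dims))) + 0.1, dims)
  maps <- lapply(1:5, function(i) as_sca_map(base))
  gs <- group_mean_effect(maps, fisher = FALSE, n_perm = 5000)
  expect_true(gs$exhaustive)
  expect_identical(gs$n_permutations, 32L)
  expect_equal(min(gs$fwe_p), 1 / 32, tolerance = 1e-12)
  expect_true(all(gs$fwe_p == 1 / 32))
})

test_that("group inference is invariant to subject order", {
  dims <- c(4, 4, 3)
  set.seed(25)
  maps <- lapply(1:5, function(i)
    as_sca_map(array(rnorm(prod(dims), 0.2), dims)))
  g1 <- group_mean_effect(maps, fisher = FALSE)
  g2 <- group_mean_effect(maps[c(3, 1, 5, 2, 4)], fisher = FALSE)
  expect_equal(g1$tstat, g2$tstat, tolerance = 1e-12)
  expect_equal(g1$fwe_p, g2$fwe_p, tolerance = 1e-12)
})

test_that("FWE control is valid under a sign-symmetric null", {
  dims <- c(4, 4, 3)
  n_sub <- 6
  n_rep <- 100
  any_sig <- logical(n_rep)
  set.seed(26)
  for (r in seq_len(n_rep)) {
    maps <- lapply(seq_len(n_sub), function(i)
      as_sca_map(array(rnorm(prod(dims)), dims)))
    gs <- group_mean_effect(maps, fisher = FALSE)
    any_sig[r] <- any(gs$fwe_p <= 0.05)
  }
  mc_se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(mean(any_sig), 0.05 + 3 * mc_se)
})

test_that("covariate residualization is applied before flipping", {
  dims <- c(4, 4, 3)
  set.seed(27)
  cov <- c(2, -1, 0.5, 1.5, -2, -1) / 10   # zero mean: pure covariate effect
  # maps are exactly a covariate effect with no group mean effect: after
  # residualization the t map must vanish
  maps <- lapply(1:6, function(i) as_sca_map(array(cov[i], dims)))
  gs <- group_mean_effect(maps, covariates = data.frame(age = cov),
                          fisher = FALSE)
  expect_lt(max(abs(gs$tstat)), 1e-6)
  expect_error(group_mean_effect(maps, covariates = data.frame(a = 1:3)),
               "covariate rows")
  expect_error(group_mean_effect(maps[1], n_perm = 10), "2 subjects")
})

test_that("meanFC over a mask averages the non-zero voxels", {
  vol <- array(0.4, c(3, 3, 1))
  mask <- array(TRUE, c(3, 3, 1))
  expect_equal(mean_fc_over_mask(as_sca_map(vol), mask), 0.4)

  vol2 <- array(c(rep(0.2, 4), rep(0.6, 4), 0), c(3, 3, 1))
  mask2 <- array(c(rep(TRUE, 8), FALSE), c(3, 3, 1))
  expect_equal(mean_fc_over_mask(as_sca_map(vol2), mask2), 0.4)

  vol3 <- array(c(0, 0.3, 0.5, rep(0, 6)), c(3, 3, 1))
  mask3 <- array(c(TRUE, TRUE, TRUE, rep(FALSE, 6)), c(3, 3, 1))
  expect_equal(mean_fc_over_mask(as_sca_map(vol3), mask3), 0.4)

  expect_error(mean_fc_over_mask(as_sca_map(vol3), array(FALSE, c(3, 3, 1))),
               "empty")
  zmask <- array(c(TRUE, rep(FALSE, 8)), c(3, 3, 1))
  expect_error(mean_fc_over_mask(as_sca_map(vol3), zmask), "zero")
})

test_that("rcFC obeys its defining identities", {
  expect_equal(rcfc(0.5, 0.5), 0)
  expect_equal(rcfc(0.4, 0.5), -0.2)
  # scale invariance
  for (c_scale in c(0.1, 2, 17)) {
    expect_equal(rcfc(c_scale * 0.4, c_scale * 0.5), rcfc(0.4, 0.5),
                 tolerance = 1e-12)
  }
  expect_error(rcfc(0.4, 0), "undefined")

  tab <- rcfc_table(data.frame(
    subject = rep(1:3, 4),
    phase = rep(c("baseline", "prodrome", "full_blown", "recovery"),
                each = 3),
    mean_fc = c(0.5, 0.6, 0.4, 0.4, 0.5, 0.3, 0.3, 0.35, 0.25,
                0.45, 0.55, 0.4)))
  expect_equal(tab$rcfc[tab$phase == "baseline"], 0)
})

test_that("phase comparison matches the paired-t oracle and handles ties", {
  # identical values per subject: degenerate F = 0, p = 1
  same <- data.frame(subject = rep(1:4, 3),
                     phase = rep(c("a", "b", "c"), each = 4),
                     mean_fc = rep(c(0.2, 0.4, 0.3, 0.5), 3))
  cmp <- compare_rcfc(same)
  expect_equal(cmp$anova$F, 0)
  expect_equal(cmp$anova$p, 1)

  # two phases: ANOVA p equals the paired t-test p (Bonferroni factor 1)
  set.seed(28)
  a <- rnorm(6, 0.5, 0.1); b <- rnorm(6, 0.4, 0.1)
  two <- data.frame(subject = rep(1:6, 2), phase = rep(c("a", "b"), each = 6),
                    mean_fc = c(a, b))
  cmp2 <- compare_rcfc(two)
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(cmp2$anova$p, tt$p.value, tolerance = 1e-10)
  expect_equal(cmp2$pairwise$p_bonferroni, cmp2$pairwise$p_raw)

  # three phases: adjusted p = min(1, 3 * raw)
  set.seed(29)
  three <- data.frame(subject = rep(1:5, 3),
                      phase = rep(c("a", "b", "c"), each = 5),
                      mean_fc = rnorm(15, 0.4, 0.1))
  cmp3 <- compare_rcfc(three)
  expect_equal(cmp3$pairwise$p_bonferroni,
               pmin(1, cmp3$pairwise$p_raw * 3), tolerance = 1e-12)

  unbalanced <- three[-1, ]
  expect_error(compare_rcfc(unbalanced), "balanced")
})
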