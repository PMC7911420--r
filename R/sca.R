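# Seed-based correlation analysis: voxelwise Pearson maps, Fisher-z
# stabilization, TFCE, sign-flip permutation inference with FWE correction,
# and the baseline-normalised relative change in FC (rcFC) index.

#' Voxelwise seed correlation map
#'
#' Pearson correlation of every voxel's time series with a seed reference
#' time course. Zero-variance voxels map to r = 0 and are flagged.
#'
#' @param scan a `bold_scan` (preprocessed identically to the seed signal).
#' @param seed_tc a `timecourse` with length equal to the scan's t-dimension.
#' @param seed_name,subject_id provenance labels.
#' @return an object of class `sca_map`: list with 3D `r` volume, affine,
#'   `zero_variance` mask, labels, and `fisher_z` flag (FALSE).
#' @export
seed_correlation_map <- function(scan, seed_tc, seed_name = "seed",
                                 subject_id = "") {
  stopifnot(inherits(scan, "bold_scan"))
  d <- dim(scan$data)
  x <- as.numeric(seed_tc)
  if (length(x) != d[4])
    stop_mod("sca", "seed length %d != scan volumes %d", length(x), d[4])
  Y <- t(array(scan$data, c(prod(d[1:3]), d[4])))   # time x voxels
  xc <- x - mean(x)
  Yc <- sweep(Y, 2, colMeans(Y))
  sx <- sqrt(sum(xc^2))
  sy <- sqrt(colSums(Yc^2))
  zero <- sy < 1e-12 * max(sy, 1) | sx == 0
  denom <- sx * sy
  denom[zero] <- 1
  r <- as.vector(crossprod(Yc, xc)) / denom
  r[zero] <- 0
  structure(list(r = array(r, d[1:3]), affine = scan$affine,
                 zero_variance = array(zero, d[1:3]),
                 seed_name = seed_name, phase_name = scan$phase_name,
                 subject_id = subject_id, fisher_z = FALSE),
            class = "sca_map")
}

#' @export
print.sca_map <- function(x, ...) {
  cat(sprintf("<sca_map> seed '%s', phase '%s'%s: r in [%.3f, %.3f]%s\n",
              x$seed_name, x$phase_name,
              if (nzchar(x$subject_id)) paste0(", subject ", x$subject_id)
              else "",
              min(x$r), max(x$r), if (x$fisher_z) " (Fisher z)" else ""))
  invisible(x)
}

#' Fisher z-transform of a correlation map
#'
#' Variance-stabilizing `z = atanh(r)`; correlations at +-1 are clipped to
#' `+-(1 - 1e-7)` with a warning.
#'
#' @param map an `sca_map`.
#' @return the map with `r` replaced by z values and `fisher_z = TRUE`.
#' @export
fisher_z <- function(map) {
  stopifnot(inherits(map, "sca_map"))
  if (map$fisher_z) return(map)
  r <- map$r
  if (any(abs(r) >= 1)) {
    warning("correlations at +-1 clipped before atanh", call. = FALSE)
    r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  }
  map$r <- atanh(r)
  map$fisher_z <- TRUE
  map
}

#' Threshold-free cluster enhancement
#'
#' TFCE integral of a statistic volume: each voxel accumulates
#' `e(h)^E * h^H * dh` over thresholds `h = dh, 2dh, ...` up to its height,
#' where `e(h)` is the size of its connected suprathreshold component.
#' Negative values are enhanced on the negated volume and re-negated.
#'
#' @param stat_volume 3D numeric array (finite).
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh threshold step; default `max(abs(stat)) / 100`.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return enhanced volume, same dimensions.
#' @export
tfce_enhance <- function(stat_volume, E = 0.5, H = 2, dh = NULL,
                         connectivity = 26) {
  stat_volume <- as.array(stat_volume)
  if (length(dim(stat_volume)) != 3L)
    stop_mod("tfce", "stat_volume must be 3D")
  if (!all(is.finite(stat_volume)))
    stop_mod("tfce", "non-finite values in stat volume")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop_mod("tfce", "connectivity must be 6, 18 or 26")
  if (is.null(dh)) dh <- max(abs(stat_volume)) / 100
  if (max(abs(stat_volume)) == 0) return(stat_volume * 0)
  if (dh <= 0) stop_mod("tfce", "dh must be > 0")
  dims <- dim(stat_volume)
  pos <- pmax(stat_volume, 0)
  neg <- pmax(-stat_volume, 0)
  enh <- .tfce_cpp(as.numeric(pos), as.integer(dims), E, H, dh,
                   as.integer(connectivity))
  if (any(neg > 0))
    enh <- enh - .tfce_cpp(as.numeric(neg), as.integer(dims), E, H, dh,
                           as.integer(connectivity))
  array(enh, dims)
}

#' Group mean-effect inference by sign-flip permutation with TFCE/FWE
#'
#' Covariates are residualized out of the (Fisher z) subject maps; the
#' one-sample t statistic is computed per voxel; the null is built by
#' sign-flipping subject residual maps (exhaustive enumeration when
#' `2^n <= n_perm`, otherwise `n_perm` random flips including the identity).
#' The FWE-corrected p value of each voxel is the proportion of permutations
#' whose maximum TFCE statistic reaches that voxel's observed TFCE value
#' (one-sided, positive tail — the mean-effect contract).
#'
#' @param maps list of per-subject `sca_map` objects on a common grid.
#' @param covariates optional data.frame/matrix of per-subject covariates
#'   (e.g., age, gender, disease duration); columns are mean-centered and
#'   projected out before flipping.
#' @param n_perm permutation budget (default 5000).
#' @param seed RNG seed for random flips.
#' @param fisher apply [fisher_z()] to the maps first (default TRUE).
#' @param E,H,dh,connectivity TFCE parameters; `dh` defaults to the observed
#'   `max(|t|) / 100` and is held fixed across permutations.
#' @param t_cap cap on |t| at zero-residual-variance voxels (default 100).
#' @return an object of class `group_stat` with `tstat`, `tfce` and `fwe_p`
#'   volumes, the effective permutation count, and the covariates used.
#' @export
group_mean_effect <- function(maps, covariates = NULL, n_perm = 5000,
                              seed = NULL, fisher = TRUE, E = 0.5, H = 2,
                              dh = NULL, connectivity = 26, t_cap = 100) {
  n <- length(maps)
  if (n < 2) stop_mod("group_stat", "need at least 2 subjects")
  stopifnot(all(vapply(maps, inherits, logical(1), "sca_map")))
  dims <- dim(maps[[1]]$r)
  if (fisher) maps <- lapply(maps, fisher_z)
  M <- do.call(rbind, lapply(maps, function(m) as.numeric(m$r)))
  if (all(apply(M, 2, function(v) max(v) - min(v)) < 1e-14) &&
      max(abs(M)) < 1e-14)
    stop_mod("group_stat", "constant (all-zero) maps")
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (nrow(C) != n)
      stop_mod("group_stat", "covariate rows (%d) != subjects (%d)",
               nrow(C), n)
    C <- sweep(C, 2, colMeans(C))
    qC <- qr(C)
    M <- M - qr.fitted(qC, M)
  }
  ss <- colSums(M^2)
  m_scale <- sqrt(max(ss) / n) + 1e-300

  tstat_for <- function(signs) {
    m <- as.vector(signs %*% M) / n
    v <- pmax((ss - n * m^2) / (n - 1), 0)
    t <- m / sqrt(pmax(v, 1e-300) / n)
    degen <- v <= 1e-24 * m_scale^2        # zero residual variance
    t[degen] <- sign(m[degen]) * t_cap
    t[degen & abs(m) <= 1e-10 * m_scale] <- 0
    pmin(pmax(t, -t_cap), t_cap)
  }

  exhaustive <- 2^n <= n_perm
  if (exhaustive) {
    flips <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    flips <- with_seed(seed, {
      f <- matrix(sample(c(1, -1), (n_perm - 1) * n, replace = TRUE),
                  n_perm - 1, n)
      rbind(rep(1, n), f)
    })
  }
  # ensure the identity flip is present and first
  idr <- which(apply(flips, 1, function(r) all(r == 1)))[1]
  flips <- rbind(rep(1, n), flips[-idr, , drop = FALSE])

  t_obs <- tstat_for(flips[1, ])
  if (is.null(dh)) dh <- max(abs(t_obs)) / 100
  enh_obs <- tfce_enhance(array(t_obs, dims), E, H, dh, connectivity)
  max_null <- vapply(seq_len(nrow(flips)), function(i) {
    enh <- if (i == 1) enh_obs else
      tfce_enhance(array(tstat_for(flips[i, ]), dims), E, H, dh, connectivity)
    max(enh)
  }, numeric(1))
  n_eff <- length(max_null)
  fwe_p <- array(vapply(as.numeric(enh_obs), function(e)
    mean(max_null >= e - 1e-12), numeric(1)), dims)

  structure(list(tstat = array(t_obs, dims), tfce = enh_obs, fwe_p = fwe_p,
                 n_permutations = n_eff, exhaustive = exhaustive,
                 covariates = covariates, affine = maps[[1]]$affine,
                 seed_name = maps[[1]]$seed_name,
                 phase_name = maps[[1]]$phase_name),
            class = "group_stat")
}

#' @export
print.group_stat <- function(x, ...) {
  cat(sprintf(paste0("<group_stat> seed '%s', phase '%s': %d %s sign-flips, ",
                     "min FWE p = %.4g, %d voxels p < 0.05\n"),
              x$seed_name, x$phase_name, x$n_permutations,
              if (x$exhaustive) "exhaustive" else "random",
              min(x$fwe_p), sum(x$fwe_p < 0.05)))
  invisible(x)
}

#' Mean functional connectivity over a significant mask
#'
#' Mean of the map values over mask voxels whose value is non-zero (the
#' non-zero-voxel convention of the group mean-FC summary).
#'
#' @param map an `sca_map` (raw r values, not Fisher z).
#' @param sig_mask logical 3D mask (e.g., `group_stat$fwe_p < 0.05`).
#' @return scalar meanFC.
#' @export
mean_fc_over_mask <- function(map, sig_mask) {
  stopifnot(inherits(map, "sca_map"))
  if (!any(sig_mask)) stop_mod("mean_fc", "empty significance mask")
  vals <- map$r[sig_mask]
  vals <- vals[vals != 0]
  if (length(vals) == 0L)
    stop_mod("mean_fc", "all masked values are zero; meanFC undefined")
  mean(vals)
}

#' Relative change in functional connectivity (rcFC)
#'
#' `rcFC_x = (meanFC_x - meanFC_baseline) / meanFC_baseline`: each phase's
#' mean FC normalised by the baseline value, so baseline maps to 0 exactly
#' and the index is invariant to common positive rescaling.
#'
#' @param mean_fc_x meanFC of the phase of interest.
#' @param mean_fc_baseline meanFC of the baseline phase (non-zero).
#' @return scalar rcFC.
#' @export
rcfc <- function(mean_fc_x, mean_fc_baseline) {
  if (!is.finite(mean_fc_baseline) || mean_fc_baseline == 0)
    stop_mod("rcfc", "baseline meanFC is zero; rcFC undefined")
  (mean_fc_x - mean_fc_baseline) / mean_fc_baseline
}

#' Build the per-phase meanFC / rcFC table
#'
#' @param subject_fc data.frame with columns `subject`, `phase`, `mean_fc`
#'   (per-subject meanFC values over the phase's significant mask).
#' @param baseline name of the baseline phase (default `"baseline"`).
#' @return an `rcfc_table` data.frame with per-phase group meanFC and rcFC.
#' @export
rcfc_table <- function(subject_fc, baseline = "baseline") {
  subject_fc <- as.data.frame(subject_fc)
  stopifnot(all(c("subject", "phase", "mean_fc") %in% names(subject_fc)))
  phases <- unique(subject_fc$phase)
  if (!baseline %in% phases)
    stop_mod("rcfc", "baseline phase '%s' absent", baseline)
  grp <- vapply(phases, function(p)
    mean(subject_fc$mean_fc[subject_fc$phase == p]), numeric(1))
  out <- data.frame(phase = phases, mean_fc = unname(grp),
                    rcfc = vapply(unname(grp), rcfc, numeric(1),
                                  mean_fc_baseline = grp[[baseline]]))
  attr(out, "subject_fc") <- subject_fc
  class(out) <- c("rcfc_table", "data.frame")
  out
}

#' Compare per-subject meanFC values across phases
#'
#' One-way repeated-measures ANOVA (subjects as the error stratum) on the
#' per-subject meanFC values across phases, followed by post-hoc paired
#' t tests with Bonferroni-multiplied p values capped at 1. Requires a
#' balanced design (every subject measured in every phase). When the phase
#' effect is numerically zero the degenerate F = 0, p = 1 result is returned.
#'
#' @param subject_fc data.frame with columns `subject`, `phase`, `mean_fc`,
#'   or an `rcfc_table` carrying one.
#' @return list of class `rcfc_comparison` with `anova` (F, df, p) and
#'   `pairwise` (phase pair, raw and Bonferroni-adjusted p).
#' @export
compare_rcfc <- function(subject_fc) {
  if (inherits(subject_fc, "rcfc_table"))
    subject_fc <- attr(subject_fc, "subject_fc")
  df <- as.data.frame(subject_fc)
  stopifnot(all(c("subject", "phase", "mean_fc") %in% names(df)))
  df$subject <- factor(df$subject)
  df$phase <- factor(df$phase)
  tab <- table(df$subject, df$phase)
  if (any(tab != 1L))
    stop_mod("compare_rcfc", "balanced design required (one value per
             subject x phase)")
  if (nlevels(df$phase) < 2 || nlevels(df$subject) < 2)
    stop_mod("compare_rcfc", "need >= 2 phases and >= 2 subjects")

  cell <- tapply(df$mean_fc, list(df$subject, df$phase), identity)
  ss_phase <- nrow(cell) * sum((colMeans(cell) - mean(cell))^2)
  if (ss_phase < 1e-20 * max(1, sum(cell^2))) {
    an <- list(F = 0, df1 = nlevels(df$phase) - 1,
               df2 = (nlevels(df$phase) - 1) * (nlevels(df$subject) - 1),
               p = 1)
  } else {
    fit <- stats::aov(mean_fc ~ phase + Error(subject), data = df)
    s <- summary(fit)[["Error: Within"]][[1]]
    an <- list(F = s["phase", "F value"], df1 = s["phase", "Df"],
               df2 = s["Residuals", "Df"], p = s["phase", "Pr(>F)"])
  }

  prs <- utils::combn(levels(df$phase), 2)
  k <- ncol(prs)
  pairwise <- do.call(rbind, lapply(seq_len(k), function(i) {
    a <- cell[, prs[1, i]]
    b <- cell[, prs[2, i]]
    p <- if (sd(a - b) < 1e-14) 1 else stats::t.test(a, b, paired = TRUE)$p.value
    data.frame(phase_a = prs[1, i], phase_b = prs[2, i], p_raw = p,
               p_bonferroni = min(1, p * k))
  }))
  structure(list(anova = an, pairwise = pairwise, n_comparisons = k),
            class = "rcfc_comparison")
}

#' @export
print.rcfc_comparison <- function(x, ...) {
  cat(sprintf("<rcfc_comparison> RM-ANOVA F(%d,%d) = %.3f, p = %.4g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
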