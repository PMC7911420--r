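# Group spatial ICA on temporally concatenated data, template-based network
# selection, and per-scan network time-course extraction by the first stage
# of dual regression.

#' Temporally concatenate scans across subjects
#'
#' Stacks every subject's scans (in phase order) into one time-by-voxel
#' matrix; each scan block is voxelwise demeaned, so the concatenated data
#' set has zero voxel means.
#'
#' @param scans_by_subject list (one per subject) of lists of `bold_scan`
#'   objects in phase order, all on the same grid.
#' @return numeric matrix (time x voxels) with attributes `dims` (spatial
#'   dims), `affine`, and `row_index` (data.frame subject / phase / volume).
#' @export
temporal_concat_group <- function(scans_by_subject) {
  stopifnot(is.list(scans_by_subject), length(scans_by_subject) >= 1)
  ref <- scans_by_subject[[1]][[1]]
  blocks <- list()
  idx <- list()
  for (s in seq_along(scans_by_subject)) {
    for (scan in scans_by_subject[[s]]) {
      if (!same_geometry(scan, ref))
        stop_mod("netid", "geometry mismatch at subject %d", s)
      d <- dim(scan$data)
      m <- t(array(scan$data, c(prod(d[1:3]), d[4])))
      m <- sweep(m, 2, colMeans(m))
      blocks[[length(blocks) + 1L]] <- m
      idx[[length(idx) + 1L]] <- data.frame(subject = s,
                                            phase = scan$phase_name,
                                            volume = seq_len(d[4]))
    }
  }
  out <- do.call(rbind, blocks)
  attr(out, "dims") <- dim(ref$data)[1:3]
  attr(out, "affine") <- ref$affine
  attr(out, "row_index") <- do.call(rbind, idx)
  out
}

#' Group spatial ICA by PCA whitening and fixed-point iteration
#'
#' The time-by-voxel data matrix is reduced to `k` dimensions by PCA
#' (spatial whitening), then unmixed by symmetric fixed-point iteration
#' maximizing spatial non-Gaussianity with the log-cosh contrast. Component
#' maps are unit-norm, sign-aligned so each map's largest-magnitude weight is
#' positive, and ordered by variance explained.
#'
#' @param data time x voxels matrix (demeaned), e.g. from
#'   [temporal_concat_group()].
#' @param k number of components; must not exceed the data rank. `k = NULL`
#'   selects the smallest k whose PCA subspace explains `var_threshold` of
#'   the variance, capped at `k_max`.
#' @param seed RNG seed for the unmixing initialization.
#' @param var_threshold PCA variance-explained threshold used when `k` is
#'   `NULL` (default 0.9).
#' @param k_max cap for automatic order selection (default 20).
#' @param fun non-Gaussianity contrast: `"logcosh"` (default) or `"pow3"`
#'   (kurtosis). When every log-cosh restart fails to settle — typical when
#'   the sources are sub-Gaussian, e.g. oscillatory — the kurtosis contrast
#'   is tried automatically (with a warning) before giving up.
#' @param max_iter,tol fixed-point iteration controls (defaults 500, 1e-4;
#'   tighter tolerances can fail to settle when part of the retained subspace
#'   is near-Gaussian noise, whose unmixing rotation is undetermined).
#' @param restarts random re-initializations attempted per contrast before
#'   giving up (default 3).
#' @return an object of class `ica_decomp`: `maps` (k x voxels, unit norm),
#'   `mixing` (time x k), `var_explained`, `iterations`, plus grid metadata.
#' @export
group_spatial_ica <- function(data, k = NULL, seed = NULL,
                              var_threshold = 0.9, k_max = 20,
                              fun = c("logcosh", "pow3"), max_iter = 500,
                              tol = 1e-4, restarts = 3) {
  fun <- match.arg(fun)
  X <- as.matrix(data)
  nt <- nrow(X); nv <- ncol(X)
  E <- tcrossprod(X)              # nt x nt
  eg <- eigen(E, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  rank <- sum(pos)
  if (is.null(k)) {
    cum <- cumsum(eg$values[pos]) / sum(eg$values[pos])
    k <- min(which(cum >= var_threshold)[1], k_max, rank)
  }
  if (k > rank)
    stop_mod("ica", "k = %d exceeds data rank %d", k, rank)
  if (k < 1) stop_mod("ica", "k must be >= 1")
  dvals <- sqrt(eg$values[seq_len(k)])
  U <- eg$vectors[, seq_len(k), drop = FALSE]
  # whitened spatial data: k x voxels, rows with variance 1 over voxels
  Z <- sqrt(nv) * (t(U) %*% X) / dvals

  fixed_point <- function(contrast) {
    last_delta <- NA_real_
    for (attempt in seq_len(restarts)) {
      Wa <- with_seed(derive_seed(seed %||% 0, attempt), {
        sym_decorrelate(matrix(rnorm(k * k), k, k))
      })
      for (it in seq_len(max_iter)) {
        U <- Wa %*% Z
        if (contrast == "logcosh") {
          G <- tanh(U)
          gprime <- rowMeans(1 - G^2)
        } else {
          G <- U^3
          gprime <- rowMeans(3 * U^2)
        }
        W_new <- sym_decorrelate(G %*% t(Z) / nv - diag(gprime, k) %*% Wa)
        last_delta <- max(abs(abs(rowSums(W_new * Wa)) - 1))
        Wa <- W_new
        if (last_delta < tol) return(list(W = Wa, iterations = it))
      }
    }
    list(W = NULL, delta = last_delta)
  }

  fit <- fixed_point(fun)
  if (is.null(fit$W) && fun == "logcosh") {
    warning(sprintf(paste0("log-cosh contrast did not settle (delta = %.3g ",
                           "after %d x %d iterations); retrying with the ",
                           "kurtosis contrast"), fit$delta, restarts,
                    max_iter), call. = FALSE)
    fit <- fixed_point("pow3")
  }
  if (is.null(fit$W))
    stop_mod("ica",
             "no convergence after %d iterations x %d restarts (delta = %.3g)",
             max_iter, restarts, fit$delta)
  W <- fit$W
  it <- fit$iterations

  S <- W %*% Z                      # k x voxels spatial maps
  norms <- sqrt(rowSums(S^2))
  S <- S / norms
  A <- X %*% t(S)                   # time x k mixing (S rows orthonormal-ish)
  # sign-align: largest-|weight| voxel of each map is positive
  for (i in seq_len(k)) {
    j <- which.max(abs(S[i, ]))
    if (S[i, j] < 0) {
      S[i, ] <- -S[i, ]
      A[, i] <- -A[, i]
    }
  }
  ve <- colSums(A^2) / sum(X^2)
  o <- order(ve, decreasing = TRUE)
  structure(list(maps = S[o, , drop = FALSE], mixing = A[, o, drop = FALSE],
                 var_explained = ve[o], k = k, iterations = it,
                 dims = attr(data, "dims"), affine = attr(data, "affine")),
            class = "ica_decomp")
}

sym_decorrelate <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}

#' @export
print.ica_decomp <- function(x, ...) {
  cat(sprintf("<ica_decomp> %d components (%d voxels), %d iterations\n",
              nrow(x$maps), ncol(x$maps), x$iterations))
  cat("  variance explained:",
      paste(sprintf("%.3f", x$var_explained), collapse = " "), "\n")
  invisible(x)
}

#' Reshape one ICA component map to its 3D volume
#'
#' @param decomp an `ica_decomp` with grid metadata.
#' @param i component index.
#' @return 3D array.
#' @export
ica_map_volume <- function(decomp, i) {
  if (is.null(decomp$dims))
    stop_mod("ica", "decomposition carries no grid metadata")
  array(decomp$maps[i, ], decomp$dims)
}

#' Select the component matching a network template
#'
#' Returns the component whose spatial map maximizes the absolute Pearson
#' correlation with the template map; invariant to component sign and order.
#'
#' @param decomp an `ica_decomp`.
#' @param template numeric array/vector (weight map or binary mask) on the
#'   same grid as the data.
#' @param floor warn when the best correlation falls below this value
#'   (default 0.3); the component is still returned.
#' @return list with `index`, `map` (voxel vector, sign-aligned to correlate
#'   positively with the template), `correlation`, and `runner_up_margin`.
#' @export
select_network <- function(decomp, template, floor = 0.3) {
  stopifnot(inherits(decomp, "ica_decomp"))
  tv <- as.numeric(template)
  if (length(tv) != ncol(decomp$maps))
    stop_mod("netid", "template has %d voxels, data has %d", length(tv),
             ncol(decomp$maps))
  if (sd(tv) == 0) stop_mod("netid", "constant template")
  cors <- as.vector(cor(tv, t(decomp$maps)))
  a <- abs(cors)
  best <- which.max(a)
  margin <- if (length(a) > 1) a[best] - max(a[-best]) else a[best]
  if (a[best] < floor)
    warning(sprintf("best template correlation %.3f below floor %.2f",
                    a[best], floor), call. = FALSE)
  map <- decomp$maps[best, ] * sign(cors[best])
  list(index = best, map = map, correlation = a[best],
       runner_up_margin = margin)
}

#' Network time course by stage-1 dual regression
#'
#' For each volume, the least-squares coefficient of regressing that volume's
#' voxel values on an intercept plus the (spatial) network map — the spatial
#' regression stage of dual regression.
#'
#' @param map numeric spatial weight map (array or vector) on the scan grid.
#' @param scan a `bold_scan`.
#' @return a `timecourse` with the scan's TR.
#' @export
network_timecourse <- function(map, scan) {
  stopifnot(inherits(scan, "bold_scan"))
  d <- dim(scan$data)
  m <- as.numeric(map)
  if (length(m) != prod(d[1:3]))
    stop_mod("netid", "map is off-grid")
  mc <- m - mean(m)
  s2 <- sum(mc^2)
  if (s2 < 1e-24) stop_mod("netid", "constant spatial map")
  Y <- array(scan$data, c(prod(d[1:3]), d[4]))
  timecourse(as.vector(crossprod(Y, mc)) / s2, scan$tr_s,
             provenance = paste0("network@", scan$phase_name))
}

#' Average standardized time courses across subjects
#'
#' Each subject's signal is z-scored (so no subject dominates), then the
#' pointwise mean is taken; segment bounds are preserved.
#'
#' @param tcs list of `timecourse` objects of equal length and dt.
#' @param standardize z-score each input first (default TRUE).
#' @return a `timecourse`.
#' @export
average_across_subjects <- function(tcs, standardize = TRUE) {
  stopifnot(is.list(tcs), length(tcs) >= 1)
  n <- length(tcs[[1]])
  dt <- tc_dt(tcs[[1]])
  for (tc in tcs) {
    if (length(tc) != n) stop_mod("netid", "time-course length mismatch")
    if (abs(tc_dt(tc) - dt) > 1e-12)
      stop_mod("netid", "sampling-interval mismatch")
  }
  M <- vapply(tcs, function(tc) {
    x <- as.numeric(tc)
    if (standardize) {
      s <- sd(x)
      if (s > 0) x <- (x - mean(x)) / s else x <- x - mean(x)
    }
    x
  }, numeric(n))
  timecourse(rowMeans(M), dt, segments = tc_segments(tcs[[1]]),
             provenance = "group_average")
}
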