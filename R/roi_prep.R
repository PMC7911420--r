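# ROI construction and temporal preprocessing: spherical ROIs in MNI mm,
# frequency-domain high-pass filtering, Gaussian spatial smoothing, WM/CSF
# nuisance regression, and mean time-course extraction.

#' Define a spherical ROI in MNI space
#'
#' @param name region label.
#' @param center_mni numeric length-3 MNI (x, y, z) center in mm.
#' @param radius_mm sphere radius in mm (> 0).
#' @return an object of class `sphere_roi`.
#' @export
sphere_roi <- function(name, center_mni, radius_mm) {
  stopifnot(length(center_mni) == 3L, is.numeric(center_mni))
  if (!is.numeric(radius_mm) || radius_mm <= 0)
    stop_mod("sphere_roi", "radius_mm must be > 0")
  structure(list(name = name, center_mni = as.numeric(center_mni),
                 radius_mm = radius_mm), class = "sphere_roi")
}

#' The study's eight small-volume-correction ROI spheres
#'
#' Brainstem/diencephalic spheres (dorsal pons, PAG, hypothalamus, spinal
#' trigeminal nuclei, dorsal raphe) at their literature MNI centers and radii.
#'
#' @return a named list of `sphere_roi` objects (8 entries).
#' @export
svc_roi_table <- function() {
  spec <- list(
    list("left_dorsal_pons",  c(-8, -24, -32), 5),
    list("right_dorsal_pons", c( 8, -24, -32), 5),
    list("left_pag",          c(-2, -28,  -6), 3),
    list("right_pag",         c( 4, -28,  -6), 3),
    list("hypothalamus",      c( 0,   2,  -6), 3),
    list("left_spinal_trigeminal",  c( 4, -40, -55), 3),
    list("right_spinal_trigeminal", c(-4, -40, -55), 3),
    list("dorsal_raphe",      c( 0, -28, -12), 3))
  out <- lapply(spec, function(s) sphere_roi(s[[1]], s[[2]], s[[3]]))
  names(out) <- vapply(spec, `[[`, character(1), 1)
  out
}

#' Rasterize a spherical ROI onto a reference grid
#'
#' A voxel belongs to the mask when its world-space center lies within
#' `radius_mm` (inclusive) of the sphere center.
#'
#' @param sphere a `sphere_roi`.
#' @param reference a `bold_scan` or `label_atlas` supplying grid and affine.
#' @return logical 3D mask.
#' @export
make_sphere_roi <- function(sphere, reference) {
  stopifnot(inherits(sphere, "sphere_roi"))
  dims <- spatial_dims(reference)
  coords <- voxel_world_coords(dims, ref_affine(reference))
  d2 <- (coords[, 1] - sphere$center_mni[1])^2 +
    (coords[, 2] - sphere$center_mni[2])^2 +
    (coords[, 3] - sphere$center_mni[3])^2
  mask <- array(d2 <= sphere$radius_mm^2 + 1e-9, dim = dims)
  if (!any(mask))
    stop_mod("make_sphere_roi",
             "sphere '%s' contains no voxel center on this grid", sphere$name)
  mask
}

# High-pass filtering ----------------------------------------------------------

#' High-pass filter frequency response
#'
#' The documented gain of [highpass()]: 0 at DC and for `f <= cutoff_hz / 2`,
#' a raised-cosine ramp on `(cutoff_hz / 2, cutoff_hz)`, and 1 at and above
#' `cutoff_hz`. The stop band is therefore `[0, cutoff_hz / 2]` with nominal
#' gain 0. The gain applies exactly to the DFT bins of the analysed window:
#' a stop-band sinusoid aligned with a DFT bin is removed completely, while
#' one that completes only a fraction of a cycle in the window (effectively
#' a slow trend) leaks across bins and can retain up to about half its
#' excursion; the filtered output always equals the input DFT multiplied by
#' this response.
#'
#' @param f frequency in Hz (vectorized).
#' @param cutoff_hz high-pass cutoff in Hz.
#' @return gain in `[0, 1]`.
#' @export
highpass_response <- function(f, cutoff_hz) {
  f <- abs(f)
  lo <- cutoff_hz / 2
  g <- ifelse(f >= cutoff_hz, 1,
              ifelse(f <= lo, 0,
                     0.5 * (1 - cos(pi * (f - lo) / (cutoff_hz - lo)))))
  g[f == 0] <- 0
  g
}

#' High-pass filter a time course or BOLD scan
#'
#' Frequency-domain filter applying [highpass_response()] to the DFT of each
#' series. The DC component is removed exactly, so output series are
#' zero-mean; frequencies at or above the cutoff pass unattenuated.
#'
#' @param x a `timecourse` or `bold_scan`.
#' @param cutoff_hz cutoff frequency in Hz (e.g., 0.007 for a 150 s high-pass);
#'   must be below Nyquist.
#' @return filtered object of the same class.
#' @export
highpass <- function(x, cutoff_hz) UseMethod("highpass")

hp_gain_vector <- function(n, dt, cutoff_hz) {
  nyq <- 1 / (2 * dt)
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyq)
    stop_mod("highpass", "cutoff %.4g Hz not in (0, Nyquist = %.4g Hz)",
             cutoff_hz, nyq)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) / (n * dt)   # two-sided DFT frequencies
  highpass_response(f, cutoff_hz)
}

#' @export
highpass.timecourse <- function(x, cutoff_hz) {
  g <- hp_gain_vector(length(x), tc_dt(x), cutoff_hz)
  y <- Re(fft(fft(as.numeric(x)) * g, inverse = TRUE)) / length(x)
  timecourse(y, tc_dt(x), segments = tc_segments(x),
             provenance = attr(x, "provenance"))
}

#' @export
highpass.bold_scan <- function(x, cutoff_hz) {
  d <- dim(x$data)
  g <- hp_gain_vector(d[4], x$tr_s, cutoff_hz)
  m <- t(array(x$data, c(prod(d[1:3]), d[4])))      # time x voxels
  y <- Re(mvfft(mvfft(m) * g, inverse = TRUE)) / d[4]
  bold_scan(array(t(y), d), x$affine, x$tr_s, x$phase_name)
}

# Spatial smoothing ------------------------------------------------------------

#' Gaussian spatial smoothing of a BOLD scan
#'
#' Per-volume separable Gaussian convolution with kernel standard deviation
#' `fwhm_mm / (2 sqrt(2 log 2))` in mm, converted to voxels via the affine
#' column scales. Kernels are renormalized at the grid boundary so constant
#' volumes are preserved. Requires an axis-aligned (orthogonal) affine.
#'
#' @param scan a `bold_scan`.
#' @param fwhm_mm full width at half maximum in mm; 0 returns the scan
#'   unchanged.
#' @return smoothed `bold_scan`.
#' @export
spatial_smooth <- function(scan, fwhm_mm) {
  stopifnot(inherits(scan, "bold_scan"))
  if (!is.numeric(fwhm_mm) || fwhm_mm < 0)
    stop_mod("spatial_smooth", "fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(scan)
  R <- scan$affine[1:3, 1:3]
  if (max(abs(R - diag(diag(R)))) > 1e-6 * max(abs(R)))
    stop_mod("spatial_smooth",
             "non-axis-aligned affine unsupported for smoothing")
  voxdim <- abs(diag(R))
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxdim
  d <- dim(scan$data)
  out <- scan$data
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 1e-6) next
    half <- max(1L, ceiling(4 * s))
    kern <- exp(-((-half:half)^2) / (2 * s^2))
    kern <- kern / sum(kern)
    out <- convolve_axis(out, kern, ax)
  }
  bold_scan(out, scan$affine, scan$tr_s, scan$phase_name)
}

# Convolve a 4D array along spatial axis `ax` with kernel `kern`
# (odd length, sums to 1), renormalizing at the boundary.
convolve_axis <- function(arr, kern, ax) {
  d <- dim(arr)
  n <- d[ax]
  half <- (length(kern) - 1L) / 2L
  K <- matrix(0, n, n)   # row i: weights applied to input positions
  for (i in seq_len(n)) {
    j <- (i - half):(i + half)
    keep <- j >= 1 & j <= n
    w <- kern[keep]
    K[i, j[keep]] <- w / sum(w)
  }
  perm <- c(ax, setdiff(1:4, ax))
  m <- array(aperm(arr, perm), c(n, prod(d[-ax])))
  sm <- K %*% m
  aperm(array(sm, d[perm]), order(perm))
}

# Nuisance regression ----------------------------------------------------------

#' Regress nuisance compartment signals out of a BOLD scan
#'
#' For each voxel series, returns the least-squares residual of a regression
#' on an intercept plus the mean series of each nuisance mask (typically white
#' matter and CSF). Linearly dependent regressors are reported and handled by
#' a pseudo-inverse.
#'
#' @param scan a `bold_scan`.
#' @param nuisance_masks list of logical 3D masks on the scan grid.
#' @return residual `bold_scan` (voxel means removed by the intercept).
#' @export
regress_nuisance <- function(scan, nuisance_masks) {
  stopifnot(inherits(scan, "bold_scan"))
  if (!is.list(nuisance_masks) || length(nuisance_masks) == 0L)
    stop_mod("regress_nuisance", "need at least one nuisance mask")
  d <- dim(scan$data)
  Y <- t(array(scan$data, c(prod(d[1:3]), d[4])))   # time x voxels
  regs <- lapply(seq_along(nuisance_masks), function(i) {
    m <- nuisance_masks[[i]]
    if (!any(m)) stop_mod("regress_nuisance", "nuisance mask %d is empty", i)
    if (!all(dim(m) == d[1:3]))
      stop_mod("regress_nuisance", "nuisance mask %d is off-grid", i)
    rowMeans(Y[, as.vector(m), drop = FALSE])
  })
  X <- cbind(1, do.call(cbind, regs))
  sv <- svd(X)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (rank < ncol(X))
    warning("linearly dependent nuisance regressors; using pseudo-inverse",
            call. = FALSE)
  dinv <- ifelse(sv$d > max(sv$d) * 1e-10, 1 / sv$d, 0)
  beta <- sv$v %*% (dinv * (t(sv$u) %*% Y))
  res <- Y - X %*% beta
  bold_scan(array(t(res), d), scan$affine, scan$tr_s, scan$phase_name)
}

#' Extract the mean time course over a mask
#'
#' Per-volume arithmetic mean of the voxel intensities inside the mask; the
#' sampling interval is inherited from the scan's TR.
#'
#' @param scan a `bold_scan`.
#' @param mask logical 3D mask on the scan grid.
#' @param name provenance label (used in error messages and the result).
#' @return a `timecourse`.
#' @export
extract_mean_timecourse <- function(scan, mask, name = "roi") {
  stopifnot(inherits(scan, "bold_scan"))
  d <- dim(scan$data)
  if (!all(dim(mask) == d[1:3]))
    stop_mod("extract_mean_timecourse", "mask is off-grid for ROI '%s'", name)
  idx <- which(as.vector(mask))
  if (length(idx) == 0L)
    stop_mod("extract_mean_timecourse", "empty mask for ROI '%s'", name)
  Y <- array(scan$data, c(prod(d[1:3]), d[4]))
  timecourse(colMeans(Y[idx, , drop = FALSE]), scan$tr_s,
             provenance = name)
}
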