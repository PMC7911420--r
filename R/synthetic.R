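# Synthetic multi-subject, four-phase BOLD sessions with planted seed blobs,
# a salience-network-like spatial component whose phase relation to the seeds
# follows a per-phase protocol, AR(1) background noise, and WM/CSF nuisance
# compartments. Everything is a pure function of (config, seed), so all
# downstream stages are testable without any acquisition data.

#' Specify one attack phase of the coupling protocol
#'
#' @param phase_name one of `baseline`, `prodrome`, `full_blown`, `recovery`.
#' @param phase_offset_rad planted phase offset (radians, in `(-pi, pi]`) of
#'   the network oscillation relative to the seed oscillation, or the string
#'   `"incoherent"` for an uncoupled phase.
#' @param coupling_snr amplitude of the planted oscillation as a multiple of
#'   the background-noise standard deviation (>= 0).
#' @return an object of class `phase_spec`.
#' @export
phase_spec <- function(phase_name, phase_offset_rad, coupling_snr = 1) {
  phase_name <- match.arg(phase_name,
                          c("baseline", "prodrome", "full_blown", "recovery"))
  if (!identical(phase_offset_rad, "incoherent")) {
    if (!is.numeric(phase_offset_rad) || length(phase_offset_rad) != 1L ||
        phase_offset_rad <= -pi || phase_offset_rad > pi)
      stop_mod("phase_spec",
               "phase_offset_rad must be in (-pi, pi] or \"incoherent\"")
  }
  if (!is.numeric(coupling_snr) || coupling_snr < 0)
    stop_mod("phase_spec", "coupling_snr must be >= 0")
  structure(list(phase_name = phase_name,
                 phase_offset_rad = phase_offset_rad,
                 coupling_snr = coupling_snr), class = "phase_spec")
}

#' Default four-phase coupling protocol
#'
#' Encodes the qualitative seed-network phase sequence observed across an
#' induced attack: antiphase at baseline (pi), seed leading in the prodrome
#' (-pi/2), loss of coherence at full blown (`"incoherent"`), and in-phase
#' coupling at recovery (0).
#'
#' @param coupling_snr planted oscillation amplitude / noise SD for all
#'   phases (default 1).
#' @return list of four `phase_spec` objects.
#' @export
default_phase_protocol <- function(coupling_snr = 1) {
  list(phase_spec("baseline", pi, coupling_snr),
       phase_spec("prodrome", -pi / 2, coupling_snr),
       phase_spec("full_blown", "incoherent", coupling_snr),
       phase_spec("recovery", 0, coupling_snr))
}

#' Synthetic-session configuration
#'
#' Defaults mirror the acquisition this generator emulates: 200 volumes per
#' scan at TR 3.01 s on a 2.5 mm isotropic grid, with a planted 0.05 Hz
#' oscillation (inside the 0.007 Hz high-pass band and below Nyquist).
#'
#' @param n_subjects number of subjects (default 5).
#' @param n_volumes_per_scan volumes per scan (default 200, minimum 8).
#' @param tr_s repetition time in seconds (default 3.01).
#' @param grid_dims 3 voxel counts (default `c(24, 24, 16)`).
#' @param voxel_mm isotropic voxel edge in mm (default 2.5).
#' @param osc_freq_hz planted oscillation frequency (default 0.05; must be
#'   below Nyquist).
#' @param ar1_phi AR(1) noise autocorrelation in `[0, 1)` (default 0.4).
#' @param ar1_sigma AR(1) innovation SD (default 1).
#' @param nuisance_amp compartment nuisance amplitude as a multiple of the
#'   noise SD (default 1).
#' @param spatial_fwhm_mm optional Gaussian smoothing applied to the noise
#'   field (default 0 = spatially independent noise, which keeps analytic
#'   significance calibration valid).
#' @param seed RNG seed for the whole session family.
#' @param phase_protocol list of 4 `phase_spec` (default
#'   [default_phase_protocol()]).
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 5, n_volumes_per_scan = 200,
                         tr_s = 3.01, grid_dims = c(24, 24, 16),
                         voxel_mm = 2.5, osc_freq_hz = 0.05, ar1_phi = 0.4,
                         ar1_sigma = 1, nuisance_amp = 1,
                         spatial_fwhm_mm = 0, seed = 1,
                         phase_protocol = default_phase_protocol()) {
  stopifnot(n_subjects >= 1, length(grid_dims) == 3L)
  if (n_volumes_per_scan < 8)
    stop_mod("synth_config", "n_volumes_per_scan must be >= 8")
  if (any(grid_dims < 1))
    stop_mod("synth_config", "grid dims must be positive")
  if (osc_freq_hz <= 0 || osc_freq_hz >= 1 / (2 * tr_s))
    stop_mod("synth_config", "osc_freq_hz must be in (0, Nyquist = %.4g Hz)",
             1 / (2 * tr_s))
  if (ar1_phi < 0 || ar1_phi >= 1)
    stop_mod("synth_config", "ar1_phi must be in [0, 1)")
  if (ar1_sigma <= 0) stop_mod("synth_config", "ar1_sigma must be > 0")
  if (length(phase_protocol) != 4L ||
      !all(vapply(phase_protocol, inherits, logical(1), "phase_spec")))
    stop_mod("synth_config", "phase_protocol must be 4 phase_spec entries")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_volumes_per_scan = as.integer(n_volumes_per_scan),
                 tr_s = tr_s, grid_dims = as.integer(grid_dims),
                 voxel_mm = voxel_mm, osc_freq_hz = osc_freq_hz,
                 ar1_phi = ar1_phi, ar1_sigma = ar1_sigma,
                 nuisance_amp = nuisance_amp,
                 spatial_fwhm_mm = spatial_fwhm_mm,
                 seed = as.integer(seed), phase_protocol = phase_protocol),
            class = "synth_config")
}

#' Generate a stationary AR(1) series
#'
#' `x_t = phi * x_{t-1} + e_t`, `e_t ~ N(0, sigma^2)`, with `x_1` drawn from
#' the stationary distribution `N(0, sigma^2 / (1 - phi^2))`. This is the red
#' noise model used both as background noise and as the null for the wavelet
#' coherence Monte Carlo test.
#'
#' @param n number of samples (>= 2).
#' @param phi autocorrelation in `[0, 1)`.
#' @param sigma innovation SD (> 0).
#' @param seed RNG seed; the same seed gives identical output.
#' @param dt_s sampling interval attached to the result (default 1).
#' @return a `timecourse`.
#' @export
gen_ar1_series <- function(n, phi, sigma, seed = NULL, dt_s = 1) {
  if (n < 2) stop_mod("gen_ar1_series", "n must be >= 2")
  if (!is.numeric(phi) || phi < 0 || phi >= 1)
    stop_mod("gen_ar1_series", "phi must be in [0, 1)")
  if (sigma <= 0) stop_mod("gen_ar1_series", "sigma must be > 0")
  x <- with_seed(seed, ar1_matrix(n, 1L, phi, sigma))
  timecourse(x[, 1], dt_s, provenance = sprintf("ar1(phi=%.3g)", phi))
}

# Stationary AR(1) noise matrix, n times x nser series; consumes the ambient
# RNG stream (callers wrap in with_seed).
ar1_matrix <- function(n, nser, phi, sigma) {
  x0 <- rnorm(nser, 0, sigma / sqrt(1 - phi^2))
  if (n == 1L) return(matrix(x0, 1L, nser))
  e <- matrix(rnorm((n - 1L) * nser, 0, sigma), n - 1L, nser)
  rest <- stats::filter(e, phi, method = "recursive", init = matrix(x0, 1L))
  rbind(x0, matrix(rest, n - 1L, nser), deparse.level = 0)
}

#' Generate a phase-offset oscillatory pair in AR(1) noise
#'
#' `x_t = sin(2 pi f t dt) + noise`, `y_t = sin(2 pi f t dt + phase_offset) +
#' noise`, with independent AR(1) noise streams scaled so that the oscillation
#' amplitude divided by the noise SD equals `snr`. `snr = Inf` disables the
#' noise and returns pure sinusoids.
#'
#' @param n samples per series.
#' @param dt sampling interval (seconds).
#' @param freq oscillation frequency in Hz, strictly below Nyquist.
#' @param phase_offset offset of `y` relative to `x` in radians.
#' @param snr oscillation amplitude / noise SD (> 0, possibly `Inf`).
#' @param phi AR(1) autocorrelation of the noise (default 0.4).
#' @param seed RNG seed.
#' @return list with `timecourse` elements `x` and `y`.
#' @export
gen_oscillatory_pair <- function(n, dt, freq, phase_offset, snr = Inf,
                                 phi = 0.4, seed = NULL) {
  if (freq <= 0 || freq >= 1 / (2 * dt))
    stop_mod("gen_oscillatory_pair",
             "freq %.4g Hz at/above Nyquist %.4g Hz", freq, 1 / (2 * dt))
  t <- (0:(n - 1)) * dt
  x <- sin(2 * pi * freq * t)
  y <- sin(2 * pi * freq * t + phase_offset)
  if (is.finite(snr)) {
    if (snr <= 0) stop_mod("gen_oscillatory_pair", "snr must be > 0 or Inf")
    noise_sd <- 1 / snr
    sig <- noise_sd * sqrt(1 - phi^2)
    nz <- with_seed(seed, ar1_matrix(n, 2L, phi, sig))
    x <- x + nz[, 1]
    y <- y + nz[, 2]
  }
  list(x = timecourse(x, dt, provenance = "osc_x"),
       y = timecourse(y, dt, provenance = "osc_y"))
}

# Component placement ----------------------------------------------------------

# Voxel-index geometry of the planted components, scaled to the grid.
session_layout <- function(dims) {
  frac <- function(f) round(f * (dims - 1))
  seed_r <- max(1, round(min(dims) / 8))
  list(seed_r = seed_r,
       left_seed = frac(c(0.30, 0.50, 0.50)),
       right_seed = frac(c(0.70, 0.50, 0.50)),
       net_centers = list(frac(c(0.28, 0.20, 0.55)),
                          frac(c(0.72, 0.20, 0.55))),
       net_sigma = 1.5,
       csf_lo = frac(c(0.42, 0.72, 0.42)),
       csf_hi = frac(c(0.58, 0.85, 0.58)))
}

ball_mask <- function(dims, center, radius) {
  i <- array(rep(0:(dims[1] - 1), times = dims[2] * dims[3]), dims)
  j <- array(rep(rep(0:(dims[2] - 1), each = dims[1]), times = dims[3]), dims)
  k <- array(rep(0:(dims[3] - 1), each = dims[1] * dims[2]), dims)
  (i - center[1])^2 + (j - center[2])^2 + (k - center[3])^2 <= radius^2 + 1e-9
}

gaussian_blob <- function(dims, center, sigma, floor = 0.05) {
  i <- array(rep(0:(dims[1] - 1), times = dims[2] * dims[3]), dims)
  j <- array(rep(rep(0:(dims[2] - 1), each = dims[1]), times = dims[3]), dims)
  k <- array(rep(0:(dims[3] - 1), each = dims[1] * dims[2]), dims)
  d2 <- (i - center[1])^2 + (j - center[2])^2 + (k - center[3])^2
  w <- exp(-d2 / (2 * sigma^2))
  w[w < floor] <- 0
  w
}

#' Generate one subject's four-phase synthetic session
#'
#' Builds four scans sharing geometry. Voxels inside the two seed masks carry
#' the seed oscillation; voxels weighted by the network map carry the network
#' oscillation whose phase offset relative to the seed follows that phase's
#' `phase_spec` (an `"incoherent"` phase substitutes an independent AR(1)
#' signal of matched power). Every voxel receives independent AR(1) noise;
#' WM- and CSF-labelled compartments each receive a shared nuisance signal.
#'
#' @param config a `synth_config`.
#' @param subject_index 1-based subject number (changes the noise streams,
#'   not the planted protocol).
#' @return list with elements `scans` (named list of four `bold_scan`),
#'   `atlas` (a `label_atlas` with left/right thalamus, white matter and CSF
#'   labels), and `ground_truth` (seed masks, network weight map, realized
#'   phase schedule, noise parameters, and planted component time-courses per
#'   scan).
#' @export
gen_session <- function(config, subject_index = 1) {
  stopifnot(inherits(config, "synth_config"), subject_index >= 1)
  dims <- config$grid_dims
  lay <- session_layout(dims)

  left <- ball_mask(dims, lay$left_seed, lay$seed_r)
  right <- ball_mask(dims, lay$right_seed, lay$seed_r)
  net <- gaussian_blob(dims, lay$net_centers[[1]], lay$net_sigma) +
    gaussian_blob(dims, lay$net_centers[[2]], lay$net_sigma)
  net_core <- net > 0.5
  shell <- array(TRUE, dims)
  shell[2:(dims[1] - 1), 2:(dims[2] - 1), 2:(dims[3] - 1)] <- FALSE
  csf <- array(FALSE, dims)
  csf[(lay$csf_lo[1]:lay$csf_hi[1]) + 1, (lay$csf_lo[2]:lay$csf_hi[2]) + 1,
      (lay$csf_lo[3]:lay$csf_hi[3]) + 1] <- TRUE
  csf <- csf & !shell

  comps <- list(left, right, net_core, csf)
  overlap <- Reduce(`+`, lapply(comps, function(m) m * 1L))
  if (!all(vapply(comps, any, logical(1))) || any(overlap > 1L) ||
      any(left & shell) || any(right & shell) || any(net_core & shell))
    stop_mod("gen_session",
             "grid %s too small to place all components without overlap",
             paste(dims, collapse = "x"))

  origin <- -(dims - 1) / 2 * config$voxel_mm
  affine <- rbind(cbind(diag(config$voxel_mm, 3), origin), c(0, 0, 0, 1))
  atlas <- label_atlas(
    left * 1L + right * 2L + shell * 3L + csf * 4L, affine,
    data.frame(label = 1:4,
               name = c("left_thalamus", "right_thalamus",
                        "white_matter", "csf")))

  n <- config$n_volumes_per_scan
  tvec <- (0:(n - 1)) * config$tr_s
  noise_sd <- config$ar1_sigma / sqrt(1 - config$ar1_phi^2)
  nvox <- prod(dims)
  phases <- vapply(config$phase_protocol, `[[`, character(1), "phase_name")

  scans <- vector("list", 4L)
  comp_tcs <- vector("list", 4L)
  names(scans) <- names(comp_tcs) <- phases
  for (p in 1:4) {
    ps <- config$phase_protocol[[p]]
    sseed <- derive_seed(config$seed, subject_index, p)
    amp <- ps$coupling_snr * noise_sd
    seed_sig <- amp * sin(2 * pi * config$osc_freq_hz * tvec)
    dat <- with_seed(sseed, {
      if (identical(ps$phase_offset_rad, "incoherent")) {
        net_sig <- (amp / sqrt(2) / noise_sd) *
          ar1_matrix(n, 1L, config$ar1_phi, config$ar1_sigma)[, 1]
      } else {
        net_sig <- amp * sin(2 * pi * config$osc_freq_hz * tvec +
                               ps$phase_offset_rad)
      }
      nuis <- ar1_matrix(n, 2L, config$ar1_phi, config$ar1_sigma) *
        config$nuisance_amp
      noise <- ar1_matrix(n, nvox, config$ar1_phi, config$ar1_sigma)
      vol <- t(noise)                                   # voxels x time
      vol[as.vector(left | right), ] <-
        vol[as.vector(left | right), , drop = FALSE] +
        rep(seed_sig, each = sum(left | right))
      netw <- as.vector(net)
      nz <- which(netw > 0)
      vol[nz, ] <- vol[nz, , drop = FALSE] + outer(netw[nz], net_sig)
      vol[as.vector(shell), ] <- vol[as.vector(shell), , drop = FALSE] +
        rep(nuis[, 1], each = sum(shell))
      vol[as.vector(csf), ] <- vol[as.vector(csf), , drop = FALSE] +
        rep(nuis[, 2], each = sum(csf))
      list(vol = vol, net_sig = net_sig, nuis = nuis)
    })
    scan <- bold_scan(array(dat$vol, c(dims, n)), affine, config$tr_s,
                      phase_name = ps$phase_name)
    if (config$spatial_fwhm_mm > 0)
      scan <- spatial_smooth(scan, config$spatial_fwhm_mm)
    scans[[p]] <- scan
    comp_tcs[[p]] <- list(
      seed = timecourse(seed_sig, config$tr_s, provenance = "seed"),
      network = timecourse(dat$net_sig, config$tr_s, provenance = "network"),
      wm_nuisance = timecourse(dat$nuis[, 1], config$tr_s),
      csf_nuisance = timecourse(dat$nuis[, 2], config$tr_s))
  }

  ground_truth <- structure(list(
    seed_masks = list(left_thalamus = left, right_thalamus = right),
    network_map = net,
    phase_schedule = config$phase_protocol,
    noise_params = c(ar1_phi = config$ar1_phi, ar1_sigma = config$ar1_sigma),
    component_timecourses = comp_tcs), class = "ground_truth")

  list(scans = scans, atlas = atlas, ground_truth = ground_truth)
}
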