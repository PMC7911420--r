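# Full-study orchestration: simulate or ingest four-phase sessions, run the
# static arm (SCA + permutation inference + rcFC), the dynamic arm (group
# ICA -> network time-courses -> concatenation -> wavelet coherence), and
# summarize the clinical workflow.

#' Study configuration
#'
#' @param mode `"synthetic"` (generate sessions from `synth`) or `"nifti"`
#'   (read four NIfTI scans per subject from `paths`).
#' @param synth a `synth_config` (synthetic mode).
#' @param paths nifti mode: list with `scans` (list per subject of 4 NIfTI
#'   paths in phase order), `atlas` (label NIfTI), `atlas_labels` (optional
#'   data.frame), `template` (network template NIfTI), `tr_s`.
#' @param seed_rois character vector of atlas region names used as seeds
#'   (default left/right thalamus).
#' @param highpass_hz high-pass cutoff in Hz (default 0.007; `NULL` skips).
#' @param fwhm_mm spatial smoothing FWHM in mm (default 5; 0 skips).
#' @param nuisance regress WM/CSF compartment means out (default TRUE).
#' @param n_perm sign-flip permutation budget (default 5000).
#' @param alpha significance level for FWE-corrected maps (default 0.05).
#' @param tfce_E,tfce_H,tfce_connectivity TFCE parameters.
#' @param ica_k ICA model order (`NULL` = PCA variance threshold).
#' @param wca a `wca_params`.
#' @param clinical optional `clinical_table` (or path to one).
#' @param seed global RNG seed; all stage seeds derive from it.
#' @return an object of class `study_config`.
#' @export
study_config <- function(mode = c("synthetic", "nifti"), synth = NULL,
                         paths = NULL,
                         seed_rois = c("left_thalamus", "right_thalamus"),
                         highpass_hz = 0.007, fwhm_mm = 5, nuisance = TRUE,
                         n_perm = 5000, alpha = 0.05, tfce_E = 0.5,
                         tfce_H = 2, tfce_connectivity = 26, ica_k = NULL,
                         wca = wca_params(), clinical = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "synthetic") {
    synth <- synth %||% synth_config(seed = seed)
    stopifnot(inherits(synth, "synth_config"))
  } else if (is.null(paths)) {
    stop_mod("study_config", "nifti mode requires paths")
  }
  if (alpha <= 0 || alpha >= 1) stop_mod("study_config", "alpha in (0,1)")
  if (is.character(clinical)) clinical <- read_clinical_table(clinical)
  structure(list(mode = mode, synth = synth, paths = paths,
                 seed_rois = seed_rois, highpass_hz = highpass_hz,
                 fwhm_mm = fwhm_mm, nuisance = nuisance, n_perm = n_perm,
                 alpha = alpha, tfce_E = tfce_E, tfce_H = tfce_H,
                 tfce_connectivity = tfce_connectivity, ica_k = ica_k,
                 wca = wca, clinical = clinical, seed = as.integer(seed)),
            class = "study_config")
}

phase_order <- c("baseline", "prodrome", "full_blown", "recovery")

load_sessions <- function(config) {
  if (config$mode == "synthetic") {
    sessions <- lapply(seq_len(config$synth$n_subjects), function(s)
      gen_session(config$synth, s))
    template <- sessions[[1]]$ground_truth$network_map
    list(sessions = sessions, atlas = sessions[[1]]$atlas,
         template = template)
  } else {
    p <- config$paths
    # validate the phase structure before touching any file
    for (s in seq_along(p$scans))
      if (length(p$scans[[s]]) != 4L)
        stop_mod("run_study", "subject %d: expected 4 phase scans, got %d",
                 s, length(p$scans[[s]]))
    atlas <- read_atlas_nifti(p$atlas, p$atlas_labels %||% NULL)
    sessions <- lapply(seq_along(p$scans), function(s) {
      files <- p$scans[[s]]
      scans <- lapply(seq_len(4L), function(i)
        read_bold_nifti(files[[i]], tr_s = p$tr_s %||% NULL,
                        phase_name = phase_order[i]))
      names(scans) <- phase_order
      list(scans = scans, atlas = atlas, ground_truth = NULL)
    })
    template <- as.array(RNifti::readNifti(p$template))
    list(sessions = sessions, atlas = atlas, template = template)
  }
}

preprocess_scan <- function(scan, atlas, config) {
  if (!is.null(config$fwhm_mm) && config$fwhm_mm > 0)
    scan <- spatial_smooth(scan, config$fwhm_mm)
  if (!is.null(config$highpass_hz))
    scan <- highpass(scan, config$highpass_hz)
  if (isTRUE(config$nuisance)) {
    masks <- list()
    for (nm in c("white_matter", "csf"))
      if (nm %in% atlas$label_table$name)
        masks[[nm]] <- atlas_mask(atlas, nm)
    if (length(masks)) scan <- regress_nuisance(scan, masks)
  }
  scan
}

#' Run the full static + dynamic connectivity study
#'
#' Executes preprocessing, then per seed the static arm (per-subject,
#' per-phase seed correlation maps; group mean-effect inference by sign-flip
#' permutation with TFCE/FWE; per-phase meanFC over the FWE-significant
#' mask; rcFC with its repeated-measures comparison), then the dynamic arm
#' (group spatial ICA on the temporally concatenated data, network selection
#' against the template, per-scan network time-courses by dual regression,
#' per-subject concatenation to the session-long signal, subject averaging,
#' and wavelet coherence of each seed signal against the network with Monte
#' Carlo red-noise significance and per-segment phase summaries). Fully
#' reproducible given the configuration.
#'
#' @param config a `study_config` (exactly 4 phase scans per subject).
#' @return an object of class `study_result`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  loaded <- load_sessions(config)
  sessions <- loaded$sessions
  atlas <- loaded$atlas
  n_sub <- length(sessions)
  for (s in seq_len(n_sub))
    if (length(sessions[[s]]$scans) != 4L)
      stop_mod("run_study", "subject %d has %d phases; exactly 4 required",
               s, length(sessions[[s]]$scans))

  pp <- lapply(sessions, function(ses)
    lapply(ses$scans, preprocess_scan, atlas = atlas, config = config))

  seed_masks <- lapply(config$seed_rois, function(nm) atlas_mask(atlas, nm))
  names(seed_masks) <- config$seed_rois

  # --- static arm: SCA + group inference + rcFC --------------------------
  sca_results <- list()
  for (seed_nm in config$seed_rois) {
    maps <- list()       # maps[[phase]][[subject]]
    for (ph in phase_order) maps[[ph]] <- vector("list", n_sub)
    for (s in seq_len(n_sub)) {
      for (ph in phase_order) {
        scan <- pp[[s]][[ph]]
        tc <- extract_mean_timecourse(scan, seed_masks[[seed_nm]], seed_nm)
        maps[[ph]][[s]] <- seed_correlation_map(scan, tc, seed_nm,
                                                subject_id = as.character(s))
      }
    }
    group <- list()
    subject_fc <- NULL
    for (ph in phase_order) {
      gs <- group_mean_effect(maps[[ph]], n_perm = config$n_perm,
                              seed = derive_seed(config$seed, 101,
                                                 match(ph, phase_order)),
                              E = config$tfce_E, H = config$tfce_H,
                              connectivity = config$tfce_connectivity)
      group[[ph]] <- gs
      sig <- gs$fwe_p < config$alpha
      fc <- vapply(seq_len(n_sub), function(s) {
        if (!any(sig)) return(NA_real_)
        tryCatch(mean_fc_over_mask(maps[[ph]][[s]], sig),
                 error = function(e) NA_real_)
      }, numeric(1))
      subject_fc <- rbind(subject_fc,
                          data.frame(subject = seq_len(n_sub), phase = ph,
                                     mean_fc = fc))
    }
    tab <- if (all(is.finite(subject_fc$mean_fc)))
      rcfc_table(subject_fc) else NULL
    cmp <- if (!is.null(tab) && n_sub >= 2)
      tryCatch(compare_rcfc(subject_fc), error = function(e) NULL) else NULL
    sca_results[[seed_nm]] <- list(group_stats = group, subject_fc =
                                     subject_fc, rcfc = tab,
                                   comparison = cmp)
  }

  # --- dynamic arm: ICA -> network time-courses -> WCA -------------------
  data_mat <- temporal_concat_group(pp)
  decomp <- group_spatial_ica(data_mat, k = config$ica_k,
                              seed = derive_seed(config$seed, 202))
  sel <- select_network(decomp, loaded$template)

  net_concat <- lapply(seq_len(n_sub), function(s) {
    parts <- lapply(phase_order, function(ph)
      network_timecourse(sel$map, pp[[s]][[ph]]))
    concatenate_timecourses(parts, phase_order)
  })
  net_avg <- average_across_subjects(net_concat)

  wca_results <- list()
  for (seed_nm in config$seed_rois) {
    seed_concat <- lapply(seq_len(n_sub), function(s) {
      parts <- lapply(phase_order, function(ph)
        extract_mean_timecourse(pp[[s]][[ph]], seed_masks[[seed_nm]],
                                seed_nm))
      concatenate_timecourses(parts, phase_order)
    })
    seed_avg <- average_across_subjects(seed_concat)
    wp <- config$wca
    wp$seed <- wp$seed %||% derive_seed(config$seed, 303,
                                        match(seed_nm, config$seed_rois))
    w <- wtc(seed_avg, net_avg, wp, significance = TRUE)
    wca_results[[seed_nm]] <- list(wtc = w,
                                   phase_summary = segment_phase_summary(w),
                                   seed_signal = seed_avg,
                                   network_signal = net_avg)
  }

  clinical <- if (!is.null(config$clinical))
    summarize_clinical(config$clinical) else NULL

  structure(list(sca = sca_results, network = list(decomposition = decomp,
                                                   selection = sel),
                 wca = wca_results, clinical = clinical, atlas = atlas,
                 config = config,
                 provenance = list(config_hash = config_hash(config),
                                   seed = config$seed,
                                   r_version = R.version.string,
                                   package_version =
                                     as.character(utils::packageVersion("dynfc")))),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> config %s, %d seed(s)\n",
              x$provenance$config_hash, length(x$sca)))
  for (nm in names(x$wca)) {
    cat(sprintf("  %s vs network, dominant classes: %s\n", nm,
                paste(x$wca[[nm]]$phase_summary$dominant_class,
                      collapse = ", ")))
  }
  invisible(x)
}

#' Write study outputs to a directory
#'
#' Group statistic and subject mean maps as NIfTI; rcFC, phase summaries and
#' clinical summary as TSV; each coherence result's fields (R^2, phase, COI,
#' significance mask, scales, thresholds) as TSV matrices; plus a JSON
#' manifest with the config hash and per-file MD5 checksums.
#'
#' @param result a `study_result`.
#' @param outdir output directory.
#' @param force overwrite an existing non-empty directory (default FALSE).
#' @return the manifest, invisibly.
#' @export
write_outputs <- function(result, outdir, force = FALSE) {
  stopifnot(inherits(result, "study_result"))
  if (dir.exists(outdir) && length(dir(outdir)) > 0 && !force)
    stop_mod("write_outputs", "'%s' exists and is not empty (use force)",
             outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  aff <- result$atlas$affine
  put_tsv <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
  }
  put_mat <- function(m, name) put_tsv(as.data.frame(m), name)

  for (seed_nm in names(result$sca)) {
    res <- result$sca[[seed_nm]]
    for (ph in names(res$group_stats)) {
      gs <- res$group_stats[[ph]]
      path <- file.path(outdir, sprintf("%s_%s_tstat.nii.gz", seed_nm, ph))
      write_nifti_volume(gs$tstat, aff, path)
      files <- c(files, path)
      path <- file.path(outdir, sprintf("%s_%s_fwep.nii.gz", seed_nm, ph))
      write_nifti_volume(gs$fwe_p, aff, path)
      files <- c(files, path)
    }
    if (!is.null(res$rcfc))
      put_tsv(as.data.frame(res$rcfc), sprintf("%s_rcfc.tsv", seed_nm))
    put_tsv(res$subject_fc, sprintf("%s_subject_fc.tsv", seed_nm))
  }
  for (seed_nm in names(result$wca)) {
    w <- result$wca[[seed_nm]]$wtc
    base <- sprintf("wtc_%s", seed_nm)
    put_mat(w$rsq, paste0(base, "_rsq.tsv"))
    put_mat(w$phase, paste0(base, "_phase.tsv"))
    put_mat(w$sig_mask * 1L, paste0(base, "_sig.tsv"))
    put_tsv(data.frame(scale_s = w$scales, fourier_period_s =
                         w$fourier_periods,
                       threshold = w$thresholds %||% NA_real_),
            paste0(base, "_scales.tsv"))
    put_tsv(data.frame(time_s = w$times, coi_period_s = w$coi),
            paste0(base, "_coi.tsv"))
    put_tsv(result$wca[[seed_nm]]$phase_summary,
            paste0(base, "_phase_summary.tsv"))
  }
  if (!is.null(result$clinical)) {
    cs <- result$clinical
    put_tsv(data.frame(measure = names(cs$medians),
                       median = unname(cs$medians)),
            "clinical_summary.tsv")
  }
  manifest <- list(config_hash = result$provenance$config_hash,
                   seed = result$provenance$seed,
                   package_version = result$provenance$package_version,
                   files = lapply(files, function(f)
                     list(path = basename(f),
                          md5 = unname(tools::md5sum(f)))))
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
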