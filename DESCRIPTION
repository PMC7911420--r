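Package: dynfc
Title: Static and Dynamic Seed-Based Functional Connectivity with Wavelet
    Coherence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the functional coupling between a seed
    region (e.g., the thalamus) and a cortical network (e.g., the salience
    network) evolves across the phases of a provoked migraine attack in
    resting-state BOLD fMRI. Implements the static arm (spherical ROI
    construction in MNI space, high-pass filtering, spatial smoothing,
    nuisance regression, voxelwise seed correlation maps, sign-flip
    permutation inference with threshold-free cluster enhancement and
    family-wise error control, and a baseline-normalised relative change in
    functional connectivity index with repeated-measures comparison) and the
    dynamic arm (group spatial ICA with template-based network selection,
    dual-regression network time-courses, continuous Morlet wavelet
    transform, wavelet transform coherence with phase, cone of influence,
    and Monte Carlo red-noise significance testing). A synthetic multi-
    subject four-phase BOLD generator with planted phase-coupling structure
    supports end-to-end validation without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    graphics,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
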