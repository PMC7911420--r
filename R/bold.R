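# BOLD scan and label atlas containers, with NIfTI-backed I/O via RNifti.
# Voxel indices are 0-based throughout; world coordinates (MNI mm) are
# voxel-to-world through the 4x4 affine: world = A %*% c(i, j, k, 1).

#' Construct a BOLD scan
#'
#' @param data 4D numeric array indexed `(i, j, k, t)`.
#' @param affine 4x4 voxel-to-world (MNI mm) matrix; last row `c(0,0,0,1)`.
#' @param tr_s repetition time in seconds.
#' @param phase_name attack-phase label (free text).
#' @return an object of class `bold_scan`.
#' @export
bold_scan <- function(data, affine, tr_s, phase_name = "") {
  data <- as.array(data)
  if (length(dim(data)) != 4L)
    stop_mod("bold_scan", "data must be a 4D (i,j,k,t) array")
  if (dim(data)[4] < 2L)
    stop_mod("bold_scan", "need at least 2 volumes")
  if (!all(is.finite(data)))
    stop_mod("bold_scan", "non-finite intensities")
  affine <- check_affine(affine)
  if (!is.numeric(tr_s) || tr_s <= 0)
    stop_mod("bold_scan", "tr_s must be positive")
  structure(list(data = data, affine = affine, tr_s = tr_s,
                 phase_name = phase_name), class = "bold_scan")
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop_mod("geometry", "affine must be 4x4")
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop_mod("geometry", "affine is singular")
  affine
}

#' @export
print.bold_scan <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_scan> %dx%dx%d voxels x %d volumes, TR = %.4g s%s\n",
              d[1], d[2], d[3], d[4], x$tr_s,
              if (nzchar(x$phase_name)) paste0(" [", x$phase_name, "]") else ""))
  invisible(x)
}

#' Construct a label atlas
#'
#' @param labels 3D integer array of region labels (0 = background).
#' @param affine 4x4 voxel-to-world matrix.
#' @param label_table data.frame with columns `label` (integer) and `name`;
#'   every nonzero label present in `labels` must appear.
#' @return an object of class `label_atlas`.
#' @export
label_atlas <- function(labels, affine, label_table) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    stop_mod("label_atlas", "labels must be a 3D array")
  affine <- check_affine(affine)
  label_table <- as.data.frame(label_table)
  stopifnot(all(c("label", "name") %in% names(label_table)))
  present <- setdiff(unique(as.vector(labels)), 0)
  missing <- setdiff(present, label_table$label)
  if (length(missing))
    stop_mod("label_atlas", "labels missing from table: %s",
             paste(missing, collapse = ", "))
  structure(list(labels = labels, affine = affine,
                 label_table = label_table), class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_atlas> %dx%dx%d voxels, %d regions\n", d[1], d[2], d[3],
              nrow(x$label_table)))
  invisible(x)
}

#' Extract a binary mask for one atlas region
#'
#' @param atlas a `label_atlas`.
#' @param region region name or integer label.
#' @return logical 3D array.
#' @export
atlas_mask <- function(atlas, region) {
  stopifnot(inherits(atlas, "label_atlas"))
  if (is.character(region)) {
    hit <- atlas$label_table$label[atlas$label_table$name == region]
    if (length(hit) != 1L)
      stop_mod("label_atlas", "region '%s' not found", region)
    region <- hit
  }
  atlas$labels == region
}

# Spatial geometry helpers ----------------------------------------------------

spatial_dims <- function(x) {
  if (inherits(x, "bold_scan")) dim(x$data)[1:3]
  else if (inherits(x, "label_atlas")) dim(x$labels)
  else stop_mod("geometry", "reference must be a bold_scan or label_atlas")
}

ref_affine <- function(x) x$affine

same_geometry <- function(a, b) {
  all(spatial_dims(a) == spatial_dims(b)) &&
    all(abs(ref_affine(a) - ref_affine(b)) < 1e-6)
}

# World coordinates (mm) of every voxel center, rows in array order.
voxel_world_coords <- function(dims, affine) {
  idx <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                               k = 0:(dims[3] - 1)))
  t(affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
}

# NIfTI I/O --------------------------------------------------------------------

#' Read a 4D NIfTI volume as a BOLD scan
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param tr_s repetition time override; defaults to the header pixdim.
#' @param phase_name attack-phase label.
#' @return a `bold_scan`.
#' @export
read_bold_nifti <- function(path, tr_s = NULL, phase_name = "") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L)
    stop_mod("nifti", "%s is not 4D", path)
  aff <- structure(RNifti::xform(img), class = NULL)
  if (is.null(tr_s)) {
    pd <- RNifti::pixdim(img)
    tr_s <- if (length(pd) >= 4L && pd[4] > 0) pd[4] else
      stop_mod("nifti", "TR not present in header; pass tr_s")
  }
  bold_scan(arr, aff, tr_s, phase_name)
}

#' Read a 3D NIfTI label volume as an atlas
#'
#' @param path NIfTI file.
#' @param label_table data.frame with `label`, `name` columns; if `NULL`, names
#'   are auto-generated as `region_<label>`.
#' @return a `label_atlas`.
#' @export
read_atlas_nifti <- function(path, label_table = NULL) {
  img <- RNifti::readNifti(path)
  arr <- round(as.array(img))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  aff <- structure(RNifti::xform(img), class = NULL)
  if (is.null(label_table)) {
    labs <- sort(setdiff(unique(as.vector(arr)), 0))
    label_table <- data.frame(label = labs,
                              name = sprintf("region_%d", labs))
  }
  label_atlas(arr, aff, label_table)
}

#' Write a 3D/4D array to NIfTI with a given affine
#'
#' @param arr array to write.
#' @param affine 4x4 voxel-to-world matrix.
#' @param path output path (.nii or .nii.gz).
#' @param tr_s optional repetition time stored in pixdim4.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(arr, affine, path, tr_s = NULL) {
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  img <- RNifti::asNifti(as.array(arr), reference = list(
    pixdim = c(1, vox, tr_s %||% 1, 0, 0, 0)))
  RNifti::sform(img) <- structure(affine, code = 4L)
  RNifti::qform(img) <- structure(affine, code = 4L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
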