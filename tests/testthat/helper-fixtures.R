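# Shared fixtures: small grids, reference geometries, and brute-force
# oracles used across the module tests.

# A bare reference geometry (empty label atlas) with the given dims/affine.
blank_reference <- function(dims, affine) {
  label_atlas(array(0L, dims), affine,
              data.frame(label = integer(), name = character()))
}

# Axis-aligned affine with voxel size `vox` mm and world origin `origin`
# (world coordinate of voxel (0,0,0)).
make_affine <- function(vox = 2.5, origin = c(0, 0, 0)) {
  rbind(cbind(diag(vox, 3), origin), c(0, 0, 0, 1))
}

# Reference grid with 2.5 mm voxels whose centers lie on multiples of 2.5 mm,
# covering the brainstem/diencephalic MNI coordinates of the ROI table.
mni_reference <- function() {
  blank_reference(c(20, 26, 30), make_affine(2.5, c(-25, -55, -70)))
}

# Exhaustive distance oracle: count voxels whose center is within radius of
# the sphere center, enumerating every voxel on the grid.
brute_force_sphere_count <- function(dims, affine, center, radius) {
  count <- 0L
  for (i in 0:(dims[1] - 1))
    for (j in 0:(dims[2] - 1))
      for (k in 0:(dims[3] - 1)) {
        w <- affine %*% c(i, j, k, 1)
        if (sum((w[1:3] - center)^2) <= radius^2 + 1e-9) count <- count + 1L
      }
  count
}

# Random scan fixture.
tiny_scan <- function(dims = c(5, 5, 4), nt = 30, tr = 2, seed = 1,
                      phase_name = "baseline") {
  set.seed(seed)
  bold_scan(array(rnorm(prod(dims) * nt), c(dims, nt)),
            make_affine(2.5, -dims * 2.5 / 2), tr, phase_name)
}

# Wrap a plain statistic volume as an sca_map (for group-level tests).
as_sca_map <- function(vol, phase = "baseline", seed_name = "seed",
                       subject = "", fisher = TRUE) {
  structure(list(r = vol, affine = make_affine(),
                 zero_variance = array(FALSE, dim(vol)),
                 seed_name = seed_name, phase_name = phase,
                 subject_id = subject, fisher_z = fisher),
            class = "sca_map")
}

# Discrete TFCE sum oracle for an isolated single-voxel peak of height h0:
# sum over thresholds h = dh, 2dh, ... <= h0 of 1^E * h^H * dh.
tfce_single_voxel_oracle <- function(h0, E, H, dh) {
  h <- seq(dh, h0 + 1e-12, by = dh)
  sum(1^E * h^H * dh)
}
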