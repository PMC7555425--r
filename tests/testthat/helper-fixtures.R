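# Small fixtures built in code.

# A block mask: 1s on [x1..x2] x [y1..y2] x [z1..z2].
block_mask <- function(dm, x, y, z, spacing = c(1, 1, 1)) {
  vox <- array(0L, dm)
  vox[x, y, z] <- 1L
  seg_mask(vox, spacing = spacing)
}

# Random connected-ish blob mask on a small grid (thresholded smooth noise
# around a seeded ball); always nonempty.
random_blob_mask <- function(dm = c(12, 12, 12), spacing = c(1, 1, 1)) {
  ctr <- dm / 2 + stats::runif(3, -1.5, 1.5)
  rad <- stats::runif(3, dm[1] / 5, dm[1] / 2.8)
  ax1 <- ((seq_len(dm[1]) - ctr[1]) / rad[1])^2
  ax2 <- ((seq_len(dm[2]) - ctr[2]) / rad[2])^2
  ax3 <- ((seq_len(dm[3]) - ctr[3]) / rad[3])^2
  r2 <- outer(outer(ax1, ax2, `+`), ax3, `+`)
  noise <- array(stats::rnorm(prod(dm), sd = 0.25), dm)
  vox <- array(as.integer(r2 + noise <= 1), dm)
  if (sum(vox) == 0) vox[ceiling(dm[1] / 2), ceiling(dm[2] / 2), ceiling(dm[3] / 2)] <- 1L
  seg_mask(vox, spacing = spacing)
}

# Random labelled ROI (0 = outside) for texture oracles.
random_label_roi <- function(dm = c(5, 5, 5), n_levels = 3, p_in = 0.7) {
  L <- array(0L, dm)
  inmask <- stats::runif(prod(dm)) < p_in
  if (!any(inmask)) inmask[1] <- TRUE
  L[inmask] <- sample.int(n_levels, sum(inmask), replace = TRUE)
  L
}

# Wrap a label array as a discretized_roi so package texture code accepts it.
roi_from_labels <- function(L) {
  structure(list(labels = L, levels = sort(unique(L[L > 0])),
                 n_bins = max(L), bin_width = 1, n_voxels = sum(L > 0)),
            class = "discretized_roi")
}

small_phantom_spec <- function(seed = 1L, grid = c(32L, 32L, 32L)) {
  phantom_spec(grid_shape = grid, ellipsoid_radii = c(9, 10, 8), seed = seed)
}

# A valid metric panel crafted directly from values (all cells valid).
panel_from_values <- function(values) {
  nm <- c(outer(c("whole", "apex", "base"), c("DSC", "aRVD", "HD95", "ASD"),
                paste, sep = "_"))
  structure(setNames(as.numeric(values), nm),
            valid = setNames(rep(TRUE, 12), nm),
            class = c("metric_panel", "numeric"))
}
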