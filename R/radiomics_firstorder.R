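# Frozen feature-name orders: class order first-order, shape, glcm, glrlm,
# glszm, gldm, ngtdm; alphabetical within class. The trained model stores
# coefficients by position, so this order must never change.
FIRSTORDER_NAMES <- c(
  "10Percentile", "90Percentile", "Energy", "Entropy", "InterquartileRange",
  "Kurtosis", "Maximum", "Mean", "MeanAbsoluteDeviation", "Median", "Minimum",
  "Range", "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
  "TotalEnergy", "Uniformity", "Variance")

SHAPE_NAMES <- c(
  "Elongation", "Flatness", "LeastAxisLength", "MajorAxisLength",
  "Maximum2DDiameterColumn", "Maximum2DDiameterRow", "Maximum2DDiameterSlice",
  "Maximum3DDiameter", "MeshVolume", "MinorAxisLength", "Sphericity",
  "SurfaceArea", "SurfaceVolumeRatio", "VoxelVolume")

#' Fixed-bin-width intensity discretization of a region of interest
#'
#' Assigns each in-mask voxel the integer gray level
#' `floor((x - min_in_mask) / bin_width) + 1`, i.e. fixed-width bins anchored
#' at the in-mask minimum, so all labels are >= 1 and the discretization is
#' invariant to a constant intensity shift. Bin width 64 is the package
#' default throughout, matching a large-ROI setting.
#'
#' @param volume An [image_volume()].
#' @param mask A nonempty [seg_mask()] on the same grid.
#' @param bin_width Positive bin width in intensity units.
#' @return A `discretized_roi`: list with `labels` (integer array, 0 outside
#'   the mask), `levels` (sorted distinct labels present), `n_bins`
#'   (`max(labels)`), `bin_width`, `n_voxels`.
#' @export
discretize <- function(volume, mask, bin_width = 64) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "seg_mask"))
  check_same_grid(volume, mask)
  if (is_empty_mask(mask)) stop("cannot discretize an empty mask")
  if (!is.finite(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  sel <- mask$voxels == 1L
  x <- volume$intensities[sel]
  lab <- as.integer(floor((x - min(x)) / bin_width)) + 1L
  labels <- array(0L, dim(mask$voxels))
  labels[sel] <- lab
  structure(list(labels = labels, levels = sort(unique(lab)),
                 n_bins = max(lab), bin_width = bin_width,
                 n_voxels = length(lab)),
            class = "discretized_roi")
}

#' First-order intensity statistics (18 features)
#'
#' The standard first-order panel over in-mask intensities. Entropy and
#' Uniformity are computed on the fixed-bin-width discretized histogram;
#' everything else on raw intensities. Conventions for degenerate ROIs:
#' zero-variance skewness and kurtosis are 0; kurtosis is the uncorrected
#' `m4 / m2^2` form (3 for a normal distribution); variance is the
#' population variance.
#'
#' @param volume An [image_volume()].
#' @param mask A nonempty [seg_mask()].
#' @param bin_width Bin width for the entropy/uniformity histogram.
#' @return Named numeric vector of the 18 features.
#' @export
first_order_features <- function(volume, mask, bin_width = 64) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "seg_mask"))
  check_same_grid(volume, mask)
  if (is_empty_mask(mask)) stop("first-order features of an empty mask")
  x <- volume$intensities[mask$voxels == 1L]
  n <- length(x)
  voxvol <- prod(volume$spacing)
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90),
                       names = FALSE, type = 7)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  robust <- x[x >= q[1] & x <= q[5]]
  disc <- discretize(volume, mask, bin_width)
  p <- tabulate(disc$labels[disc$labels > 0L]) / n
  p <- p[p > 0]
  stats::setNames(c(
    q[1],                                   # 10Percentile
    q[5],                                   # 90Percentile
    sum(x^2),                               # Energy
    -sum(p * log2(p)),                      # Entropy
    q[4] - q[2],                            # InterquartileRange
    if (m2 > 0) m4 / m2^2 else 0,           # Kurtosis
    max(x),                                 # Maximum
    mu,                                     # Mean
    mean(abs(x - mu)),                      # MeanAbsoluteDeviation
    q[3],                                   # Median
    min(x),                                 # Minimum
    max(x) - min(x),                        # Range
    mean(abs(robust - mean(robust))),       # RobustMeanAbsoluteDeviation
    sqrt(mean(x^2)),                        # RootMeanSquared
    if (m2 > 0) m3 / m2^1.5 else 0,         # Skewness
    voxvol * sum(x^2),                      # TotalEnergy
    sum(p^2),                               # Uniformity
    m2                                      # Variance
  ), FIRSTORDER_NAMES)
}

#' 3D shape descriptors (14 features)
#'
#' Mesh-based surface area and volume come from a watertight triangulated
#' isosurface of the binary mask (marching tetrahedra at level 0.5, vertices
#' at voxel-edge midpoints); diameters are maximal pairwise Euclidean
#' distances between surface voxel centers (overall and within planes
#' orthogonal to each axis); axis lengths are `4 * sqrt(eigenvalue)` of the
#' population covariance of the physical voxel-center coordinates. All in
#' physical units from the spacing. Masks with fewer than 2 voxels get 0 for
#' the eigenvalue-based features (degenerate convention).
#'
#' @param mask A nonempty [seg_mask()].
#' @return Named numeric vector of the 14 features.
#' @export
shape_features <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  if (is_empty_mask(mask)) stop("shape features of an empty mask")
  dm <- dim(mask$voxels)
  sp <- mask$spacing
  av <- cpp_mesh_area_volume(as.integer(mask$voxels), as.integer(dm),
                             as.numeric(sp))
  area <- av[1]; meshvol <- av[2]
  nvox <- sum(mask$voxels)
  voxvol <- nvox * prod(sp)
  sphericity <- if (area > 0) (36 * pi * meshvol^2)^(1 / 3) / area else 0
  sv_ratio <- if (meshvol > 0) area / meshvol else 0

  surf <- surface_voxels(mask)
  pts <- sweep(surf, 2, sp, `*`)
  d3 <- cpp_max_pairwise_dist(pts)
  plane_diam <- function(fix_axis) {
    best <- 0
    for (v in unique(surf[, fix_axis])) {
      sub <- pts[surf[, fix_axis] == v, , drop = FALSE]
      if (nrow(sub) >= 2) {
        sub[, fix_axis] <- 0
        best <- max(best, cpp_max_pairwise_dist(sub))
      }
    }
    best
  }

  coords <- which(mask$voxels == 1L, arr.ind = TRUE)
  phys <- sweep(coords, 2, sp, `*`)
  if (nrow(phys) >= 2) {
    cen <- sweep(phys, 2, colMeans(phys))
    ev <- sort(pmax(eigen(crossprod(cen) / nrow(phys),
                          symmetric = TRUE)$values, 0), decreasing = TRUE)
  } else ev <- c(0, 0, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])

  stats::setNames(c(
    if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,  # Elongation
    if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0,  # Flatness
    least, major,
    plane_diam(2),                              # Maximum2DDiameterColumn
    plane_diam(1),                              # Maximum2DDiameterRow
    plane_diam(3),                              # Maximum2DDiameterSlice
    d3,                                         # Maximum3DDiameter
    meshvol, minor, sphericity, area, sv_ratio,
    voxvol                                      # VoxelVolume
  ), SHAPE_NAMES)
}
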