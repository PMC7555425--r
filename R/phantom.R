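# Morphological erosion/dilation of a binary array with an explicit offset set.
morpho_op <- function(vox, offsets, op = c("erode", "dilate")) {
  op <- match.arg(op)
  acc <- vox
  for (d in offsets) {
    sh <- shift_array(vox, d)
    acc <- if (op == "erode") acc * sh else pmax(acc, sh)
  }
  array(as.integer(acc), dim(vox))
}

# Periodic Gaussian smoothing of a 3D array via FFT. Adequate here because
# every structure of interest sits well inside the grid.
gaussian_smooth3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  dm <- dim(arr)
  kern1 <- function(n) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * sigma^2))
    k / sum(k)
  }
  K <- outer(outer(kern1(dm[1]), kern1(dm[2])), kern1(dm[3]))
  out <- Re(stats::fft(stats::fft(arr) * stats::fft(K), inverse = TRUE)) /
    prod(dm)
  array(out, dm)
}

#' Specification of a synthetic prostate-like phantom
#'
#' Defines an ellipsoidal "gland" embedded in a textured background, emulating
#' the geometry and two-compartment contrast of a transverse T2-weighted
#' prostate volume. Intensity means/SDs are arbitrary units chosen so that a
#' fixed bin width of 64 yields several gray levels inside the gland.
#'
#' @param grid_shape Integer length-3 voxel grid size.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @param ellipsoid_center Numeric length-3 center in voxel coordinates
#'   (0-based); default grid center.
#' @param ellipsoid_radii Numeric length-3 semi-axes in mm.
#' @param intensity_params List with `prostate_mean`, `prostate_sd`,
#'   `pz_mean`, `pz_sd` (brighter peripheral-zone shell), `background_mean`,
#'   `background_sd`.
#' @param texture_params List with `correlation_length` (voxels, SD of the
#'   Gaussian smoothing of the multiplicative noise field) and
#'   `multiplicative_sd` (relative SD of that field).
#' @param seed Integer; all randomness is a pure function of it.
#' @return A `phantom_spec` list, validated (the ellipsoid must fit inside
#'   the grid).
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         spacing = c(1, 1, 1),
                         ellipsoid_center = (grid_shape - 1) / 2,
                         ellipsoid_radii = c(20, 25, 22),
                         intensity_params = list(
                           prostate_mean = 180, prostate_sd = 28,
                           pz_mean = 300, pz_sd = 40,
                           background_mean = 60, background_sd = 18),
                         texture_params = list(
                           correlation_length = 2, multiplicative_sd = 0.12),
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0L),
            length(spacing) == 3L, all(spacing > 0),
            length(ellipsoid_center) == 3L,
            length(ellipsoid_radii) == 3L, all(ellipsoid_radii > 0))
  radii_vox <- ellipsoid_radii / spacing
  lo <- ellipsoid_center - radii_vox
  hi <- ellipsoid_center + radii_vox
  if (any(lo < 0) || any(hi > grid_shape - 1))
    stop("ellipsoid exceeds grid bounds: center ", paste(ellipsoid_center, collapse = ","),
         " with radii ", paste(ellipsoid_radii, collapse = ","),
         " mm does not fit a ", paste(grid_shape, collapse = "x"), " grid")
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 ellipsoid_center = as.numeric(ellipsoid_center),
                 ellipsoid_radii = as.numeric(ellipsoid_radii),
                 intensity_params = intensity_params,
                 texture_params = texture_params,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic T2W-like volume and its gold-standard mask
#'
#' The mask is the voxelized ellipsoid of the spec. The image assigns the
#' gland, a peripheral-zone shell (outer 25% of the normalized ellipsoid
#' radius) and the background their own mean/SD, then applies a spatially
#' correlated multiplicative noise field plus white noise. Identical seeds
#' give bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` ([image_volume()]) and `mask` ([seg_mask()]).
#' @examples
#' p <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 32),
#'                                    ellipsoid_radii = c(9, 10, 8)))
#' mask_volume_mm3(p$mask)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape
  radii_vox <- spec$ellipsoid_radii / spec$spacing
  cx <- spec$ellipsoid_center
  ax1 <- (seq_len(dm[1]) - 1 - cx[1]) / radii_vox[1]
  ax2 <- (seq_len(dm[2]) - 1 - cx[2]) / radii_vox[2]
  ax3 <- (seq_len(dm[3]) - 1 - cx[3]) / radii_vox[3]
  r2 <- outer(outer(ax1^2, ax2^2, `+`), ax3^2, `+`)
  vox <- array(as.integer(r2 <= 1), dm)
  ip <- spec$intensity_params
  tp <- spec$texture_params
  img <- with_seed(spec$seed, {
    mean_map <- array(ip$background_mean, dm)
    sd_map <- array(ip$background_sd, dm)
    inside <- vox == 1L
    shell <- inside & r2 > 0.75^2
    core <- inside & !shell
    mean_map[core] <- ip$prostate_mean
    sd_map[core] <- ip$prostate_sd
    mean_map[shell] <- ip$pz_mean
    sd_map[shell] <- ip$pz_sd
    corr <- gaussian_smooth3(array(stats::rnorm(prod(dm)), dm),
                             tp$correlation_length)
    corr <- corr / stats::sd(corr)
    white <- array(stats::rnorm(prod(dm)), dm)
    mean_map * (1 + tp$multiplicative_sd * corr) + sd_map * white
  })
  list(image = image_volume(img, spacing = spec$spacing,
                            provenance = sprintf("phantom:seed=%d", spec$seed)),
       mask = seg_mask(vox, spacing = spec$spacing))
}

#' Specification of a mask perturbation
#'
#' Graded degradations standing in for the failure modes of automated
#' segmentation methods: over/under-segmentation (`dilate`/`erode`),
#' misregistration (`translate`), missing apex/base coverage
#' (`drop_apex_slices`/`drop_base_slices`), leakage into adjacent structures
#' (`leak_blob`) and observer-style boundary variability (`boundary_jitter`).
#'
#' @param kind One of `none`, `erode`, `dilate`, `translate`,
#'   `drop_apex_slices`, `drop_base_slices`, `leak_blob`, `boundary_jitter`.
#' @param magnitude Nonnegative severity: structuring-element radius in
#'   voxels (erode/dilate/leak_blob), shift in voxels (translate), slice
#'   count (drop_*), or boundary displacement scale in voxels
#'   (boundary_jitter). Zero always yields the identity.
#' @param seed Integer seed for the stochastic kinds.
#' @return A `perturbation_spec` list.
#' @export
perturbation_spec <- function(kind = c("none", "erode", "dilate", "translate",
                                       "drop_apex_slices", "drop_base_slices",
                                       "leak_blob", "boundary_jitter"),
                              magnitude = 0, seed = 1L) {
  kind <- match.arg(kind)
  magnitude <- as.numeric(magnitude)
  if (!is.finite(magnitude) || magnitude < 0)
    stop("`magnitude` must be a nonnegative real")
  if (kind == "none" && magnitude != 0)
    stop("kind = 'none' requires magnitude 0")
  structure(list(kind = kind, magnitude = magnitude, seed = as.integer(seed)),
            class = "perturbation_spec")
}

# Gain translating boundary_jitter magnitude into threshold perturbation;
# fixed so magnitude is roughly the boundary displacement in voxels.
JITTER_GAIN <- 0.12

#' Apply a graded perturbation to a segmentation mask
#'
#' Grid and spacing are always preserved. `magnitude = 0` (and
#' `kind = "none"`) return the mask unchanged. A perturbation that empties
#' the mask returns an empty mask with the `emptied` flag set and a warning,
#' never an error: downstream metric code must handle empty automated masks.
#'
#' @param mask A nonempty [seg_mask()].
#' @param spec A [perturbation_spec()].
#' @return The perturbed [seg_mask()].
#' @export
perturb_mask <- function(mask, spec) {
  stopifnot(inherits(mask, "seg_mask"), inherits(spec, "perturbation_spec"))
  if (is_empty_mask(mask)) stop("cannot perturb an empty mask")
  if (spec$kind == "none" || spec$magnitude == 0) return(mask)
  vox <- mask$voxels
  dm <- dim(vox)
  m <- spec$magnitude
  out <- switch(spec$kind,
    erode = morpho_op(vox, ball_offsets(m), "erode"),
    dilate = morpho_op(vox, ball_offsets(m), "dilate"),
    translate = shift_array(vox, c(as.integer(round(m)), 0L, 0L)),
    drop_apex_slices = drop_slices(vox, as.integer(round(m)), from_apex = TRUE),
    drop_base_slices = drop_slices(vox, as.integer(round(m)), from_apex = FALSE),
    leak_blob = with_seed(spec$seed, add_leak_blob(vox, m)),
    boundary_jitter = with_seed(spec$seed, jitter_boundary(vox, m))
  )
  emptied <- sum(out) == 0L
  if (emptied)
    warning("perturbation '", spec$kind, "' (magnitude ", m,
            ") emptied the mask")
  seg_mask(out, spacing = mask$spacing, emptied = emptied)
}

drop_slices <- function(vox, k, from_apex) {
  slices <- which(apply(vox, 3, sum) > 0)
  if (k <= 0L) return(vox)
  drop <- if (from_apex) utils::head(slices, k) else utils::tail(slices, k)
  vox[, , drop] <- 0L
  vox
}

add_leak_blob <- function(vox, radius) {
  dm <- dim(vox)
  surf <- which(surface_logical(vox), arr.ind = TRUE)
  pick <- surf[sample.int(nrow(surf), 1L), ]
  ctr <- colMeans(which(vox == 1L, arr.ind = TRUE))
  dir <- pick - ctr
  nrm <- sqrt(sum(dir^2))
  dir <- if (nrm < 1e-9) c(1, 0, 0) else dir / nrm
  center <- pmin(pmax(round(pick + dir * (radius + 1)), 1), dm)
  ax1 <- (seq_len(dm[1]) - center[1])^2
  ax2 <- (seq_len(dm[2]) - center[2])^2
  ax3 <- (seq_len(dm[3]) - center[3])^2
  blob <- outer(outer(ax1, ax2, `+`), ax3, `+`) <= radius^2 + 1e-9
  array(pmax(vox, as.integer(blob)), dm)
}

jitter_boundary <- function(vox, magnitude) {
  dm <- dim(vox)
  f <- gaussian_smooth3(array(as.numeric(vox), dm), 1.5)
  u <- gaussian_smooth3(array(stats::rnorm(prod(dm)), dm), 3)
  u <- u / stats::sd(u)
  array(as.integer(f > 0.5 + JITTER_GAIN * magnitude * u), dm)
}

# Foreground voxels with at least one 6-connected background neighbour
# (grid boundary counts as background).
surface_logical <- function(vox) {
  nb <- shift_array(vox, c(1L, 0L, 0L)) + shift_array(vox, c(-1L, 0L, 0L)) +
    shift_array(vox, c(0L, 1L, 0L)) + shift_array(vox, c(0L, -1L, 0L)) +
    shift_array(vox, c(0L, 0L, 1L)) + shift_array(vox, c(0L, 0L, -1L))
  vox == 1L & nb < 6L
}

#' Generate a synthetic second-observer calibration cohort
#'
#' Emulates the cohort used to anchor the quality-score calibration: `n`
#' phantom cases, each with a gold-standard mask and a mildly perturbed
#' "second-observer" mask. The phantom spec is held fixed; per-case noise and
#' observer seeds are derived deterministically from `seed`.
#'
#' @param n Number of cases (>= 2; a calibration needs a cohort mean).
#' @param phantom_spec A [phantom_spec()] (its own `seed` field is replaced
#'   per case).
#' @param observer_noise A [perturbation_spec()], by default mild
#'   `boundary_jitter` of magnitude 1.
#' @param seed Integer master seed.
#' @return List of `n` cases, each `list(image, gold, observer)`.
#' @export
generate_observer_cohort <- function(n, phantom_spec,
                                     observer_noise = perturbation_spec(
                                       "boundary_jitter", magnitude = 1),
                                     seed = 1L) {
  n <- as.integer(n)
  if (n < 2L) stop("calibration cohort needs n >= 2 cases")
  stopifnot(inherits(phantom_spec, "phantom_spec"),
            inherits(observer_noise, "perturbation_spec"))
  lapply(seq_len(n), function(i) {
    ps <- phantom_spec
    ps$seed <- derive_seed(seed, i, salt = 11L)
    case <- generate_phantom(ps)
    ob_spec <- observer_noise
    ob_spec$seed <- derive_seed(seed, i, salt = 23L)
    observer <- if (ob_spec$kind == "none" || ob_spec$magnitude == 0) case$mask
                else perturb_mask(case$mask, ob_spec)
    list(image = case$image, gold = case$mask, observer = observer)
  })
}
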