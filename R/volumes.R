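#' @useDynLib segqc, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' 3D image volume with physical voxel spacing
#'
#' Container for a scalar 3D image grid (e.g. a T2-weighted MR volume) with
#' anisotropic voxel spacing in millimetres. The through-plane (slice) axis is
#' always the third array axis; "inferior" is the lowest slice index.
#'
#' @param intensities 3D numeric array of voxel intensities (finite).
#' @param spacing Numeric length-3, mm per voxel along each axis; all > 0.
#' @param provenance Optional character vector recording processing steps.
#' @return An object of class `image_volume` with fields `intensities`,
#'   `spacing`, `slice_axis` (always 3) and `provenance`.
#' @examples
#' v <- image_volume(array(rnorm(8 * 8 * 4), c(8, 8, 4)), spacing = c(0.5, 0.5, 3))
#' dim(v$intensities)
#' @export
image_volume <- function(intensities, spacing = c(1, 1, 1), provenance = character()) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array")
  if (!all(is.finite(intensities)))
    stop("`intensities` must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  structure(
    list(intensities = intensities, spacing = spacing, slice_axis = 3L,
         provenance = provenance),
    class = "image_volume"
  )
}

#' Binary 3D segmentation mask
#'
#' A mask aligned voxel-for-voxel to an [image_volume()]; values strictly 0/1.
#'
#' @param voxels 3D array coercible to 0/1 (logical or numeric).
#' @param spacing Numeric length-3, mm per voxel; all > 0.
#' @param emptied Logical flag set by [perturb_mask()] when a perturbation
#'   removed every voxel; downstream metric code treats this as a degenerate
#'   (worst-case) segmentation rather than an error.
#' @return An object of class `seg_mask`.
#' @examples
#' m <- seg_mask(array(c(rep(0, 30), rep(1, 2)), c(4, 4, 2)))
#' mask_volume_voxels(m)
#' @export
seg_mask <- function(voxels, spacing = c(1, 1, 1), emptied = FALSE) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  v <- array(as.integer(voxels != 0), dim(voxels))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  structure(
    list(voxels = v, spacing = spacing, slice_axis = 3L, emptied = isTRUE(emptied)),
    class = "seg_mask"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$intensities), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "), " mm\n",
      sep = "")
  if (length(x$provenance))
    cat("  provenance: ", paste(x$provenance, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' @export
print.seg_mask <- function(x, ...) {
  cat("<seg_mask> ", paste(dim(x$voxels), collapse = "x"),
      " voxels, ", sum(x$voxels), " foreground, spacing ",
      paste(signif(x$spacing, 4), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

#' Number of foreground voxels in a mask
#' @param mask A [seg_mask()].
#' @return Integer voxel count.
#' @export
mask_volume_voxels <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  sum(mask$voxels)
}

#' Physical mask volume in cubic millimetres
#' @param mask A [seg_mask()].
#' @return Voxel count times voxel volume (mm^3).
#' @export
mask_volume_mm3 <- function(mask) {
  mask_volume_voxels(mask) * prod(mask$spacing)
}

is_empty_mask <- function(mask) sum(mask$voxels) == 0L

check_same_grid <- function(a, b) {
  if (!identical(dim(grid_of(a)), dim(grid_of(b))))
    stop(sprintf("grid mismatch: %s vs %s",
                 paste(dim(grid_of(a)), collapse = "x"),
                 paste(dim(grid_of(b)), collapse = "x")))
  if (max(abs(a$spacing - b$spacing)) > 1e-9)
    stop("spacing mismatch between grids")
  invisible(TRUE)
}

grid_of <- function(x) if (inherits(x, "seg_mask")) x$voxels else x$intensities

# Shift a 3D array by integer offset d: out[i] = a[i + d], zero padded.
shift_array <- function(a, d) {
  dm <- dim(a)
  out <- array(if (is.integer(a)) 0L else 0, dm)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    n <- dm[k] - abs(d[k])
    if (n <= 0L) return(out)
    if (d[k] >= 0L) {
      dst[[k]] <- seq_len(n)
      src[[k]] <- seq_len(n) + d[k]
    } else {
      dst[[k]] <- seq_len(n) - d[k]
      src[[k]] <- seq_len(n)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# The 13 unique 3D directions of the 26-neighbourhood (one per +/- pair).
directions_13 <- function() {
  list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L),
       c(1L, 1L, 0L), c(1L, -1L, 0L), c(1L, 0L, 1L), c(1L, 0L, -1L),
       c(0L, 1L, 1L), c(0L, 1L, -1L),
       c(1L, 1L, 1L), c(1L, 1L, -1L), c(1L, -1L, 1L), c(1L, -1L, -1L))
}

# All 26 neighbour offsets.
offsets_26 <- function() {
  d13 <- directions_13()
  c(d13, lapply(d13, function(d) -d))
}

# Ball structuring-element offsets: integer offsets with Euclidean norm <= r.
ball_offsets <- function(r) {
  if (r < 0) stop("radius must be nonnegative")
  ri <- floor(r)
  g <- expand.grid(x = -ri:ri, y = -ri:ri, z = -ri:ri)
  keep <- g$x^2 + g$y^2 + g$z^2 <= r^2 + 1e-9
  g <- g[keep & !(g$x == 0 & g$y == 0 & g$z == 0), , drop = FALSE]
  lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
}

# Run code with a local, restored RNG state seeded at `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a reproducible child seed below 2^31 from a parent seed and index.
derive_seed <- function(seed, index, salt = 0L) {
  s <- (as.double(seed) * 48271 + as.double(index) * 16807 + salt * 69621) %%
    2147483629
  as.integer(s + 1)
}
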