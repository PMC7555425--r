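#' Partition a mask into apex / middle / base slice thirds
#'
#' The apex and base are the inferior and superior thirds of the
#' mask-containing slices: with `n` such slices and `k = floor(n/3)`, the
#' apex gets the first `k`, the base the last `k`, and the middle the
#' remainder (so for `n = 10` the split is 3/4/3, and a single-slice mask is
#' all middle). Slice indices are absolute indices into the third array axis;
#' "inferior" is the lowest index.
#'
#' @param mask A nonempty [seg_mask()].
#' @return A `region_partition` with integer slice-index vectors
#'   `apex_slices`, `mid_slices`, `base_slices`.
#' @examples
#' m <- seg_mask(array(rep(c(0, 1), c(16, 16 * 9)), c(4, 4, 10)))
#' region_partition(m)
#' @export
region_partition <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  slices <- which(apply(mask$voxels, 3, sum) > 0)
  if (length(slices) == 0L)
    stop("cannot partition an empty mask into apex/middle/base")
  n <- length(slices)
  k <- n %/% 3L
  structure(list(
    apex_slices = slices[seq_len(k)],
    mid_slices = slices[seq_len(n - 2L * k) + k],
    base_slices = if (k > 0L) slices[seq_len(k) + (n - k)] else integer(0)
  ), class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  fmt <- function(s) if (length(s)) paste0("[", min(s), "..", max(s), "] (", length(s), ")") else "(none)"
  cat("<region_partition> apex ", fmt(x$apex_slices),
      ", mid ", fmt(x$mid_slices), ", base ", fmt(x$base_slices), "\n", sep = "")
  invisible(x)
}

#' Restrict a mask to one anatomical region
#'
#' Zeroes all voxels outside the region's slice range. `"whole"` returns the
#' mask unchanged. The partition need not come from this mask: for the
#' reference-based metric panel the reference mask defines the regions for
#' both masks.
#'
#' @param mask A [seg_mask()].
#' @param region One of `"whole"`, `"apex"`, `"base"`, `"mid"`.
#' @param partition A [region_partition()] on the same grid.
#' @return The restricted [seg_mask()].
#' @export
restrict_region <- function(mask, region, partition) {
  stopifnot(inherits(mask, "seg_mask"))
  region <- match.arg(region, c("whole", "apex", "base", "mid"))
  if (region == "whole") return(mask)
  stopifnot(inherits(partition, "region_partition"))
  keep <- switch(region, apex = partition$apex_slices,
                 mid = partition$mid_slices, base = partition$base_slices)
  vox <- array(0L, dim(mask$voxels))
  if (length(keep)) vox[, , keep] <- mask$voxels[, , keep]
  seg_mask(vox, spacing = mask$spacing)
}
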