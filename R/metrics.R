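#' Dice similarity coefficient
#'
#' `2|A ∩ B| / (|A| + |B|)`, dimensionless in \[0, 1\]. Two empty masks are
#' defined to agree perfectly (DSC 1).
#'
#' @param a,b [seg_mask()]s on the same grid.
#' @return A single real in \[0, 1\].
#' @export
dice <- function(a, b) {
  check_same_grid(a, b)
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0L) return(1)
  2 * sum(a$voxels * b$voxels) / (na + nb)
}

#' Absolute relative volume difference (percent)
#'
#' `|V_a / V_ref - 1| * 100` with volumes in voxel counts (the spacing
#' cancels). Asymmetric: the reference volume is the denominator and must be
#' nonempty.
#'
#' @param a The automated [seg_mask()].
#' @param b_reference The reference [seg_mask()] (nonempty).
#' @return Nonnegative percent.
#' @export
arvd <- function(a, b_reference) {
  check_same_grid(a, b_reference)
  vref <- sum(b_reference$voxels)
  if (vref == 0L) stop("aRVD undefined for an empty reference mask")
  abs(sum(a$voxels) / vref - 1) * 100
}

#' Surface voxels of a mask
#'
#' Foreground voxels with at least one 6-connected background neighbour; the
#' grid boundary counts as background. Surfaces are voxel-center point sets;
#' all distances in this package are Euclidean distances between voxel
#' centers in mm.
#'
#' @param mask A nonempty [seg_mask()].
#' @return Integer matrix of 1-based voxel coordinates, one row per surface
#'   voxel.
#' @export
surface_voxels <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  if (is_empty_mask(mask)) stop("empty mask has no surface")
  which(surface_logical(mask$voxels), arr.ind = TRUE)
}

surface_points_mm <- function(mask) {
  sv <- surface_voxels(mask)
  sweep(sv, 2, mask$spacing, `*`)
}

# Linear-interpolation percentile (quantile type 7), the convention used for
# the 95th-percentile Hausdorff distance.
interp_percentile <- function(x, p) {
  stats::quantile(x, p, names = FALSE, type = 7)
}

directed_surface_dists <- function(pa, pb) {
  cpp_directed_min_dists(pa, pb)
}

# Both directed surface-distance lists for a mask pair, computed once and
# shared by hd95 and asd inside metric_panel.
surface_dist_lists <- function(a, b) {
  pa <- surface_points_mm(a); pb <- surface_points_mm(b)
  list(ab = directed_surface_dists(pa, pb),
       ba = directed_surface_dists(pb, pa))
}

hd95_from_lists <- function(dl) {
  max(interp_percentile(dl$ab, 0.95), interp_percentile(dl$ba, 0.95))
}

asd_from_lists <- function(dl) {
  (sum(dl$ab) + sum(dl$ba)) / (length(dl$ab) + length(dl$ba))
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' The maximum of the two directed 95th-percentile surface distances. Each
#' directed distance set holds, for every surface voxel of one mask, the
#' minimum Euclidean mm distance to the other mask's surface; percentiles use
#' linear interpolation. Symmetric by construction.
#'
#' @param a,b Nonempty [seg_mask()]s on the same grid.
#' @return Nonnegative distance in mm.
#' @export
hd95 <- function(a, b) {
  check_same_grid(a, b)
  if (is_empty_mask(a) || is_empty_mask(b))
    stop("hd95 undefined for an empty mask; metric_panel() flags this case")
  hd95_from_lists(surface_dist_lists(a, b))
}

#' Average symmetric surface distance (mm)
#'
#' The mean of all directed surface distances pooled from both directions
#' (sum of both directed lists divided by the total count), not the mean of
#' the two directed means.
#'
#' @param a,b Nonempty [seg_mask()]s on the same grid.
#' @return Nonnegative distance in mm.
#' @export
asd <- function(a, b) {
  check_same_grid(a, b)
  if (is_empty_mask(a) || is_empty_mask(b))
    stop("asd undefined for an empty mask; metric_panel() flags this case")
  asd_from_lists(surface_dist_lists(a, b))
}

panel_cells <- function() {
  as.vector(outer(c("whole", "apex", "base"),
                  c("DSC", "aRVD", "HD95", "ASD"),
                  function(r, m) paste(r, m, sep = "_")))
}

#' Region-wise segmentation metric panel (12 cells)
#'
#' Computes DSC, aRVD, HD95 and ASD for the whole gland, apex and base —
#' the 12 raw ingredients of the composite quality score. The apex/base
#' partition is derived from the reference mask and applied to both masks,
#' so both are compared in the same anatomical frame.
#'
#' Degenerate regions are flagged rather than fatal: if the automated mask is
#' empty within a region, DSC is 0 and aRVD 100 but the distance cells are
#' invalid (`NA`) — scoring assigns those cells the floor score. If the
#' reference itself has no voxels in a region (masks spanning < 3 slices),
#' all four cells of that region are invalid.
#'
#' @param auto The automated [seg_mask()].
#' @param reference The reference (manual/gold) [seg_mask()], nonempty.
#' @return A `metric_panel`: named numeric vector of 12 cells
#'   (`whole_DSC`, ..., `base_ASD`) with a logical `valid` attribute.
#' @export
metric_panel <- function(auto, reference) {
  check_same_grid(auto, reference)
  if (is_empty_mask(reference)) stop("reference mask must be nonempty")
  part <- region_partition(reference)
  values <- stats::setNames(rep(NA_real_, 12L), panel_cells())
  valid <- stats::setNames(rep(FALSE, 12L), panel_cells())
  for (region in c("whole", "apex", "base")) {
    ref_r <- restrict_region(reference, region, part)
    auto_r <- restrict_region(auto, region, part)
    cell <- function(metric) paste(region, metric, sep = "_")
    if (is_empty_mask(ref_r)) next  # reference region empty: all 4 invalid
    values[cell("DSC")] <- dice(auto_r, ref_r)
    values[cell("aRVD")] <- arvd(auto_r, ref_r)
    valid[cell("DSC")] <- valid[cell("aRVD")] <- TRUE
    if (!is_empty_mask(auto_r)) {
      dl <- surface_dist_lists(auto_r, ref_r)
      values[cell("HD95")] <- hd95_from_lists(dl)
      values[cell("ASD")] <- asd_from_lists(dl)
      valid[cell("HD95")] <- valid[cell("ASD")] <- TRUE
    }
  }
  structure(values, valid = valid, class = c("metric_panel", "numeric"))
}

#' @export
print.metric_panel <- function(x, ...) {
  cat("<metric_panel>\n")
  m <- matrix(unclass(x), nrow = 3,
              dimnames = list(c("whole", "apex", "base"),
                              c("DSC", "aRVD", "HD95", "ASD")))
  print(round(m, 3))
  if (!all(attr(x, "valid"))) cat("invalid cells:",
                                  paste(names(x)[!attr(x, "valid")], collapse = ", "), "\n")
  invisible(x)
}

#' Collect metric panels into a data frame
#' @param panels Named list of `metric_panel` objects.
#' @return A data frame with `case_id` plus the 12 metric columns.
#' @export
panels_to_df <- function(panels) {
  df <- as.data.frame(do.call(rbind, lapply(panels, unclass)))
  df <- cbind(case_id = names(panels) %||% seq_along(panels), df)
  rownames(df) <- NULL
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
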