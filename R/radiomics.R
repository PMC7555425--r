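feature_names_one_region <- function() {
  c(paste0("firstorder_", FIRSTORDER_NAMES),
    paste0("shape_", SHAPE_NAMES),
    paste0("glcm_", GLCM_NAMES),
    paste0("glrlm_", GLRLM_NAMES),
    paste0("glszm_", GLSZM_NAMES),
    paste0("gldm_", GLDM_NAMES),
    paste0("ngtdm_", NGTDM_NAMES))
}

#' The frozen 321-entry feature-name vector
#'
#' Region-major order (whole, apex, base), class order first-order, shape,
#' GLCM, GLRLM, GLSZM, GLDM, NGTDM, alphabetical within class. Models store
#' coefficients by this order.
#'
#' @return Character vector of length 321 (`region_class_Feature`).
#' @export
feature_names <- function() {
  as.vector(vapply(c("whole", "apex", "base"),
                   function(r) paste(r, feature_names_one_region(), sep = "_"),
                   character(107L)))
}

region_features <- function(volume, rmask, bin_width) {
  if (is_empty_mask(rmask))
    return(list(values = stats::setNames(rep(0, 107L),
                                         feature_names_one_region()),
                valid = FALSE))
  disc <- discretize(volume, rmask, bin_width)
  fo <- first_order_features(volume, rmask, bin_width)
  sh <- shape_features(rmask)
  tx <- texture_features(texture_matrices(disc))
  vals <- c(stats::setNames(fo, paste0("firstorder_", FIRSTORDER_NAMES)),
            stats::setNames(sh, paste0("shape_", SHAPE_NAMES)),
            tx)
  list(values = vals, valid = sum(rmask$voxels) > 1L)
}

#' Extract the 321-entry radiomics feature vector for one case
#'
#' 107 features (18 first-order, 14 shape, 75 texture at fixed bin width)
#' from each of the whole gland, apex and base of the automated mask —
#' 321 per case. The apex/base partition is derived from the automated mask
#' itself, since no reference exists at inference time, and each region is
#' discretized independently. Degenerate regions (empty or single-voxel)
#' yield the documented zero conventions and are flagged, but the case
#' always emits exactly 321 finite entries.
#'
#' @param volume The (preprocessed) [image_volume()].
#' @param auto_mask The nonempty automated [seg_mask()].
#' @param bin_width Fixed bin width for intensity discretization; default 64.
#' @return A `feature_vector`: named numeric of length 321 with attributes
#'   `valid_regions` (named logical) and `settings` (fingerprint string).
#' @export
extract_case <- function(volume, auto_mask, bin_width = 64) {
  stopifnot(inherits(volume, "image_volume"), inherits(auto_mask, "seg_mask"))
  check_same_grid(volume, auto_mask)
  if (is_empty_mask(auto_mask))
    stop("feature extraction requires a nonempty automated mask")
  part <- region_partition(auto_mask)
  out <- numeric(0)
  valid <- stats::setNames(logical(3), c("whole", "apex", "base"))
  for (region in c("whole", "apex", "base")) {
    rmask <- restrict_region(auto_mask, region, part)
    rf <- region_features(volume, rmask, bin_width)
    out <- c(out, stats::setNames(rf$values,
                                  paste(region, names(rf$values), sep = "_")))
    valid[region] <- rf$valid
  }
  stopifnot(length(out) == 321L, all(is.finite(out)))
  structure(out, valid_regions = valid,
            settings = sprintf(
              "binwidth=%g;directions=13;connectivity=26;distance=1", bin_width),
            class = c("feature_vector", "numeric"))
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector> 321 features [", attr(x, "settings"), "]\n", sep = "")
  invisible(x)
}

#' Collect feature vectors into a data frame
#' @param fvs Named list of [extract_case()] results.
#' @return Data frame with `case_id` plus 321 feature columns.
#' @export
features_to_df <- function(fvs) {
  df <- as.data.frame(do.call(rbind, lapply(fvs, unclass)))
  df <- cbind(case_id = names(fvs) %||% seq_along(fvs), df)
  rownames(df) <- NULL
  df
}
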