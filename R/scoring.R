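metric_ideals <- function() {
  stats::setNames(rep(c(1, 0, 0, 0), each = 3L), panel_cells())
}

#' Fit the per-metric quality-score calibration from an observer cohort
#'
#' For each of the 12 metric cells, fits the linear map metric → score
#' through two anchor points: the metric's ideal value (DSC 1; aRVD, HD95,
#' ASD 0) maps to 100, and the cohort mean of that cell — the average
#' performance of the second observer — maps to `anchor` (85 by default).
#' Applied scores are later clipped to \[0, 100\] per cell.
#'
#' @param cohort_panels List of fully valid [metric_panel()]s (>= 2) from
#'   (gold, second-observer) mask pairs.
#' @param anchor Score assigned to the cohort mean of each cell; default 85.
#' @return A `score_calibration`: per-cell `slope`, `intercept`, `ideal`,
#'   `cohort_mean`, plus cohort size. Error-type cells get negative slopes,
#'   DSC a positive one, by construction.
#' @examples
#' # a cell whose cohort-mean DSC is 0.9 yields s(d) = 100 - 150 (1 - d)
#' @export
fit_calibration <- function(cohort_panels, anchor = 85) {
  if (length(cohort_panels) < 2L)
    stop("calibration needs at least 2 cohort panels")
  if (!all(vapply(cohort_panels, inherits, logical(1), "metric_panel")))
    stop("cohort_panels must be metric_panel objects")
  ok <- vapply(cohort_panels, function(p) all(attr(p, "valid")), logical(1))
  if (!all(ok))
    stop("calibration cohort contains invalid metric cells (cases: ",
         paste(which(!ok), collapse = ", "), ")")
  mat <- do.call(rbind, lapply(cohort_panels, unclass))
  means <- colMeans(mat)
  ideals <- metric_ideals()
  degenerate <- abs(means - ideals) < 1e-12
  if (any(degenerate))
    stop("cohort mean equals the ideal value for cell(s) ",
         paste(names(means)[degenerate], collapse = ", "),
         "; the score line is underdetermined (zero-error cohort)")
  slope <- (anchor - 100) / (means - ideals)
  intercept <- 100 - slope * ideals
  structure(list(slope = slope, intercept = intercept, ideal = ideals,
                 cohort_mean = means, anchor = anchor,
                 cohort_size = length(cohort_panels)),
            class = "score_calibration")
}

#' @export
print.score_calibration <- function(x, ...) {
  cat("<score_calibration> anchor ", x$anchor, " at cohort mean (n = ",
      x$cohort_size, ")\n", sep = "")
  print(round(rbind(slope = x$slope, intercept = x$intercept,
                    cohort_mean = x$cohort_mean), 3))
  invisible(x)
}

#' Combine a metric panel into a single 0-100 quality score
#'
#' Each cell is mapped by its calibrated line and clipped to \[0, 100\];
#' invalid cells (empty-region degeneracies) receive the floor score 0.
#' The combined score is the arithmetic mean of the 12 cell scores. With a
#' reference mask this is the reference quality score (rQS).
#'
#' @param panel A [metric_panel()].
#' @param calibration A [fit_calibration()] result.
#' @return A `quality_score`: list with `value` (the combined score) and
#'   `cell_scores` (12 named reals in \[0, 100\]).
#' @export
score_panel <- function(panel, calibration) {
  stopifnot(inherits(panel, "metric_panel"),
            inherits(calibration, "score_calibration"))
  raw <- calibration$slope * unclass(panel) + calibration$intercept
  cell <- pmin(pmax(raw, 0), 100)
  cell[!attr(panel, "valid")] <- 0
  cell <- stats::setNames(as.numeric(cell), names(calibration$slope))
  structure(list(value = mean(cell), cell_scores = cell),
            class = "quality_score")
}

#' @export
print.quality_score <- function(x, ...) {
  cat("<quality_score> ", round(x$value, 2), "\n", sep = "")
  invisible(x)
}

#' Serialize / restore a score calibration as JSON
#' @param calibration A `score_calibration`.
#' @param path Output (input) JSON path.
#' @return `path` invisibly; `read_calibration` returns the object.
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "score_calibration"))
  jsonlite::write_json(
    list(anchor = calibration$anchor, cohort_size = calibration$cohort_size,
         cells = names(calibration$slope),
         slope = as.numeric(calibration$slope),
         intercept = as.numeric(calibration$intercept),
         ideal = as.numeric(calibration$ideal),
         cohort_mean = as.numeric(calibration$cohort_mean)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- j$cells
  structure(list(slope = stats::setNames(j$slope, nm),
                 intercept = stats::setNames(j$intercept, nm),
                 ideal = stats::setNames(j$ideal, nm),
                 cohort_mean = stats::setNames(j$cohort_mean, nm),
                 anchor = j$anchor, cohort_size = j$cohort_size),
            class = "score_calibration")
}
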