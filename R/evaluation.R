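#' Evaluate estimated against reference quality scores
#'
#' Computes the agreement panel used to judge the QC system: mean absolute
#' error (after eQS clamping), SD and IQR of the absolute errors (IQR via
#' linear-interpolated quartiles), Spearman's rank correlation with p-value
#' (average ranks for ties), the ordinary least-squares fit of eQS on rQS,
#' the pointwise 95% prediction interval of that fit, the Bland-Altman mean
#' difference (eQS - rQS), and the cases falling outside the prediction
#' interval (the outliers a reader would inspect).
#'
#' @param eqs Estimated quality scores, already clamped to \[0, 100\].
#' @param rqs Reference quality scores.
#' @param ids Optional case identifiers (default `1..n`).
#' @param level Prediction-interval level (default 0.95).
#' @return An `evaluation_report` list.
#' @export
qc_evaluate <- function(eqs, rqs, ids = seq_along(eqs), level = 0.95) {
  eqs <- as.numeric(eqs); rqs <- as.numeric(rqs)
  if (length(eqs) != length(rqs) || length(eqs) != length(ids))
    stop("eqs, rqs and ids must have equal length")
  if (length(eqs) < 3L) stop("evaluation needs at least 3 cases")
  abs_err <- abs(eqs - rqs)
  sp <- suppressWarnings(
    stats::cor.test(eqs, rqs, method = "spearman", exact = FALSE))
  fit <- stats::lm(eqs ~ rqs, data = data.frame(eqs = eqs, rqs = rqs))
  pi_band <- suppressWarnings(  # in-sample PI is intentional here
    stats::predict(fit, interval = "prediction", level = level))
  outlier <- eqs < pi_band[, "lwr"] | eqs > pi_band[, "upr"]
  structure(list(
    n = length(eqs),
    mae = mean(abs_err),
    sd_abs_err = stats::sd(abs_err),
    iqr_abs_err = diff(stats::quantile(abs_err, c(0.25, 0.75),
                                       names = FALSE, type = 7)),
    rho = unname(sp$estimate),
    rho_p = sp$p.value,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    mean_diff = mean(eqs - rqs),
    level = level,
    prediction_interval = data.frame(id = ids, rqs = rqs, eqs = eqs,
                                     lwr = pi_band[, "lwr"],
                                     upr = pi_band[, "upr"],
                                     outlier = outlier),
    outlier_ids = ids[outlier]
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> n = %d | MAE %.2f +/- %.2f (IQR %.2f) | rho %.2f (p %.3g)\n",
    x$n, x$mae, x$sd_abs_err, x$iqr_abs_err, x$rho, x$rho_p))
  cat(sprintf("  fit eQS = %.2f + %.2f rQS | mean diff %.2f | %d outliers\n",
              x$intercept, x$slope, x$mean_diff, length(x$outlier_ids)))
  invisible(x)
}

#' Per-subgroup evaluation reports
#'
#' One report per combination of dataset and segmentation-method label, plus
#' the pooled report over all cases. Combinations with fewer than 3 cases
#' are skipped with a warning.
#'
#' @param cases Data frame with columns `eqs`, `rqs`, `dataset`, `method`
#'   and optionally `id`.
#' @return List with `pooled` and `subgroups` (named list of reports).
#' @export
subgroup_report <- function(cases) {
  need <- c("eqs", "rqs", "dataset", "method")
  if (!all(need %in% names(cases)))
    stop("cases must have columns ", paste(need, collapse = ", "))
  if (is.null(cases$id)) cases$id <- seq_len(nrow(cases))
  pooled <- qc_evaluate(cases$eqs, cases$rqs, cases$id)
  combos <- unique(cases[, c("dataset", "method")])
  subgroups <- list()
  for (i in seq_len(nrow(combos))) {
    sel <- cases$dataset == combos$dataset[i] & cases$method == combos$method[i]
    label <- paste(combos$dataset[i], combos$method[i], sep = "-")
    if (sum(sel) < 3L) {
      warning("subgroup ", label, " has n = ", sum(sel), " < 3; skipped")
      next
    }
    subgroups[[label]] <- qc_evaluate(cases$eqs[sel], cases$rqs[sel],
                                      cases$id[sel])
  }
  list(pooled = pooled, subgroups = subgroups)
}

#' Write an evaluation report (JSON) and its per-case table (CSV)
#' @param report An `evaluation_report`.
#' @param json_path,csv_path Output paths (either may be `NULL` to skip).
#' @return `json_path` invisibly.
#' @export
write_evaluation <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  if (!is.null(json_path)) {
    keep <- c("n", "mae", "sd_abs_err", "iqr_abs_err", "rho", "rho_p",
              "slope", "intercept", "mean_diff", "level")
    jsonlite::write_json(c(report[keep],
                           list(outlier_ids = report$outlier_ids)),
                         json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(csv_path))
    utils::write.csv(report$prediction_interval, csv_path, row.names = FALSE)
  invisible(json_path)
}
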