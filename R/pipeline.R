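#' Run configuration for the end-to-end pipeline
#'
#' Defaults reproduce the method's stated settings: fixed bin width 64,
#' 5-fold cross-validation, observer anchor score 85.
#'
#' @param out_dir Output directory (created if absent).
#' @param n_patients Number of phantom patients to simulate.
#' @param methods Perturbation kinds standing in for segmentation methods;
#'   each patient gets one automated mask per method.
#' @param phantom A [phantom_spec()] template.
#' @param observer_noise A [perturbation_spec()] for the second-observer
#'   masks.
#' @param bin_width Discretization bin width.
#' @param folds CV folds for lambda selection.
#' @param anchor Observer anchor score.
#' @param bias_tol Bland-Altman bias tolerance (score points).
#' @param normalize Intensity normalization for feature extraction.
#' @param seed Master seed; every stage derives from it.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, n_patients = 10L,
                       methods = c("erode", "dilate", "boundary_jitter",
                                   "drop_apex_slices"),
                       phantom = phantom_spec(),
                       observer_noise = perturbation_spec("boundary_jitter",
                                                          magnitude = 1),
                       bin_width = 64, folds = 5L, anchor = 85,
                       bias_tol = 1, normalize = "none", seed = 42L) {
  structure(list(out_dir = out_dir, n_patients = as.integer(n_patients),
                 methods = methods, phantom = phantom,
                 observer_noise = observer_noise, bin_width = bin_width,
                 folds = as.integer(folds), anchor = anchor,
                 bias_tol = bias_tol, normalize = normalize,
                 seed = as.integer(seed)),
            class = "run_config")
}

ensure_dir <- function(path) {
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("cannot create output directory ", path)
  invisible(path)
}

case_path <- function(config, case_id, what) {
  file.path(config$out_dir, sprintf("%s_%s.nii.gz", case_id, what))
}

#' Simulate a phantom dataset on disk
#'
#' Writes, per patient, the image, gold-standard and observer masks, and one
#' automated mask per method (graded perturbation magnitudes spanning the
#' quality range), as NIfTI files plus a `manifest.csv` listing case id,
#' patient id, method, magnitude and seed. Deterministic per seed.
#'
#' @param config A [run_config()].
#' @return The manifest data frame, invisibly written to
#'   `<out_dir>/manifest.csv`.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ensure_dir(config$out_dir)
  rows <- list()
  for (i in seq_len(config$n_patients)) {
    patient <- sprintf("pt%03d", i)
    ps <- config$phantom
    ps$seed <- derive_seed(config$seed, i, salt = 101L)
    case <- generate_phantom(ps)
    ob <- config$observer_noise
    ob$seed <- derive_seed(config$seed, i, salt = 211L)
    observer <- if (ob$magnitude == 0) case$mask else perturb_mask(case$mask, ob)
    write_volume(case$image, case_path(config, patient, "image"))
    write_volume(case$mask, case_path(config, patient, "gold"))
    write_volume(observer, case_path(config, patient, "observer"))
    for (m in seq_along(config$methods)) {
      kind <- config$methods[m]
      # magnitudes cycle with patient index so each method spans mild..severe
      mag <- switch(kind,
                    erode = 1 + (i + m) %% 3,
                    dilate = 1 + (i + m) %% 3,
                    translate = 1 + (i + m) %% 4,
                    drop_apex_slices = 1 + (i + m) %% 4,
                    drop_base_slices = 1 + (i + m) %% 4,
                    leak_blob = 2 + (i + m) %% 3,
                    boundary_jitter = 0.5 * (1 + (i + m) %% 5),
                    0)
      pspec <- perturbation_spec(kind, magnitude = mag,
                                 seed = derive_seed(config$seed, i,
                                                    salt = 300L + m))
      auto <- perturb_mask(case$mask, pspec)
      case_id <- sprintf("%s_%s", patient, kind)
      write_volume(auto, case_path(config, case_id, "auto"))
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = case_id, patient_id = patient, method = kind,
        magnitude = mag, seed = pspec$seed,
        image = case_path(config, patient, "image"),
        gold = case_path(config, patient, "gold"),
        observer = case_path(config, patient, "observer"),
        auto = case_path(config, case_id, "auto"))
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

read_manifest <- function(config) {
  path <- file.path(config$out_dir, "manifest.csv")
  if (!file.exists(path)) stop("no manifest at ", path, "; run cmd_simulate")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Calibrate and compute reference quality scores
#'
#' Fits the score calibration from the (gold, observer) pairs of the
#' simulated dataset, then scores every automated mask against its gold
#' standard. Per-case failures are recorded in the output and skipped, not
#' fatal. Writes `calibration.json` and `scores.csv` (metric panel columns
#' plus `rqs`).
#'
#' @param config A [run_config()].
#' @return The scores data frame, invisibly.
#' @export
cmd_rqs <- function(config) {
  manifest <- read_manifest(config)
  patients <- unique(manifest$patient_id)
  cohort <- list()
  for (p in patients) {
    row <- manifest[manifest$patient_id == p, ][1, ]
    image <- read_volume(row$image)
    gold <- read_mask(row$gold, image)
    observer <- read_mask(row$observer, image)
    cohort[[p]] <- metric_panel(observer, gold)
  }
  calibration <- fit_calibration(cohort, anchor = config$anchor)
  write_calibration(calibration, file.path(config$out_dir, "calibration.json"))
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      image <- read_volume(row$image)
      gold <- read_mask(row$gold, image)
      auto <- read_mask(row$auto, image)
      panel <- metric_panel(auto, gold)
      qs <- score_panel(panel, calibration)
      cbind(data.frame(case_id = row$case_id, patient_id = row$patient_id,
                       method = row$method, error = NA_character_),
            as.data.frame(t(unclass(panel))), rqs = qs$value)
    }, error = function(e) {
      data.frame(case_id = row$case_id, patient_id = row$patient_id,
                 method = row$method, error = conditionMessage(e))
    })
    rows[[i]] <- res
  }
  scores <- do.call(rbind, lapply(rows, function(r) {
    # pad failed cases with NA metric columns
    miss <- setdiff(c(panel_cells(), "rqs"), names(r))
    for (m in miss) r[[m]] <- NA_real_
    r[, c("case_id", "patient_id", "method", "error", panel_cells(), "rqs")]
  }))
  utils::write.csv(scores, file.path(config$out_dir, "scores.csv"),
                   row.names = FALSE)
  invisible(scores)
}

#' Extract features for every automated segmentation
#'
#' Preprocesses each image per the configured normalization and extracts the
#' 321-entry feature vector from the automated mask. Writes `features.csv`.
#'
#' @param config A [run_config()].
#' @return The feature data frame, invisibly.
#' @export
cmd_extract <- function(config) {
  manifest <- read_manifest(config)
  pp <- preprocess_config(normalize = config$normalize)
  fvs <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    image <- read_volume(row$image)
    auto <- read_mask(row$auto, image)
    if (is_empty_mask(auto)) {
      warning("case ", row$case_id, " has an empty automated mask; quarantined")
      next
    }
    vol <- preprocess(image, pp, mask = auto)
    fvs[[row$case_id]] <- extract_case(vol, auto, bin_width = config$bin_width)
  }
  df <- features_to_df(fvs)
  utils::write.csv(df, file.path(config$out_dir, "features.csv"),
                   row.names = FALSE)
  invisible(df)
}

#' Train the quality model from extracted features and reference scores
#'
#' Joins `features.csv` and `scores.csv`, selects lambda by patient-level
#' cross-validation with the Bland-Altman bias screen, trains the final
#' model on all cases, and writes `model.json` plus `folds.csv` (the audit
#' trail proving the patient-level split).
#'
#' @param config A [run_config()].
#' @return The trained `qc_model`, invisibly.
#' @export
cmd_train <- function(config) {
  feats <- utils::read.csv(file.path(config$out_dir, "features.csv"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  scores <- utils::read.csv(file.path(config$out_dir, "scores.csv"),
                            stringsAsFactors = FALSE)
  merged <- merge(feats, scores[, c("case_id", "patient_id", "rqs")],
                  by = "case_id")
  merged <- merged[!is.na(merged$rqs), ]
  X <- as.matrix(merged[, feature_names()])
  search <- qc_select_lambda(X, merged$rqs, patient_id = merged$patient_id,
                             k = config$folds, bias_tol = config$bias_tol,
                             seed = derive_seed(config$seed, 1L, salt = 401L))
  model <- qc_train(X, merged$rqs, lambda = search$lambda)
  write_qc_model(model, file.path(config$out_dir, "model.json"))
  utils::write.csv(data.frame(case_id = merged$case_id,
                              patient_id = merged$patient_id,
                              fold = search$folds),
                   file.path(config$out_dir, "folds.csv"), row.names = FALSE)
  invisible(model)
}

#' Predict estimated quality scores for the extracted cases
#'
#' Applies `model.json` to `features.csv`; writes `predictions.csv` with one
#' clamped eQS per case.
#'
#' @param config A [run_config()].
#' @return The predictions data frame, invisibly.
#' @export
cmd_predict <- function(config) {
  feats <- utils::read.csv(file.path(config$out_dir, "features.csv"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  model <- read_qc_model(file.path(config$out_dir, "model.json"))
  X <- as.matrix(feats[, feature_names()])
  preds <- data.frame(case_id = feats$case_id,
                      eqs = predict(model, X))
  utils::write.csv(preds, file.path(config$out_dir, "predictions.csv"),
                   row.names = FALSE)
  invisible(preds)
}

#' Evaluate predictions against reference scores
#'
#' Joins `predictions.csv` and `scores.csv` and writes `report.json` and
#' `report_cases.csv` (per-case rQS, eQS, difference, outlier flag).
#'
#' @param config A [run_config()].
#' @return The `evaluation_report`, invisibly.
#' @export
cmd_evaluate <- function(config) {
  preds <- utils::read.csv(file.path(config$out_dir, "predictions.csv"),
                           stringsAsFactors = FALSE)
  scores <- utils::read.csv(file.path(config$out_dir, "scores.csv"),
                            stringsAsFactors = FALSE)
  merged <- merge(preds, scores[, c("case_id", "rqs")], by = "case_id")
  merged <- merged[!is.na(merged$rqs), ]
  report <- qc_evaluate(merged$eqs, merged$rqs, ids = merged$case_id)
  write_evaluation(report, file.path(config$out_dir, "report.json"),
                   file.path(config$out_dir, "report_cases.csv"))
  invisible(report)
}
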