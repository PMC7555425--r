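# Cyclic coordinate descent for the lasso
#   min_b  1/(2n) ||y - Xb||^2 + lambda ||b||_1
# on predictors standardized to zero mean / unit (population) SD.
# X must already be standardized; the compiled kernel does the sweeps.
lasso_cd <- function(X, y, lambda, beta = NULL, tol = 1e-9, max_iter = 5000L) {
  if (is.null(beta)) beta <- numeric(ncol(X))
  cpp_lasso_cd(X, y - mean(y), lambda, beta, tol, as.integer(max_iter))
}

standardize_cols <- function(X) {
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2, mu)^2))
  keep <- sdv > 1e-12
  Xs <- sweep(X[, keep, drop = FALSE], 2, mu[keep])
  Xs <- sweep(Xs, 2, sdv[keep], `/`)
  list(X = Xs, mean = mu, sd = sdv, keep = keep)
}

as_feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  if (is.data.frame(features)) return(as.matrix(features))
  if (is.list(features)) return(do.call(rbind, lapply(features, unclass)))
  stop("`features` must be a matrix, data frame or list of feature vectors")
}

#' Train the LASSO quality-score model at a fixed penalty
#'
#' Fits a linear regression of quality scores on the radiomics features with
#' an L1 penalty, solved by cyclic coordinate descent on internally
#' standardized predictors (zero mean, unit SD on the training data; the
#' response is left unstandardized). Zero-variance features are dropped from
#' the fit and reported with coefficient 0.
#'
#' @param features Feature matrix (cases x features, named columns), data
#'   frame, or list of [extract_case()] vectors.
#' @param rqs Numeric responses in \[0, 100\], one per case.
#' @param lambda Nonnegative penalty on the standardized scale.
#' @return A `qc_model`: feature names, standardization means/SDs,
#'   standardized-scale coefficients, intercept, lambda and provenance.
#' @export
qc_train <- function(features, rqs, lambda) {
  X <- as_feature_matrix(features)
  rqs <- as.numeric(rqs)
  if (nrow(X) != length(rqs))
    stop("features (", nrow(X), " cases) and rqs (", length(rqs),
         ") differ in length")
  if (nrow(X) < 10L) stop("need at least 10 training cases")
  if (any(rqs < -1e-9 | rqs > 100 + 1e-9))
    stop("rqs responses must lie in [0, 100]")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  std <- standardize_cols(X)
  beta <- numeric(ncol(X))
  if (stats::sd(rqs) > 0 && any(std$keep))
    beta[std$keep] <- lasso_cd(std$X, rqs, lambda)
  structure(list(
    feature_names = colnames(X),
    center = std$mean, scale = ifelse(std$keep, std$sd, 1),
    beta = stats::setNames(beta, colnames(X)),
    intercept = mean(rqs), lambda = lambda,
    provenance = list(n = nrow(X), p = ncol(X))
  ), class = "qc_model")
}

#' @export
print.qc_model <- function(x, ...) {
  cat("<qc_model> ", sum(x$beta != 0), "/", length(x$beta),
      " nonzero coefficients, lambda = ", signif(x$lambda, 4),
      ", trained on n = ", x$provenance$n, "\n", sep = "")
  invisible(x)
}

#' Estimate the quality score (eQS) for new cases
#'
#' Linear prediction from the stored standardization and coefficients,
#' clamped to \[0, 100\]: raw predictions above 100 become 100 and below 0
#' become 0. Feature names must match the model exactly.
#'
#' @param object A [qc_train()] model.
#' @param features Feature vector, matrix, data frame or list as in
#'   [qc_train()].
#' @param ... Unused.
#' @return Numeric eQS values in \[0, 100\].
#' @export
predict.qc_model <- function(object, features, ...) {
  if (inherits(features, "feature_vector") ||
      (is.numeric(features) && !is.matrix(features)))
    features <- matrix(unclass(features), nrow = 1,
                       dimnames = list(NULL, names(features)))
  X <- as_feature_matrix(features)
  if (is.null(colnames(X)))
    stop("features must be named to match the model")
  missing <- setdiff(object$feature_names, colnames(X))
  extra <- setdiff(colnames(X), object$feature_names)
  if (length(missing) || length(extra))
    stop("feature mismatch; missing: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...", "; extra: ",
         paste(utils::head(extra, 5), collapse = ", "),
         if (length(extra) > 5) " ...")
  X <- X[, object$feature_names, drop = FALSE]
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  raw <- as.numeric(Xs %*% object$beta) + object$intercept
  pmin(pmax(raw, 0), 100)
}

default_lambda_grid <- function(X, y, n_lambda = 100L, decades = 4) {
  std <- standardize_cols(X)
  yc <- y - mean(y)
  lmax <- max(abs(crossprod(std$X, yc)) / nrow(X))
  if (lmax <= 0) lmax <- 1
  exp(seq(log(lmax), log(lmax) - decades * log(10), length.out = n_lambda))
}

#' Select the LASSO penalty by patient-level cross-validated MSE
#'
#' k-fold cross-validation with folds assigned by patient identifier, so all
#' segmentations of one patient share a fold. For each lambda on the grid,
#' out-of-fold predictions (clamped to \[0, 100\]) give a CV mean squared
#' error and a Bland-Altman mean difference (predicted minus reference). The
#' chosen lambda minimizes CV-MSE among lambdas whose absolute mean
#' difference is within `bias_tol` (the automated reading of a "non-biased
#' Bland-Altman distribution"); if none qualifies, the unconstrained
#' minimizer is chosen with a warning. MSE ties break toward the larger
#' (sparser) lambda.
#'
#' @param features,rqs As in [qc_train()].
#' @param patient_id Vector of patient identifiers, one per case; cases
#'   sharing an id are never split across folds. Default: one patient per
#'   case.
#' @param k Number of folds (default 5).
#' @param grid Lambda grid; default log-spaced, 100 points, from the
#'   smallest all-zero lambda down four decades.
#' @param bias_tol Allowed absolute out-of-fold mean difference in score
#'   points (default 1).
#' @param seed Integer seed for the fold assignment.
#' @return A `lambda_search`: `lambda` (chosen), `grid`, `cv_mse`, `bias`,
#'   `folds` (per-case fold index), and `bias_ok` flags.
#' @export
qc_select_lambda <- function(features, rqs, patient_id = NULL, k = 5L,
                             grid = NULL, bias_tol = 1, seed = 1L) {
  X <- as_feature_matrix(features)
  y <- as.numeric(rqs)
  stopifnot(nrow(X) == length(y))
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (is.null(patient_id)) patient_id <- seq_len(nrow(X))
  if (length(patient_id) != nrow(X))
    stop("patient_id must have one entry per case")
  if (is.null(grid)) grid <- default_lambda_grid(X, y)
  if (!length(grid)) stop("lambda grid is empty")
  grid <- sort(as.numeric(grid), decreasing = TRUE)
  patients <- unique(patient_id)
  if (length(patients) < k) stop("need at least k distinct patients")
  pf <- with_seed(seed, {
    stats::setNames(sample(rep_len(seq_len(k), length(patients))), patients)
  })
  folds <- as.integer(pf[as.character(patient_id)])
  pred <- matrix(NA_real_, nrow(X), length(grid))
  cv_tol <- 1e-5 * max(stats::sd(y), 1)  # CV needs MSE ranking, not 1e-9 coefs
  for (f in seq_len(k)) {
    tr <- folds != f
    std <- standardize_cols(X[tr, , drop = FALSE])
    Xs_te <- sweep(X[!tr, std$keep, drop = FALSE], 2, std$mean[std$keep])
    Xs_te <- sweep(Xs_te, 2, std$sd[std$keep], `/`)
    beta <- numeric(sum(std$keep))
    for (g in seq_along(grid)) {  # warm starts down the path
      beta <- lasso_cd(std$X, y[tr], grid[g], beta = beta, tol = cv_tol)
      raw <- as.numeric(Xs_te %*% beta) + mean(y[tr])
      pred[!tr, g] <- pmin(pmax(raw, 0), 100)
    }
  }
  cv_mse <- colMeans((pred - y)^2)
  bias <- colMeans(pred - y)
  ok <- abs(bias) <= bias_tol
  cand <- if (any(ok)) which(ok) else {
    warning("no lambda met the Bland-Altman bias tolerance of ", bias_tol,
            "; falling back to the unconstrained CV-MSE minimum")
    seq_along(grid)
  }
  best <- cand[which.min(cv_mse[cand])]
  # ties toward larger lambda (grid is decreasing, so the first index wins)
  best <- min(cand[cv_mse[cand] <= cv_mse[best] + 1e-12])
  structure(list(lambda = grid[best], grid = grid, cv_mse = cv_mse,
                 bias = bias, bias_ok = ok, folds = folds, k = k,
                 seed = seed),
            class = "lambda_search")
}

#' @export
print.lambda_search <- function(x, ...) {
  cat("<lambda_search> chosen lambda = ", signif(x$lambda, 4),
      " (CV-MSE ", signif(min(x$cv_mse), 4), ", ", x$k, " folds)\n", sep = "")
  invisible(x)
}

#' Report the selected (nonzero-coefficient) features of a model
#'
#' Groups nonzero coefficients by feature class and region, with counts and
#' selected/extracted percentages per class — the standard way to summarize
#' which feature families drive the quality estimate.
#'
#' @param model A [qc_train()] model with `region_class_Feature` names.
#' @return List with `n_selected`, `by_class` and `by_region` data frames,
#'   and the nonzero coefficient vector.
#' @export
selected_features <- function(model) {
  stopifnot(inherits(model, "qc_model"))
  nz <- model$beta[model$beta != 0]
  parts <- strsplit(names(model$beta), "_")
  region <- vapply(parts, `[`, character(1), 1)
  class_ <- vapply(parts, `[`, character(1), 2)
  sel <- model$beta != 0
  count_by <- function(groups) {
    tot <- table(groups)
    hit <- table(factor(groups[sel], levels = names(tot)))
    data.frame(group = names(tot), selected = as.integer(hit),
               extracted = as.integer(tot),
               percent = 100 * as.integer(hit) / as.integer(tot),
               stringsAsFactors = FALSE)
  }
  by_class <- count_by(class_)
  names(by_class)[1] <- "class"
  by_region <- count_by(region)
  names(by_region)[1] <- "region"
  list(n_selected = sum(sel), by_class = by_class, by_region = by_region,
       coefficients = nz)
}

#' Serialize / restore a trained model as JSON
#' @param model A `qc_model`.
#' @param path JSON path.
#' @return `path` invisibly; `read_qc_model` returns the model.
#' @export
write_qc_model <- function(model, path) {
  stopifnot(inherits(model, "qc_model"))
  jsonlite::write_json(
    list(feature_names = model$feature_names,
         center = as.numeric(model$center),
         scale = as.numeric(model$scale),
         beta = as.numeric(model$beta),
         intercept = model$intercept, lambda = model$lambda,
         provenance = model$provenance),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_qc_model
#' @export
read_qc_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    feature_names = j$feature_names,
    center = stats::setNames(j$center, j$feature_names),
    scale = stats::setNames(j$scale, j$feature_names),
    beta = stats::setNames(j$beta, j$feature_names),
    intercept = j$intercept, lambda = j$lambda,
    provenance = j$provenance
  ), class = "qc_model")
}
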