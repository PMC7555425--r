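make_xy <- function(n, p, support, coefs, noise_sd, intercept = 80,
                    seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- intercept + X[, support, drop = FALSE] %*% coefs +
    rnorm(n, sd = noise_sd)
  list(X = X, y = pmin(pmax(as.numeric(y), 0), 100))
}

test_that("the unpenalized limit recovers a noiseless linear rule", {
  # one informative predictor among constants: y = 2 x + 5
  set.seed(71)
  n <- 20
  x <- runif(n, 0, 10)
  X <- cbind(f1 = x, f2 = rep(1, n), f3 = rep(0, n))
  y <- 2 * x + 5
  m <- qc_train(X, y, lambda = 0)
  expect_equal(unname(m$beta["f1"] / m$scale["f1"]), 2, tolerance = 1e-6)
  expect_equal(unname(m$beta[c("f2", "f3")]), c(0, 0))  # zero-SD dropped
  expect_equal(predict(m, X), y, tolerance = 1e-6)
  # original-scale intercept
  orig_int <- m$intercept - sum(m$beta / m$scale * m$center)
  expect_equal(orig_int, 5, tolerance = 1e-6)
})

test_that("a huge penalty shrinks everything to the response mean", {
  d <- make_xy(50, 20, support = 1:3, coefs = c(2, -1, 3), noise_sd = 1)
  m <- qc_train(d$X, d$y, lambda = 1e6)
  expect_true(all(m$beta == 0))
  expect_equal(predict(m, d$X), rep(mean(d$y), 50))
})

test_that("sparsity is nonincreasing along an increasing lambda path", {
  d <- make_xy(80, 40, support = c(2, 9, 17), coefs = c(4, -3, 2),
               noise_sd = 1.5, seed = 72)
  lambdas <- c(0.01, 0.05, 0.2, 0.8, 3, 10)
  nnz <- vapply(lambdas, function(l) sum(qc_train(d$X, d$y, l)$beta != 0),
                numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("coordinate descent agrees with an independent lasso solver", {
  skip_if_not_installed("glmnet")
  d <- make_xy(120, 30, support = c(3, 11, 25), coefs = c(3, -2, 2),
               noise_sd = 1, seed = 73)
  for (lambda in c(0.05, 0.5, 2)) {
    m <- qc_train(d$X, d$y, lambda)
    g <- glmnet::glmnet(d$X, d$y, lambda = lambda, standardize = TRUE,
                        thresh = 1e-14)
    pred_g <- pmin(pmax(as.numeric(predict(g, d$X)), 0), 100)
    expect_equal(predict(m, d$X), pred_g, tolerance = 1e-5)
  }
})

test_that("prediction clamps to the 0-100 score range", {
  d <- make_xy(30, 5, support = 1, coefs = 2, noise_sd = 1)
  m <- qc_train(d$X, d$y, lambda = 0.1)
  m$intercept <- 110   # craft raw outputs outside the scale
  m$beta[] <- 0
  expect_equal(predict(m, d$X[1, , drop = FALSE]), 100)
  m$intercept <- -3
  expect_equal(predict(m, d$X[1, , drop = FALSE]), 0)
  m$intercept <- 82.5
  expect_equal(predict(m, d$X[1, , drop = FALSE]), 82.5)
})

test_that("prediction refuses mismatched feature names", {
  d <- make_xy(30, 5, support = 1, coefs = 2, noise_sd = 1)
  m <- qc_train(d$X, d$y, lambda = 0.1)
  bad <- d$X; colnames(bad)[2] <- "other"
  expect_error(predict(m, bad), "missing: f2")
  expect_error(predict(m, d$X[, 1:3]), "missing")
})

test_that("input contracts are enforced", {
  d <- make_xy(30, 5, support = 1, coefs = 2, noise_sd = 1)
  expect_error(qc_train(d$X, d$y[-1], lambda = 0.1), "differ in length")
  expect_error(qc_train(d$X[1:5, ], d$y[1:5], 0.1), "at least 10")
  expect_error(qc_train(d$X, d$y + 200, 0.1), "\\[0, 100\\]")
  expect_error(qc_select_lambda(d$X, d$y, grid = numeric(0)), "empty")
  expect_error(qc_select_lambda(d$X, d$y, k = 1), "k must be")
})

test_that("cross-validation folds respect patient boundaries and the seed", {
  d <- make_xy(60, 15, support = c(1, 4), coefs = c(3, -2), noise_sd = 1,
               seed = 74)
  patients <- rep(sprintf("p%02d", 1:15), each = 4)  # 4 segmentations each
  s1 <- qc_select_lambda(d$X, d$y, patient_id = patients, k = 5, seed = 42)
  s2 <- qc_select_lambda(d$X, d$y, patient_id = patients, k = 5, seed = 42)
  expect_identical(s1$folds, s2$folds)
  expect_identical(s1$lambda, s2$lambda)
  per_patient <- tapply(s1$folds, patients, function(f) length(unique(f)))
  expect_true(all(per_patient == 1))
  expect_equal(sort(unique(s1$folds)), 1:5)
})

test_that("near-noiseless data drives the chosen lambda to the small end", {
  d <- make_xy(60, 10, support = 1:2, coefs = c(4, -3), noise_sd = 1e-4,
               seed = 75)
  s <- qc_select_lambda(d$X, d$y, k = 5, seed = 2)
  expect_lt(min(s$cv_mse), 0.01)
  expect_lt(s$lambda, sort(s$grid, decreasing = TRUE)[20])
  expect_true(s$lambda %in% s$grid)
})

test_that("selected-feature report groups nonzero coefficients correctly", {
  nm <- feature_names()
  d <- make_xy(40, 321, support = c(1, 40, 150), coefs = c(4, 3, -2),
               noise_sd = 0.5, seed = 76)
  colnames(d$X) <- nm
  m <- qc_train(d$X, d$y, lambda = 1)
  rep_ <- selected_features(m)
  expect_equal(rep_$n_selected, sum(m$beta != 0))
  expect_equal(sum(rep_$by_class$selected), rep_$n_selected)
  expect_equal(sum(rep_$by_region$selected), rep_$n_selected)
  expect_true(all(rep_$by_class$percent >= 0 & rep_$by_class$percent <= 100))
  m0 <- qc_train(d$X, d$y, lambda = 1e6)
  expect_equal(selected_features(m0)$n_selected, 0)
})

test_that("model JSON round trip reproduces predictions exactly", {
  d <- make_xy(40, 12, support = c(2, 7), coefs = c(3, -2), noise_sd = 1,
               seed = 77)
  m <- qc_train(d$X, d$y, lambda = 0.2)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_qc_model(m, tmp)
  back <- read_qc_model(tmp)
  expect_equal(predict(back, d$X), predict(m, d$X))
  expect_equal(back$lambda, m$lambda)
})
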