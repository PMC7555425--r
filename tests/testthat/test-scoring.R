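cohort_with_means <- function(mean_dsc = 0.9, mean_arvd = 5, mean_hd = 4,
                              mean_asd = 1) {
  # two symmetric panels around the target means -> exact cohort means
  up <- panel_from_values(rep(c(mean_dsc + 0.02, mean_arvd + 1,
                                mean_hd + 0.5, mean_asd + 0.2), each = 3))
  dn <- panel_from_values(rep(c(mean_dsc - 0.02, mean_arvd - 1,
                                mean_hd - 0.5, mean_asd - 0.2), each = 3))
  list(up, dn)
}

test_that("calibration lines pass through the two anchor points", {
  cal <- fit_calibration(cohort_with_means(mean_dsc = 0.9, mean_hd = 4))
  s_dsc <- function(d) cal$slope["whole_DSC"] * d + cal$intercept["whole_DSC"]
  expect_equal(unname(s_dsc(1)), 100)
  expect_equal(unname(s_dsc(0.9)), 85)
  expect_equal(unname(s_dsc(0.8)), 70)         # s(d) = 100 - 150 (1 - d)
  expect_equal(unname(cal$slope["whole_DSC"]), 150)
  s_hd <- function(h) cal$slope["apex_HD95"] * h + cal$intercept["apex_HD95"]
  expect_equal(unname(s_hd(0)), 100)
  expect_equal(unname(s_hd(4)), 85)
  expect_equal(unname(cal$slope["apex_HD95"]), -3.75)
  # error cells slope down, DSC up
  expect_true(all(cal$slope[grepl("DSC", names(cal$slope))] > 0))
  expect_true(all(cal$slope[!grepl("DSC", names(cal$slope))] < 0))
})

test_that("a zero-error cohort leaves the calibration underdetermined", {
  perfect <- panel_from_values(rep(c(1, 0, 0, 0), each = 3))
  expect_error(fit_calibration(list(perfect, perfect)), "underdetermined")
  expect_error(fit_calibration(list(panel_from_values(rep(0.5, 12)))),
               "at least 2")
})

test_that("panel scoring anchors, averages, clips and floors invalid cells", {
  cal <- fit_calibration(cohort_with_means())
  perfect <- panel_from_values(rep(c(1, 0, 0, 0), each = 3))
  qs <- score_panel(perfect, cal)
  expect_equal(qs$value, 100)
  expect_equal(unname(qs$cell_scores), rep(100, 12))

  at_mean <- panel_from_values(rep(c(0.9, 5, 4, 1), each = 3))
  expect_equal(score_panel(at_mean, cal)$value, 85)

  # a hopeless metric clips at the 0 floor rather than going negative
  awful <- panel_from_values(rep(c(0.0, 500, 400, 100), each = 3))
  qa <- score_panel(awful, cal)
  expect_true(all(qa$cell_scores >= 0 & qa$cell_scores <= 100))
  expect_equal(unname(qa$cell_scores["whole_aRVD"]), 0)

  # invalid cells score 0
  vals <- rep(c(0.9, 5, 4, 1), each = 3)
  pan <- panel_from_values(vals)
  attr(pan, "valid")["apex_HD95"] <- FALSE
  qs2 <- score_panel(pan, cal)
  expect_equal(unname(qs2$cell_scores["apex_HD95"]), 0)
  expect_equal(qs2$value, mean(qs2$cell_scores))
})

test_that("the cohort scored with its own calibration averages to the anchor", {
  set.seed(51)
  for (rep in 1:5) {
    cohort <- lapply(1:8, function(i)
      panel_from_values(c(runif(3, 0.85, 0.99), runif(3, 1, 10),
                          runif(3, 0.5, 6), runif(3, 0.2, 2))))
    cal <- fit_calibration(cohort, anchor = 85)
    scores <- vapply(cohort, function(p) score_panel(p, cal)$value, numeric(1))
    clipped <- any(vapply(cohort, function(p) {
      raw <- cal$slope * unclass(p) + cal$intercept
      any(raw < 0 | raw > 100)
    }, logical(1)))
    if (!clipped) expect_equal(mean(scores), 85, tolerance = 1e-10)
  }
})

test_that("worsening any single metric cell never raises the score", {
  cal <- fit_calibration(cohort_with_means())
  base_vals <- rep(c(0.92, 4, 3, 0.8), each = 3)
  base_score <- score_panel(panel_from_values(base_vals), cal)$value
  for (cell in seq_len(12)) {
    worse <- base_vals
    # worse = lower DSC (cells 1-3), higher error metrics (cells 4-12)
    worse[cell] <- if (cell <= 3) worse[cell] - 0.1 else worse[cell] * 2
    expect_lte(score_panel(panel_from_values(worse), cal)$value, base_score)
  }
})

test_that("calibration JSON round trip preserves every coefficient", {
  cal <- fit_calibration(cohort_with_means())
  tmp <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, tmp)
  back <- read_calibration(tmp)
  expect_equal(back$slope, cal$slope)
  expect_equal(back$intercept, cal$intercept)
  expect_equal(back$anchor, cal$anchor)
  pan <- panel_from_values(rep(c(0.9, 5, 4, 1), each = 3))
  expect_equal(score_panel(pan, back)$value, score_panel(pan, cal)$value)
})
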