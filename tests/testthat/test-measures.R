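panel_get <- function(panel, name, col = "estimate") {
  panel[panel$measure == name, col]
}

test_that("build_two_by_two tabulates with the fixed orientation", {
  tab <- build_two_by_two(data.frame(index_result = c("pos", "neg"),
                                     reference_result = c("pos", "neg")))
  expect_identical(c(tab$tp, tab$fp, tab$fn, tab$tn), c(1, 0, 0, 1))

  tab <- build_two_by_two(data.frame(index_result = rep("pos", 3),
                                     reference_result = rep("neg", 3)))
  expect_identical(c(tab$tp, tab$fp, tab$fn, tab$tn), c(0, 3, 0, 0))

  # list-of-pairs input, counts sum to the participant total
  tab <- build_two_by_two(list(c("pos", "pos"), c("pos", "neg"),
                               c("neg", "pos"), c("neg", "neg")))
  expect_identical(tab$tp + tab$fp + tab$fn + tab$tn, 4)

  expect_error(build_two_by_two(data.frame()), "non-empty")
  expect_error(build_two_by_two(data.frame(index_result = "yes",
                                           reference_result = "pos")),
               "'pos' or 'neg'")
})

test_that("cohort measures match hand arithmetic over the table cells", {
  panel <- compute_measures(two_by_two(tp = 90, fp = 20, fn = 10, tn = 80),
                            "cohort")
  expect_equal(panel_get(panel, "sensitivity"), 0.9)
  expect_equal(panel_get(panel, "specificity"), 0.8)
  expect_equal(panel_get(panel, "ppv"), 90 / 110)
  expect_equal(panel_get(panel, "npv"), 80 / 90)
  expect_equal(panel_get(panel, "apparent_prevalence"), 0.5)
  expect_equal(panel_get(panel, "lr_positive"), 4.5)
  expect_equal(panel_get(panel, "lr_negative"), 0.125)
  expect_equal(panel_get(panel, "diagnostic_odds_ratio"), 36)
  expect_equal(panel_get(panel, "accuracy"), 0.85)
  expect_true(all(panel$validity == "valid"))

  perfect <- compute_measures(two_by_two(50, 0, 0, 50), "cohort")
  expect_equal(panel_get(perfect, "sensitivity"), 1)
  expect_equal(panel_get(perfect, "specificity"), 1)
})

test_that("case-control sampling suppresses predictive values and prevalence", {
  panel <- compute_measures(two_by_two(90, 20, 10, 80), "case_control")
  for (m in c("ppv", "npv", "apparent_prevalence")) {
    expect_identical(panel_get(panel, m, "validity"), "invalid_for_design")
    expect_true(is.na(panel_get(panel, m)))
  }
  expect_match(panel_get(panel, "apparent_prevalence", "note"),
               "artificial result of the design")
  # the prevalence-independent measures survive
  expect_equal(panel_get(panel, "sensitivity"), 0.9)
  expect_equal(panel_get(panel, "specificity"), 0.8)
  expect_equal(panel_get(panel, "diagnostic_odds_ratio"), 36)
})

test_that("zero denominators yield an explicit undefined status, no corrections", {
  # all reference-negative: sensitivity has an empty positive column
  panel <- compute_measures(two_by_two(0, 20, 0, 80), "cohort")
  expect_identical(panel_get(panel, "sensitivity", "validity"),
                   "undefined_zero_denominator")
  expect_true(is.na(panel_get(panel, "sensitivity")))
  # perfect specificity makes LR+ divide by zero
  panel <- compute_measures(two_by_two(10, 0, 10, 80), "cohort")
  expect_identical(panel_get(panel, "lr_positive", "validity"),
                   "undefined_zero_denominator")
  expect_identical(panel_get(panel, "diagnostic_odds_ratio", "validity"),
                   "undefined_zero_denominator")
  expect_error(compute_measures(two_by_two(0, 0, 0, 0), "cohort"), "empty")
})

test_that("DOR equals LR+/LR- and the cross-product ratio on all-positive tables", {
  set.seed(42)
  for (i in 1:50) {
    cells <- sample(1:500, 4, replace = TRUE)
    tab <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    panel <- compute_measures(tab, "cohort")
    dor <- panel_get(panel, "diagnostic_odds_ratio")
    lr_ratio <- panel_get(panel, "lr_positive") / panel_get(panel, "lr_negative")
    cross <- (tab$tp * tab$tn) / (tab$fp * tab$fn)
    expect_equal(dor, lr_ratio, tolerance = 1e-12)
    expect_equal(dor, cross, tolerance = 1e-12)
  }
})

test_that("sensitivity and specificity are invariant to column rescaling", {
  # multiplying the reference-positive and reference-negative columns by
  # independent constants changes nothing -- the property that makes them,
  # unlike predictive values, estimable under case-control sampling
  set.seed(99)
  for (i in 1:30) {
    cells <- sample(1:200, 4, replace = TRUE)
    k <- sample(1:7, 2)
    base <- compute_measures(two_by_two(cells[1], cells[2], cells[3], cells[4]),
                             "cohort")
    scaled <- compute_measures(two_by_two(cells[1] * k[1], cells[2] * k[2],
                                          cells[3] * k[1], cells[4] * k[2]),
                               "cohort")
    expect_equal(panel_get(scaled, "sensitivity"),
                 panel_get(base, "sensitivity"), tolerance = 1e-12)
    expect_equal(panel_get(scaled, "specificity"),
                 panel_get(base, "specificity"), tolerance = 1e-12)
  }
})

test_that("optional confidence intervals bracket the point estimates", {
  panel <- compute_measures(two_by_two(90, 20, 10, 80), "cohort",
                            conf_level = 0.95)
  valid <- panel[panel$validity == "valid", ]
  expect_true(all(valid$lower <= valid$estimate + 1e-12))
  expect_true(all(valid$upper >= valid$estimate - 1e-12))
  props <- valid[valid$measure %in% c("sensitivity", "specificity", "ppv",
                                      "npv", "apparent_prevalence",
                                      "accuracy"), ]
  expect_true(all(props$lower >= 0 & props$upper <= 1))
  # Wilson interval cross-checked against the closed form at x=90, n=100
  z <- qnorm(0.975)
  p <- 0.9; n <- 100
  expect_equal(panel_get(panel, "sensitivity", "lower"),
               ((p + z^2 / (2 * n)) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
                 (1 + z^2 / n))
})
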