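stage_vectors <- function(cells) {
  # cells = c(pred IA & true IA, pred IA & true IB,
  #           pred IB & true IA, pred IB & true IB)
  list(
    pred = rep(c("IA", "IA", "IB", "IB"), cells),
    true = rep(c("IA", "IB", "IA", "IB"), cells)
  )
}

test_that("diagnostic summary reproduces the published accuracy arithmetic", {
  sv <- stage_vectors(c(30, 3, 7, 8))
  ds <- diagnostic_summary(sv$pred, sv$true)
  expect_equal(ds$accuracy, 38 / 48)
  expect_equal(ds$over_diagnosis_rate, 7 / 10)
  expect_equal(ds$under_diagnosis_rate, 3 / 10)

  rad <- stage_vectors(c(39, 2, 14, 17))
  dr <- diagnostic_summary(rad$pred, rad$true)
  expect_equal(dr$accuracy, 56 / 72)
  expect_equal(dr$over_diagnosis_rate, 14 / 16)
})

test_that("diagnostic counts are conserved and edge cases flagged", {
  set.seed(10)
  for (k in 1:10) {
    n <- sample(5:60, 1)
    pred <- sample(c("IA", "IB"), n, replace = TRUE)
    true <- sample(c("IA", "IB"), n, replace = TRUE)
    ds <- diagnostic_summary(pred, true)
    expect_identical(ds$n_compatible + ds$n_over + ds$n_under, ds$n)
  }
  perfect <- diagnostic_summary(c("IA", "IB"), c("IA", "IB"))
  expect_false(perfect$rates_defined)
  expect_identical(perfect$over_diagnosis_rate, 0)
  expect_error(diagnostic_summary("IA", c("IA", "IB")))
  expect_error(diagnostic_summary("II", "IA"))
})

test_that("chi-square matches the published footnote values", {
  r <- pearson_chi2(matrix(c(38, 10, 56, 16), 2, byrow = TRUE))
  expect_equal(round(r$chi2, 3), 0.033)
  expect_equal(round(r$p, 3), 0.856)
  expect_identical(r$df, 1L)

  leio <- pearson_chi2(matrix(c(9, 6, 29, 4), 2, byrow = TRUE))
  expect_equal(round(leio$p, 3), 0.027)

  flat <- pearson_chi2(matrix(10, 2, 2))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)
})

test_that("chi-square equals the brute-force cell sum on random tables", {
  set.seed(4)
  for (k in 1:20) {
    tab <- matrix(sample(1:40, 4, replace = TRUE), 2)
    expect_equal(pearson_chi2(tab)$chi2, oracle_chi2(tab), tolerance = 1e-12)
  }
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 3), 2, byrow = TRUE)),
               class = "myoinvade_degenerate_error")
  expect_true(pearson_chi2(matrix(c(2, 1, 3, 2), 2))$small_expected)
})

test_that("correlation matches hand computation", {
  expect_equal(pearson_correlation(1:10, 2 * (1:10) + 1)$r, 1)
  expect_lt(pearson_correlation(1:10, 2 * (1:10) + 1)$p, 1e-6)
  expect_equal(pearson_correlation(c(1, 2, 3), c(3, 2, 1))$r, -1)
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)),
               class = "myoinvade_degenerate_error")
})

test_that("one-way ANOVA matches the hand decomposition", {
  r <- oneway_anova(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(r$F, 1.5)
  expect_identical(c(r$df_between, r$df_within), c(1L, 4L))
  expect_equal(r$p, 1 - stats::pf(1.5, 1, 4))

  same <- oneway_anova(list(c(1, 2, 3), c(3, 2, 1), c(2, 2, 2)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  degen <- oneway_anova(list(c(1, 1, 1), c(2, 2, 2)))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 0)
  expect_error(oneway_anova(list(1:3)))
})

test_that("ANOVA on two groups satisfies F = t^2", {
  set.seed(6)
  for (k in 1:10) {
    a <- stats::rnorm(sample(4:12, 1))
    b <- stats::rnorm(sample(4:12, 1), mean = stats::runif(1, -1, 1))
    f <- oneway_anova(list(a, b))$F
    t <- stats::t.test(a, b, var.equal = TRUE)$statistic
    expect_equal(f, unname(t)^2, tolerance = 1e-10)
  }
})

test_that("five-number summaries use linear-interpolation quartiles", {
  expect_equal(unlist(five_number_summary(1:5)), c(min = 1, q1 = 2, median = 3,
                                                   q3 = 4, max = 5))
  f <- five_number_summary(c(0, 0.5, 1))
  expect_equal(f$q1, 0.25)
  expect_equal(f$q3, 0.75)
  f1 <- five_number_summary(7)
  expect_true(all(unlist(f1) == 7))
  expect_true(with(five_number_summary(stats::rnorm(50)),
                   min <= q1 && q1 <= median && median <= q3 && q3 <= max))
  expect_error(five_number_summary(numeric(0)))
})

test_that("tidiers return broom-shaped tibbles", {
  ct <- pearson_chi2(matrix(c(9, 6, 29, 4), 2, byrow = TRUE))
  td <- tidy(ct)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("statistic", "df", "p.value", "method"))
  expect_equal(td$p.value, ct$p)
  av <- tidy(oneway_anova(list(1:4, 2:5)))
  expect_true(all(c("statistic", "p.value") %in% names(av)))
})

test_that("printed-table reproduction flags the known inconsistencies", {
  rep <- reproduce_printed_tables()
  expect_s3_class(rep, "printed_tables_report")
  expect_identical(nrow(rep), 28L)
  mism <- rep$quantity[!rep$match]
  expect_setequal(mism, c(
    "chi2_ai_t2_vs_radiologists", "p_ai_t2_vs_radiologists",
    "accuracy_ai_t2_with", "p_leiomyoma_ai_t2", "p_histology_ai_t2"
  ))
})
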