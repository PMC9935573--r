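test_that("zero coefficients give prevalence near one half and generation is bit-reproducible", {
  spec0 <- cohort_spec(4000, seed = 11,
                       coef = list(intercept = 0, pp = 0, lpca = 0,
                                   diabetes = 0, mi = 0, stroke = 0))
  co <- generate_cohort(spec0)
  expect_lt(abs(mean(co$subjects$ci_label) - 0.5), 0.03)

  co2 <- generate_cohort(spec0)
  expect_identical(co$subjects, co2$subjects)
  expect_identical(co$measurements, co2$measurements)
  co3 <- generate_cohort(cohort_spec(4000, seed = 12,
                                     coef = spec0$coef))
  expect_false(identical(co$subjects$age, co3$subjects$age))
})

test_that("every generated measurement respects SBP > DBP and scores stay in range", {
  co <- generate_cohort(cohort_spec(500, seed = 3))
  expect_true(all(co$measurements$sbp > co$measurements$dbp))
  expect_true(all(co$measurements$dbp > 0))
  sc <- unlist(co$subjects[c("ba_score", "rpca_score", "lpca_score")])
  expect_true(all(sc >= 0 & sc < 100))
  expect_true(all(table(co$measurements$subject_id) >= 1))
  expect_gt(mean(co$subjects$ci_label), 0)
  expect_lt(mean(co$subjects$ci_label), 1)
})

test_that("a univariate fit recovers the generating pulse-pressure odds ratio", {
  # pure-PP generator (all other coefficients zero), no measurement noise:
  # the fitted univariate CI should cover the true OR 1.04 in most replicates
  hits <- 0
  for (r in 1:10) {
    spec <- cohort_spec(5000, seed = 600 + r, n_meas_mean = 1,
                        meas_noise_sbp = 0, meas_noise_dbp = 0,
                        meas_noise_pulse = 0,
                        coef = list(intercept = qlogis(0.35) - log(1.04) * 61,
                                    pp = log(1.04), lpca = 0, diabetes = 0,
                                    mi = 0, stroke = 0))
    tab <- assemble_analysis_table(generate_cohort(spec))
    or <- fit_or_model(tab, "pp")
    if (or$ci_low <= 1.04 && 1.04 <= or$ci_high) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("degenerate cohort sizes are rejected", {
  expect_error(cohort_spec(0), "positive")
  expect_error(cohort_spec(-5), "positive")
})

test_that("cohort CSV round trip preserves the tables", {
  co <- generate_cohort(cohort_spec(50, seed = 9))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  co2 <- read_cohort(dir)
  expect_equal(co2$subjects$bmi, co$subjects$bmi, tolerance = 1e-12)
  expect_equal(co2$measurements$sbp, co$measurements$sbp)
})
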