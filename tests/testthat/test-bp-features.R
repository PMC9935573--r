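test_that("derived pressures follow the textbook formulas from the measurement means", {
  f <- derive_bp_features(data.frame(sbp = 120, dbp = 80, pulse = 70))
  expect_equal(f$pp, 40)
  expect_equal(f$map, 80 + 40 / 3)
  expect_equal(f$ppi, 40 / 120)

  f2 <- derive_bp_features(data.frame(sbp = c(130, 134), dbp = c(70, 70),
                                      pulse = c(60, 80)))
  expect_equal(f2$sbp, 132)
  expect_equal(f2$pp, 62)
  expect_equal(f2$map, 70 + 62 / 3)
  expect_equal(f2$pulse, 70)
})

test_that("invalid measurements are rejected and empty input errors", {
  expect_warning(
    f <- derive_bp_features(data.frame(sbp = c(120, 80), dbp = c(80, 80),
                                       pulse = c(70, 70))),
    "rejected")
  expect_equal(f$n_used, 1L)
  expect_equal(f$n_rejected, 1L)
  expect_error(
    suppressWarnings(derive_bp_features(
      data.frame(sbp = 80, dbp = 80, pulse = 60))),
    "no valid measurements")
})

test_that("feature derivation is invariant to measurement order", {
  m <- data.frame(sbp = c(118, 131, 140, 125), dbp = c(64, 70, 82, 71),
                  pulse = c(61, 72, 77, 66))
  f1 <- derive_bp_features(m)
  f2 <- derive_bp_features(m[c(3, 1, 4, 2), ])
  expect_equal(f1[c("sbp", "dbp", "pp", "map", "ppi")],
               f2[c("sbp", "dbp", "pp", "map", "ppi")])
})

test_that("BMI arithmetic and input validation", {
  expect_equal(compute_bmi(1.70, 72.25), 25)
  w <- runif(5, 50, 90)
  expect_equal(compute_bmi(rep(1, 5), w), w)
  expect_error(compute_bmi(0, 70), "positive")
  expect_error(compute_bmi(1.7, -1), "positive")
})

test_that("guideline boundaries route the published example values to their categories", {
  b <- bp_boundaries()
  expect_equal(as.character(categorize_bp(119, b$sbp)), "first")
  expect_equal(as.character(categorize_bp(120, b$sbp)), "second")
  expect_equal(as.character(categorize_bp(135, b$sbp)), "third")
  expect_equal(as.character(categorize_bp(69.9, b$dbp)), "first")
  expect_equal(as.character(categorize_bp(70, b$dbp)), "second")
  expect_equal(as.character(categorize_bp(80, b$dbp)), "third")
  expect_equal(as.character(categorize_bp(57.9, b$pp)), "first")
  expect_equal(as.character(categorize_bp(58, b$pp)), "second")  # lower bound inclusive
  expect_equal(as.character(categorize_bp(66, b$pp)), "third")
  expect_equal(as.character(categorize_bp(0.44, b$ppi)), "first")
  expect_equal(as.character(categorize_bp(0.45, b$ppi)), "second")
  expect_equal(as.character(categorize_bp(0.49, b$ppi)), "third")
  expect_equal(as.character(categorize_bp(87.9, b$map)), "first")
  expect_equal(as.character(categorize_bp(93, b$map)), "third")
  expect_equal(as.character(categorize_bp(67, b$pulse)), "first")
  expect_equal(as.character(categorize_bp(72, b$pulse)), "third")
  expect_equal(attr(categorize_bp(60, b$pp), "reference"), "second")
  expect_error(categorize_bp(1, c(5, 5)), "increasing")
})

test_that("empirical tertiles split a sample into thirds", {
  x <- rexp(3000)
  ct <- categorize_bp(x, empirical_tertiles(x))
  expect_true(all(abs(table(ct) / 3000 - 1 / 3) < 0.02))
})

test_that("case-control matching applies the sex-exact age-caliper rule", {
  subj <- data.frame(
    subject_id = c("C1", "P1", "P2"),
    age = c(84, 85, 84), sex = c("M", "M", "F"),
    ci_label = c(1, 0, 0))
  m <- match_case_control(subj)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$control_id, "P1")  # same sex beats same age

  subj2 <- data.frame(subject_id = c("C1", "P1"), age = c(84, 86),
                      sex = c("M", "M"), ci_label = c(1, 0))
  m2 <- match_case_control(subj2)
  expect_equal(nrow(m2$pairs), 0L)
  expect_equal(m2$unmatched, "C1")

  # tie on |age difference| breaks to the lowest control id
  subj3 <- data.frame(subject_id = c("C1", "P9", "P2"), age = c(84, 85, 83),
                      sex = "M", ci_label = c(1, 0, 0))
  m3 <- match_case_control(subj3)
  expect_equal(m3$pairs$control_id, "P2")
})

test_that("matched sets are balanced by construction on a simulated cohort", {
  co <- generate_cohort(cohort_spec(600, seed = 21))
  m <- match_case_control(co$subjects, seed = 4)
  expect_gt(nrow(m$pairs), 0)
  expect_true(all(abs(m$pairs$case_age - m$pairs$control_age) <= 1))
  by_id <- co$subjects[match(m$pairs$control_id, co$subjects$subject_id), ]
  expect_true(all(by_id$sex == m$pairs$sex))
  expect_false(any(duplicated(m$pairs$control_id)))
  # empty pool: every case unmatched, no exception
  cases_only <- co$subjects[co$subjects$ci_label == 1, ]
  m0 <- match_case_control(cases_only)
  expect_equal(nrow(m0$pairs), 0L)
  expect_equal(length(m0$unmatched), nrow(cases_only))
})

test_that("the analysis table carries features, categories and stenosis grades", {
  co <- generate_cohort(cohort_spec(200, seed = 8))
  tab <- assemble_analysis_table(co)
  expect_equal(nrow(tab), 200L)
  expect_true(all(tab$pp > 0))
  expect_true(all(tab$map >= tab$dbp & tab$map <= tab$sbp))
  expect_true(all(tab$ppi > 0 & tab$ppi < 1))
  expect_equal(tab$map, tab$dbp + tab$pp / 3, tolerance = 1e-12)
  expect_s3_class(tab$pp_cat, "factor")
  expect_equal(tab$lpca_ge50, as.integer(tab$lpca_score >= 50))
})
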