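test_that("the stratified split preserves class balance and is reproducible", {
  tab <- synthetic_table(100, seed = 5, kind = "null")
  sp <- split_cohort(tab, seed = 9)
  expect_equal(nrow(sp$train), 80L)
  expect_equal(nrow(sp$holdout), 20L)
  p_all <- mean(tab$ci_label)
  expect_lte(abs(sum(sp$train$ci_label) - 80 * p_all), 1)
  sp2 <- split_cohort(tab, seed = 9)
  expect_identical(sp$train, sp2$train)
  sp3 <- split_cohort(tab, seed = 10)
  expect_false(identical(sp$train, sp3$train))
  tiny <- data.frame(ci_label = c(0, 0, 1, 1), x = 1:4)
  expect_error(suppressWarnings(split_cohort(tiny)), "stratified")
})

test_that("feature sets are strictly nested", {
  f1 <- feature_set_spec(1); f2 <- feature_set_spec(2); f3 <- feature_set_spec(3)
  expect_true(all(f1 %in% f2) && length(f2) > length(f1))
  expect_true(all(f2 %in% f3) && length(f3) > length(f2))
  expect_error(feature_set_spec(4), "1, 2 or 3")
})

test_that("all four learners separate a thresholded label and stay at chance on noise", {
  sep <- synthetic_table(400, seed = 6, kind = "separable")
  sps <- split_cohort(sep, seed = 2)
  r <- train_evaluate(sps$train, sps$holdout, c("sbp", "dbp", "pulse"), seed = 3)
  expect_true(all(r$summary$cv_auc >= 0.95))

  null <- synthetic_table(400, seed = 7, kind = "null")
  spn <- split_cohort(null, seed = 2)
  rn <- train_evaluate(spn$train, spn$holdout, c("sbp", "dbp", "pulse"), seed = 3)
  expect_true(all(abs(rn$summary$cv_auc - 0.5) <= 0.1))
})

test_that("constant features are dropped with a warning rather than crashing a learner", {
  tab <- synthetic_table(200, seed = 8, kind = "separable")
  tab$flat <- 1
  sp <- split_cohort(tab, seed = 1)
  expect_warning(
    r <- train_evaluate(sp$train, sp$holdout, c("sbp", "flat"), learners = "lr",
                        seed = 1),
    "constant feature")
  expect_gt(r$summary$cv_auc, 0.9)
})

test_that("AUC is the Mann-Whitney statistic and invariant to monotone score transforms", {
  withr::local_seed(11)
  y <- rbinom(300, 1, 0.4)
  s <- rnorm(300) + y
  a1 <- auc_mw(y, s)
  expect_equal(a1, auc_mw(y, exp(s)), tolerance = 1e-12)
  expect_equal(a1, auc_mw(y, rank(s)), tolerance = 1e-12)
  # agreement with the trapezoidal ROC area from pROC
  expect_equal(a1, as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-9)
  expect_error(auc_mw(rep(1, 5), rnorm(5)), "class is absent")
})

test_that("the DeLong comparison matches pROC and is exact in its degenerate cases", {
  withr::local_seed(12)
  y <- rbinom(200, 1, 0.5)
  good <- y + rnorm(200, 0, 0.4)
  rand <- rnorm(200)

  self <- delong_compare(y, good, good)
  expect_equal(self$diff, 0)
  expect_equal(self$p_value, 1)

  d <- delong_compare(y, good, rand)
  expect_lt(d$p_value, 1e-3)
  expect_equal(d$auc_a, auc_mw(y, good), tolerance = 1e-9)

  pr <- pROC::roc.test(pROC::roc(y, good, quiet = TRUE),
                       pROC::roc(y, rand, quiet = TRUE),
                       method = "delong", paired = TRUE)
  expect_equal(d$p_value, pr$p.value, tolerance = 1e-9)

  expect_error(delong_compare(rep(1, 10), rnorm(10), rnorm(10)), "single class")
})

test_that("stenosis signal in the generator lifts the stenosis-bearing feature set", {
  co <- generate_cohort(cohort_spec(2000, seed = 15))
  tab <- assemble_analysis_table(co)
  sp <- split_cohort(tab, seed = 15)
  r1 <- train_evaluate(sp$train, sp$holdout, 1, learners = "lr", seed = 15)
  r3 <- train_evaluate(sp$train, sp$holdout, 3, learners = "lr", seed = 15)
  expect_gt(r3$summary$cv_auc, r1$summary$cv_auc)
})
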