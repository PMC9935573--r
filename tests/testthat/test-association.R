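test_that("group comparison routes to the right test and handles degenerate input", {
  withr::local_seed(31)
  # identical balanced binary variable: chi-squared p = 1
  df <- data.frame(ci_label = rep(0:1, each = 50),
                   flag = factor(rep(c(0, 1), times = 50)))
  r <- compare_groups(df, "flag")
  expect_equal(r$test, "chi-squared")
  expect_equal(r$p_value, 1)

  # strongly shifted normals: t test, tiny p
  df2 <- data.frame(ci_label = rep(0:1, each = 100),
                    x = c(rnorm(100, 0, 1), rnorm(100, 2, 1)))
  r2 <- compare_groups(df2, "x")
  expect_equal(r2$test, "t")
  expect_lt(r2$p_value, 1e-3)

  # skewed data fails the normality gate and goes to Mann-Whitney
  df3 <- data.frame(ci_label = rep(0:1, each = 150),
                    x = rexp(300)^2)
  expect_equal(compare_groups(df3, "x")$test, "mann-whitney")

  # empty expected cell: exact-test fallback with warning
  df4 <- data.frame(ci_label = rep(0:1, each = 30),
                    flag = factor(c(rep(0, 30), rep(0, 28), 1, 1)))
  expect_warning(r4 <- compare_groups(df4, "flag"), "Fisher")
  expect_equal(r4$test, "fisher")

  expect_error(compare_groups(data.frame(ci_label = rep(0:1, 20), x = 1), "x"),
               "constant")
})

test_that("a null predictor gives an odds ratio near one with a straddling interval", {
  withr::local_seed(41)
  df <- data.frame(ci_label = rbinom(800, 1, 0.4), x = rnorm(800))
  or <- fit_or_model(df, "x")
  expect_lt(or$ci_low, 1)
  expect_gt(or$ci_high, 1)
  expect_equal(or$or, 1, tolerance = 0.25)
})

test_that("logistic odds ratios agree with a direct likelihood maximization", {
  withr::local_seed(51)
  n <- 200
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rbinom(n, 1, 0.3))
  lp <- -0.3 + 0.8 * df$x1 - 0.5 * df$x2 + 0.6 * df$x3
  df$ci_label <- rbinom(n, 1, plogis(lp))
  or <- fit_or_model(df, "x1", adjust = c("x2", "x3"))

  # independent route: direct Newton-free optimization of the log-likelihood
  X <- cbind(1, df$x1, df$x2, df$x3)
  nll <- function(b) {
    eta <- X %*% b
    -sum(df$ci_label * eta - log1p(exp(eta)))
  }
  opt <- optim(rep(0, 4), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(unname(or$or), exp(opt$par[2]), tolerance = 1e-4)
})

test_that("on a saturated binary design the logistic OR equals the cross-product ratio", {
  counts <- c(n00 = 73, n01 = 29, n10 = 41, n11 = 38)  # (x, y) cells
  df <- data.frame(
    x = rep(c(0, 0, 1, 1), counts),
    ci_label = rep(c(0, 1, 0, 1), counts))
  or <- fit_or_model(df, "x")
  xpr <- (counts["n11"] * counts["n00"]) / (counts["n10"] * counts["n01"])
  expect_equal(unname(or$or), unname(xpr), tolerance = 1e-5)
})

test_that("categorical predictors are expanded against the middle reference level", {
  co <- generate_cohort(cohort_spec(1500, seed = 61))
  tab <- assemble_analysis_table(co)
  or <- fit_or_model(tab, "pp_cat")
  expect_equal(nrow(or), 2L)
  expect_setequal(or$level, c("first", "third"))
})

test_that("a unit-scale predictor on [0,1] reproduces the per-unit OR blow-up", {
  withr::local_seed(71)
  n <- 400
  ppi <- runif(n, 0.3, 0.6)
  y <- rbinom(n, 1, plogis(-3 + 8 * ppi))
  df <- data.frame(ci_label = y, ppi = ppi, ppi_c = ppi * 100)
  or_unit <- fit_or_model(df, "ppi")
  or_cent <- fit_or_model(df, "ppi_c")
  # OR per unit equals (OR per 0.01)^100; enormous per-unit CIs are expected
  expect_equal(log(or_unit$or), 100 * log(or_cent$or), tolerance = 1e-6)
  expect_gt(or_unit$ci_high / or_unit$ci_low, 50)
})

test_that("perfect separation is reported, not silently fitted", {
  df <- data.frame(x = c(rnorm(40, -5), rnorm(40, 5)),
                   ci_label = rep(0:1, each = 40))
  expect_error(fit_or_model(df, "x"), "separation")
})

test_that("the association table stacks unadjusted and adjusted models", {
  co <- generate_cohort(cohort_spec(800, seed = 81))
  tab <- assemble_analysis_table(co)
  res <- or_table(tab, c("pp", "lpca_score"))
  expect_setequal(unique(res$model), c("a", "b"))
  expect_equal(nrow(res), 4L)
  expect_true(all(res$ci_low <= res$or & res$or <= res$ci_high))
  expect_true(all(res$or > 0))
})

test_that("rank correlations behave as rank correlations", {
  withr::local_seed(91)
  df <- data.frame(a = rnorm(60), ci_label = rbinom(60, 1, 0.5))
  df$b <- -df$a
  df$c <- rnorm(60)
  sm <- spearman_matrix(df, c("a", "b", "c"))
  expect_equal(sm$all$rho["a", "a"], 1)
  expect_equal(sm$all$rho["a", "b"], -1)
  expect_equal(sm$all$rho, t(sm$all$rho))
  # invariance under strictly monotone transforms
  df$aexp <- exp(df$a)
  sm2 <- spearman_matrix(df, c("aexp", "c"))
  expect_equal(sm2$all$rho["aexp", "c"], sm$all$rho["a", "c"], tolerance = 1e-12)
  # constant columns are flagged, not zeroed
  df$k <- 5
  sm3 <- spearman_matrix(df, c("a", "k"))
  expect_equal(sm3$all$constant, "k")
  expect_true(is.na(sm3$all$rho["a", "k"]))
  # stratified by outcome
  sm4 <- spearman_matrix(df, c("a", "c"), by = "ci_label")
  expect_setequal(names(sm4), c("0", "1"))
})
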