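#' Compare a variable between outcome groups
#'
#' Continuous variables go to the independent-samples t test when both
#' groups pass a Shapiro-Wilk normality check (alpha 0.05), otherwise to
#' the Mann-Whitney U test; categorical variables go to the Chi-squared
#' test, falling back to Fisher's exact test (with a warning) when any
#' expected cell count drops below 5. Descriptives report both mean (SD)
#' and median (Q1-Q3).
#'
#' @param data data frame.
#' @param variable column to compare.
#' @param by binary grouping column (default `ci_label`).
#' @param shapiro_alpha normality-gate significance level.
#' @return list of class `group_comparison`: `variable`, `test`,
#'   `statistic`, `p_value`, `descriptives`.
#' @export
compare_groups <- function(data, variable, by = "ci_label",
                           shapiro_alpha = 0.05) {
  stopifnot(variable %in% names(data), by %in% names(data))
  x <- data[[variable]]
  g <- data[[by]]
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- factor(g[keep])
  if (nlevels(g) != 2L) stop("grouping variable must have exactly two levels")
  if (any(table(g) < 2L)) stop("need at least 2 observations per group")

  if (is.numeric(x)) {
    if (length(unique(x)) == 1L) stop("constant variable: no comparison possible")
    grp <- split(x, g)
    normal <- vapply(grp, function(v) {
      if (length(unique(v)) == 1L) return(FALSE)
      v <- if (length(v) > 5000) sample(v, 5000) else v
      shapiro.test(v)$p.value > shapiro_alpha
    }, TRUE)
    if (all(normal)) {
      tst <- t.test(x ~ g)
      test <- "t"
    } else {
      tst <- suppressWarnings(wilcox.test(x ~ g))
      test <- "mann-whitney"
    }
    desc <- do.call(rbind, lapply(names(grp), function(k) {
      v <- grp[[k]]
      q <- quantile(v, c(0.25, 0.5, 0.75))
      data.frame(group = k, n = length(v), mean = mean(v), sd = sd(v),
                 median = q[2], q1 = q[1], q3 = q[3], row.names = NULL)
    }))
  } else {
    x <- factor(x)
    if (nlevels(x) < 2L) stop("constant variable: no comparison possible")
    tb <- table(x, g)
    expected <- outer(rowSums(tb), colSums(tb)) / sum(tb)
    if (any(expected < 5)) {
      warning("expected cell count < 5: falling back to Fisher's exact test")
      tst <- fisher.test(tb)
      test <- "fisher"
    } else {
      tst <- chisq.test(tb, correct = FALSE)
      test <- "chi-squared"
    }
    desc <- as.data.frame(tb)
  }
  structure(list(variable = variable, test = test,
                 statistic = unname(tst$statistic %||% NA_real_),
                 p_value = tst$p.value, descriptives = desc),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s test, p = %.4g\n",
              x$variable, x$test, x$p_value))
  invisible(x)
}

#' Logistic odds ratios with Wald confidence intervals
#'
#' Maximum-likelihood logistic regression of the binary outcome on one
#' predictor of interest plus an adjustment set; odds ratios are
#' `exp(coefficient)` with Wald 95\% intervals on the log-odds scale.
#' Three-level categorical predictors are expanded against the declared
#' reference level (the second stage/tertile by default). Complete cases
#' only, per model.
#'
#' @param data analysis table (see [assemble_analysis_table()]).
#' @param predictor predictor column of interest.
#' @param adjust character vector of adjustment covariates.
#' @param outcome binary outcome column.
#' @param reference reference level for factor predictors.
#' @param conf_level confidence level.
#' @return data frame of class `or_result`: one row per non-reference
#'   predictor term with `or`, `ci_low`, `ci_high`, `p`, `n`, `adjustment`.
#' @export
fit_or_model <- function(data, predictor, adjust = character(0),
                         outcome = "ci_label", reference = "second",
                         conf_level = 0.95) {
  vars <- c(outcome, predictor, adjust)
  stopifnot(all(vars %in% names(data)))
  df <- data[complete.cases(data[vars]), vars, drop = FALSE]
  y <- df[[outcome]]
  if (length(unique(y)) != 2L)
    stop("outcome must be binary with both classes present")
  if (is.factor(df[[predictor]]) && reference %in% levels(df[[predictor]]))
    df[[predictor]] <- stats::relevel(df[[predictor]], ref = reference)
  fml <- as.formula(paste(outcome, "~", paste(c(predictor, adjust), collapse = " + ")))
  fit <- suppressWarnings(glm(fml, data = df, family = binomial()))
  sm <- summary(fit)$coefficients
  terms_all <- rownames(sm)
  pred_terms <- terms_all[startsWith(terms_all, predictor)]
  if (length(pred_terms) == 0L) stop("predictor dropped from the design matrix")
  se <- sm[pred_terms, "Std. Error"]
  b <- sm[pred_terms, "Estimate"]
  if (any(abs(b) > 5 & se > 50))
    stop("perfect (or quasi-perfect) separation on predictor '", predictor, "'")
  if (!fit$converged)
    stop("logistic fit did not converge after ", fit$iter, " IRLS iterations")
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(
    term = pred_terms,
    predictor = predictor,
    level = sub(paste0("^", predictor), "", pred_terms),
    or = exp(b),
    ci_low = exp(b - z * se),
    ci_high = exp(b + z * se),
    p = sm[pred_terms, "Pr(>|z|)"],
    n = nrow(df),
    adjustment = paste(adjust, collapse = "+"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("or_result", "data.frame")
  out
}

#' Association table over many predictors and adjustment sets
#'
#' Runs [fit_or_model()] for each predictor under each named adjustment set
#' (the classical pair being an unadjusted model and one adjusted for BMI,
#' myocardial-infarction history and stroke history) and stacks the rows.
#'
#' @param data analysis table.
#' @param predictors character vector of predictor columns.
#' @param models named list of adjustment sets (character vectors).
#' @param ... passed to [fit_or_model()].
#' @return a stacked `or_result` data frame with a `model` column.
#' @export
or_table <- function(data, predictors,
                     models = list(a = character(0), b = c("bmi", "mi", "stroke")),
                     ...) {
  rows <- list()
  for (mn in names(models))
    for (p in predictors) {
      r <- fit_or_model(data, p, adjust = models[[mn]], ...)
      r$model <- mn
      rows[[length(rows) + 1L]] <- r
    }
  out <- do.call(rbind, rows)
  class(out) <- c("or_result", "data.frame")
  out
}

#' Spearman correlation matrix, optionally stratified
#'
#' Rank correlations among the selected variables with pairwise-complete
#' observations and asymptotic p-values; constant columns are flagged (their
#' correlations are `NA`), never silently zeroed.
#'
#' @param data data frame.
#' @param variables columns to correlate.
#' @param by optional stratification column (e.g. the CI label).
#' @return for each stratum (or `"all"`): list with `rho`, `p`, `n`,
#'   `constant` (flagged column names); class `spearman_matrix`.
#' @export
spearman_matrix <- function(data, variables, by = NULL) {
  stopifnot(all(variables %in% names(data)))
  strata <- if (is.null(by)) list(all = data) else split(data, data[[by]])
  out <- lapply(strata, function(df) {
    m <- as.matrix(df[variables])
    const <- variables[apply(m, 2, function(v) length(unique(v[!is.na(v)])) <= 1L)]
    k <- length(variables)
    rho <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
    pv <- rho
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (variables[i] %in% const || variables[j] %in% const) next
      cc <- complete.cases(m[, i], m[, j])
      if (sum(cc) < 3L) next
      if (i == j) { rho[i, j] <- 1; pv[i, j] <- 0; next }
      ct <- suppressWarnings(cor.test(m[cc, i], m[cc, j], method = "spearman",
                                      exact = FALSE))
      rho[i, j] <- unname(ct$estimate)
      pv[i, j] <- ct$p.value
    }
    list(rho = rho, p = pv, n = nrow(df), constant = const)
  })
  structure(out, class = "spearman_matrix")
}
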