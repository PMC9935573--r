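#' Nested feature sets for risk prediction
#'
#' Set 1: mean SBP, DBP and pulse. Set 2 adds BMI and myocardial-infarction
#' and stroke history. Set 3 adds the three posterior-circulation stenosis
#' scores. The sets are strictly nested.
#'
#' @param id 1, 2 or 3.
#' @return character vector of analysis-table column names.
#' @export
feature_set_spec <- function(id) {
  sets <- list(
    `1` = c("sbp", "dbp", "pulse"),
    `2` = c("sbp", "dbp", "pulse", "bmi", "mi", "stroke"),
    `3` = c("sbp", "dbp", "pulse", "bmi", "mi", "stroke",
            "ba_score", "rpca_score", "lpca_score")
  )
  key <- as.character(id)
  if (!key %in% names(sets)) stop("feature set id must be 1, 2 or 3")
  sets[[key]]
}

#' Stratified train/holdout split
#'
#' Random split stratified by outcome (default 80/20), reproducible under
#' the seed. If a class ends up absent from either side the split is redrawn
#' with a warning, erroring after 10 attempts.
#'
#' @param data analysis table.
#' @param outcome binary outcome column.
#' @param ratio training fraction.
#' @param seed integer seed.
#' @return list with `train` and `holdout` data frames.
#' @export
split_cohort <- function(data, outcome = "ci_label", ratio = 0.8, seed = 1L) {
  stopifnot(outcome %in% names(data), ratio > 0, ratio < 1)
  y <- data[[outcome]]
  if (length(unique(y)) != 2L) stop("outcome must have both classes present")
  for (attempt in seq_len(10L)) {
    idx_train <- local_seed(seed + (attempt - 1L) * 7919L, {
      unlist(lapply(split(seq_len(nrow(data)), y), function(ii)
        sample(ii, round(length(ii) * ratio))), use.names = FALSE)
    })
    train <- data[sort(idx_train), , drop = FALSE]
    holdout <- data[-sort(idx_train), , drop = FALSE]
    ok <- length(unique(train[[outcome]])) == 2L &&
          length(unique(holdout[[outcome]])) == 2L &&
          nrow(holdout) > 0L
    if (ok) return(list(train = train, holdout = holdout))
    warning("degenerate split (a class missing on one side); redrawing")
  }
  stop("could not produce a stratified split with both classes on both sides")
}

#' Learner hyperparameters
#'
#' Defaults: unpenalized logistic regression; decision tree of maximum
#' depth 4; random forest with 500 trees; radial-kernel SVM at cost 1.
#'
#' @param dt_maxdepth,rf_ntree,svm_cost,svm_kernel tunables.
#' @return list of class `learner_config`.
#' @export
learner_config <- function(dt_maxdepth = 4L, rf_ntree = 500L,
                           svm_cost = 1, svm_kernel = "radial") {
  structure(list(dt_maxdepth = dt_maxdepth, rf_ntree = rf_ntree,
                 svm_cost = svm_cost, svm_kernel = svm_kernel),
            class = "learner_config")
}

# Standardization fit on training features only.
fit_scaler <- function(x) {
  mu <- vapply(x, mean, 0)
  sdev <- vapply(x, sd, 0)
  keep <- names(x)[sdev > 0]
  if (length(keep) < ncol(x))
    warning("constant feature(s) dropped: ",
            paste(setdiff(names(x), keep), collapse = ", "))
  list(mu = mu[keep], sd = sdev[keep], keep = keep)
}

apply_scaler <- function(x, sc) {
  x <- x[sc$keep]
  as.data.frame(Map(function(v, m, s) (v - m) / s, x, sc$mu, sc$sd))
}

fit_one_learner <- function(learner, x, y, cfg) {
  y_f <- factor(y, levels = c(0, 1))
  switch(learner,
    lr = {
      df <- cbind(x, .y = y)
      glm(.y ~ ., data = df, family = binomial())
    },
    dt = {
      df <- cbind(x, .y = y_f)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(maxdepth = cfg$dt_maxdepth))
    },
    rf = randomForest::randomForest(x = x, y = y_f, ntree = cfg$rf_ntree),
    svm = e1071::svm(x = as.matrix(x), y = y_f, kernel = cfg$svm_kernel,
                     cost = cfg$svm_cost, scale = FALSE),
    stop("unknown learner: ", learner)
  )
}

predict_one_learner <- function(learner, model, x) {
  switch(learner,
    lr = as.numeric(predict(model, newdata = x, type = "response")),
    dt = as.numeric(predict(model, newdata = x, type = "prob")[, "1"]),
    rf = as.numeric(predict(model, newdata = x, type = "prob")[, "1"]),
    svm = {
      pr <- predict(model, newdata = as.matrix(x), decision.values = TRUE)
      dec <- attr(pr, "decision.values")
      # the decision-value column "A/B" is positive when class A is favoured
      pos_first <- startsWith(colnames(dec)[1], "1")
      plogis(as.numeric(dec) * if (pos_first) 1 else -1)
    }
  )
}

#' AUC by the Mann-Whitney statistic
#'
#' Probability that a random case outscores a random control, ties counted
#' half; identical to the trapezoidal area under the empirical ROC curve.
#'
#' @param labels binary 0/1 vector.
#' @param scores numeric risk scores.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: a class is absent")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

make_folds <- function(y, k, seed) {
  local_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      ii <- sample(which(y == cls))
      fold[ii] <- rep_len(seq_len(k), length(ii))
    }
    fold
  })
}

#' Train and evaluate learners on a feature set
#'
#' Five-fold cross-validation inside the training cohort (standardization
#' refit on each fold's training part), then a final refit on the full
#' training cohort scored once on the holdout. Reports per-fold and mean CV
#' AUC plus the holdout AUC and holdout scores per learner.
#'
#' @param train,holdout data frames from [split_cohort()].
#' @param feature_set feature-set id (1/2/3) or character vector of columns.
#' @param learners subset of `c("lr", "dt", "rf", "svm")`.
#' @param outcome binary outcome column.
#' @param k number of CV folds.
#' @param seed integer seed (folds and stochastic learners).
#' @param config a [learner_config()].
#' @return object of class `prediction_report`: `summary` data frame
#'   (learner, cv_auc, holdout_auc), `fold_auc` matrix, `holdout_scores`
#'   data frame (labels plus one score column per learner), `features`.
#' @export
train_evaluate <- function(train, holdout, feature_set,
                           learners = c("lr", "dt", "rf", "svm"),
                           outcome = "ci_label", k = 5L, seed = 1L,
                           config = learner_config()) {
  features <- if (is.numeric(feature_set) || nchar(feature_set[1]) == 1)
    feature_set_spec(feature_set) else feature_set
  stopifnot(all(features %in% names(train)), all(features %in% names(holdout)))
  learners <- match.arg(learners, several.ok = TRUE)

  tr <- train[complete.cases(train[c(features, outcome)]), , drop = FALSE]
  ho <- holdout[complete.cases(holdout[c(features, outcome)]), , drop = FALSE]
  y_tr <- tr[[outcome]]
  y_ho <- ho[[outcome]]

  fold <- make_folds(y_tr, k, seed)
  # refold if a fold lost a class
  for (attempt in seq_len(10L)) {
    bad <- any(vapply(seq_len(k), function(f)
      length(unique(y_tr[fold == f])) < 2L, TRUE))
    if (!bad) break
    fold <- make_folds(y_tr, k, seed + attempt * 101L)
  }

  fold_auc <- matrix(NA_real_, nrow = k, ncol = length(learners),
                     dimnames = list(NULL, learners))
  for (f in seq_len(k)) {
    in_tr <- fold != f
    sc <- fit_scaler(tr[in_tr, features, drop = FALSE])
    x_tr <- apply_scaler(tr[in_tr, features, drop = FALSE], sc)
    x_va <- apply_scaler(tr[!in_tr, features, drop = FALSE], sc)
    for (ln in learners) {
      mod <- local_seed(seed * 1000L + f, fit_one_learner(ln, x_tr, y_tr[in_tr], config))
      s <- predict_one_learner(ln, mod, x_va)
      fold_auc[f, ln] <- auc_mw(y_tr[!in_tr], s)
    }
  }

  sc <- fit_scaler(tr[features])
  x_tr <- apply_scaler(tr[features], sc)
  x_ho <- apply_scaler(ho[features], sc)
  holdout_scores <- data.frame(label = y_ho)
  holdout_auc <- setNames(numeric(length(learners)), learners)
  for (ln in learners) {
    mod <- local_seed(seed * 1000L + 999L, fit_one_learner(ln, x_tr, y_tr, config))
    s <- predict_one_learner(ln, mod, x_ho)
    holdout_scores[[ln]] <- s
    holdout_auc[ln] <- auc_mw(y_ho, s)
  }

  structure(list(
    summary = data.frame(learner = learners,
                         cv_auc = colMeans(fold_auc)[learners],
                         holdout_auc = holdout_auc[learners],
                         row.names = NULL),
    fold_auc = fold_auc,
    holdout_scores = holdout_scores,
    features = features, k = k, seed = seed),
    class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("<prediction_report> features:", paste(x$features, collapse = ", "), "\n")
  print(transform(x$summary, cv_auc = round(cv_auc, 3),
                  holdout_auc = round(holdout_auc, 3)), row.names = FALSE)
  invisible(x)
}

#' DeLong test for two correlated ROC curves
#'
#' Nonparametric comparison of two AUCs computed from paired score vectors
#' on the same subjects, via the placement-value (structural component)
#' variance estimate; two-sided p from the normal reference. Comparing a
#' score vector with itself gives a zero AUC difference and p = 1.
#'
#' @param labels binary 0/1 outcome vector.
#' @param scores_a,scores_b paired risk-score vectors.
#' @return list of class `delong_test`: `auc_a`, `auc_b`, `diff`, `se`,
#'   `z`, `p_value`.
#' @export
delong_compare <- function(labels, scores_a, scores_b) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores_a),
            length(labels) == length(scores_b),
            all(labels %in% c(0L, 1L)))
  if (length(unique(labels)) < 2L)
    stop("DeLong test undefined: labels contain a single class")
  xs <- labels == 1L
  m <- sum(xs); n <- sum(!xs)
  placements <- function(s) {
    x <- s[xs]; y <- s[!xs]
    v10 <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / n, 0)
    v01 <- vapply(y, function(yj) (sum(x > yj) + 0.5 * sum(x == yj)) / m, 0)
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- pa$auc - pb$auc
  if (var_diff <= .Machine$double.eps) {
    p <- if (abs(diff) < 1e-12) 1 else 0
    z <- if (abs(diff) < 1e-12) 0 else sign(diff) * Inf
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, diff = diff,
                 se = sqrt(max(var_diff, 0)), z = z, p_value = p),
            class = "delong_test")
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf("<delong_test> AUC %.4f vs %.4f, diff %.4f, z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$diff, x$z, x$p_value))
  invisible(x)
}
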