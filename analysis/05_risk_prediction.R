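#!/usr/bin/env Rscript

# Predictive layer: 8:2 stratified split of the full simulated cohort, four
# learners (logistic regression, depth-4 decision tree, 500-tree random
# forest, radial SVM) over the three nested feature sets (BP means; + BMI,
# MI, stroke; + the three stenosis scores), 5-fold cross-validation inside
# the training cohort, one evaluation on the holdout, and pairwise DeLong
# comparisons of the holdout ROC curves across feature sets.
# Outputs: results/prediction_aucs.csv, results/delong_tests.csv, and an
# ROC figure under results/figures/ when ggplot2 is available.

suppressMessages(library(stenoscore))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

tab <- read.csv("results/cohort/analysis_table.csv", stringsAsFactors = FALSE)
sp <- split_cohort(tab, seed = seed)
cat(sprintf("split: %d train / %d holdout (prevalence %.2f / %.2f)\n",
            nrow(sp$train), nrow(sp$holdout),
            mean(sp$train$ci_label), mean(sp$holdout$ci_label)))

reports <- lapply(1:3, function(fs)
  train_evaluate(sp$train, sp$holdout, fs, seed = seed))
auc_tab <- do.call(rbind, lapply(1:3, function(fs)
  cbind(feature_set = fs, reports[[fs]]$summary)))
write.csv(auc_tab, "results/prediction_aucs.csv", row.names = FALSE)
print(auc_tab, row.names = FALSE)

## DeLong: does adding stenosis scores (set 3) change each learner's holdout ROC?
dl <- do.call(rbind, lapply(c("lr", "dt", "rf", "svm"), function(ln) {
  do.call(rbind, lapply(list(c(1, 2), c(2, 3), c(1, 3)), function(pair) {
    sa <- reports[[pair[1]]]$holdout_scores
    sb <- reports[[pair[2]]]$holdout_scores
    d <- delong_compare(sa$label, sb[[ln]], sa[[ln]])
    data.frame(learner = ln, sets = paste(pair[2], "vs", pair[1]),
               auc_larger = d$auc_a, auc_smaller = d$auc_b,
               diff = d$diff, p_value = d$p_value)
  }))
}))
write.csv(dl, "results/delong_tests.csv", row.names = FALSE)
cat("DeLong set-3 vs set-1 p-values:",
    paste(sprintf("%s %.3f", dl$learner[dl$sets == "3 vs 1"],
                  dl$p_value[dl$sets == "3 vs 1"]), collapse = ", "), "\n")

## ROC curves of the holdout, per learner, sets 1 vs 3
if (requireNamespace("ggplot2", quietly = TRUE)) {
  dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
  roc_pts <- do.call(rbind, lapply(c(1, 3), function(fs) {
    hs <- reports[[fs]]$holdout_scores
    do.call(rbind, lapply(c("lr", "dt", "rf", "svm"), function(ln) {
      r <- pROC::roc(hs$label, hs[[ln]], quiet = TRUE)
      data.frame(feature_set = factor(fs), learner = ln,
                 fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities))
    }))
  }))
  p <- ggplot2::ggplot(roc_pts, ggplot2::aes(fpr, tpr, colour = feature_set)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 3) +
    ggplot2::facet_wrap(~learner) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  colour = "feature set",
                  title = "Holdout ROC: BP means alone vs + history + stenosis scores") +
    ggplot2::theme_minimal()
  ggplot2::ggsave("results/figures/roc_curves.pdf", p, width = 7, height = 6)
  cat("wrote results/figures/roc_curves.pdf\n")
}
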