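#!/usr/bin/env Rscript
# Run the full experiment grid: baseline features, ratio/DE ablations with
# normalization variants, per-band DE, gamma-DE on the five electrode
# schemes, and the dual-frontal 20-feature configuration - each under all
# four classifiers and both evaluation schemes (pooled "whole" and
# per-subject "single") with stratified 10-fold cross-validation.

library(eegemo)

out <- run_suite(full_study(out_dir = "results/suite", seed = 1))
r <- out$results

cat("\nTop configurations by test accuracy:\n")
print(head(r[order(-r$test_acc),
             c("experiment", "feature_set", "scheme", "classifier",
               "n_features", "train_acc", "test_acc")], 10),
      row.names = FALSE)

band_rows <- r$experiment %in% c("3-1", "3-2", "3-3", "3-4", "3-5") &
  r$scheme == "whole" & r$classifier == "svm_linear"
cat("\nPer-band DE accuracy (SVM, whole):\n")
print(r[band_rows, c("experiment", "feature_set", "test_acc")],
      row.names = FALSE)

dt <- r[r$classifier == "dt_c45", ]
cat(sprintf("\ndecision-tree overfitting: mean train %.3f vs test %.3f\n",
            mean(dt$train_acc), mean(dt$test_acc)))
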