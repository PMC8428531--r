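#!/usr/bin/env Rscript
# Extract the feature sets used downstream and record their
# dimensionality: the 59-feature-per-channel baseline (1888 columns over
# 32 channels), the 10-per-channel energy-ratio + differential-entropy
# set, the per-band DE sets, and the 20-column dual-frontal set.

library(eegemo)

epochs <- load_epochs("scratch/data/epochs_raw")
cat("epochs loaded:", length(epochs), "\n")

sets <- list(baseline = NULL, ratio_de = NULL, de = NULL, ratio = NULL,
             de_gamma = NULL, dual20 = NULL)
dims <- data.frame(feature_set = names(sets), n_features = NA_integer_)
for (i in seq_along(sets)) {
  fm <- build_feature_matrix(epochs, names(sets)[i])
  dims$n_features[i] <- ncol(fm$x)
  if (names(sets)[i] == "de_gamma")
    write_feature_csv(fm, "scratch/features_de_gamma.csv")
}
dir.create("results", showWarnings = FALSE)
write.csv(dims, "results/feature_dimensions.csv", row.names = FALSE)
print(dims)
cat("59 features/channel x 32 channels =", dims$n_features[1], "\n")
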