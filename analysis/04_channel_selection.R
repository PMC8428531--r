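#!/usr/bin/env Rscript
# Rank the 32 electrodes by gradient-boosting contribution rate on the
# gamma-band differential entropy and build the five electrode-combination
# schemes (forehead pair, the two contribution-threshold sets, head loop,
# half loop).

library(eegemo)

seed <- 1
epochs <- load_epochs("scratch/data/epochs_raw")
fm <- build_feature_matrix(epochs, "de_gamma")
ct <- fit_gbdt_contributions(fm, seed = seed)
write_contribution_csv(ct, "results/contributions.csv")
print(head(ct, 10))
cat("rates sum:", sum(ct$contribution_rate), "\n")

schemes <- lapply(c("forehead", "thr_0.05", "thr_0.03", "head_loop",
                    "half_loop"),
                  function(r) build_scheme(ct, r))
for (s in schemes)
  cat(sprintf("%-9s: %s\n", s$name, paste(s$electrodes, collapse = ", ")))

ring <- c("Fp1", "Fp2", "T7", "T8", "TP9", "TP10", "O1", "O2", "Iz")
cat("lateral-ring electrodes hold",
    round(100 * sum(ct$contribution_rate[ct$electrode %in% ring])),
    "% of the total contribution\n")
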