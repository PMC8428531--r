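#!/usr/bin/env Rscript
# Focused look at the dual-frontal (Fp1/Fp2) mode: EEMD+ICA cleaning in
# place of the multi-channel ICA, the 20-dimensional ratio+DE feature set,
# and the accuracy cost of dropping from 32 channels to 2.

library(eegemo)

suite <- read_stamped_csv("results/suite/results.csv")
dual <- suite[suite$experiment == "dual", ]
all32 <- suite[suite$experiment == "2-1", ]

cmp <- merge(
  dual[, c("scheme", "classifier", "test_acc")],
  all32[, c("scheme", "classifier", "test_acc")],
  by = c("scheme", "classifier"), suffixes = c("_dual", "_32ch"))
cmp$drop <- cmp$test_acc_32ch - cmp$test_acc_dual
write.csv(cmp, "results/dual_vs_multichannel.csv", row.names = FALSE)
print(cmp, row.names = FALSE)
cat(sprintf("\nmean accuracy cost of 2 channels vs 32: %.3f\n",
            mean(cmp$drop)))
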