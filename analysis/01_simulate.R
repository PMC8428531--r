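#!/usr/bin/env Rscript
# Generate the desk-scale synthetic emotional-EEG dataset and persist it as
# a portable epoch container. The generator encodes the study conditions:
# 32-channel 10-20 montage, 4 positive + 4 negative video clips per
# subject, 9-point valence/arousal self-reports with the >4.5 / <4.5
# concordance rule, and a positive-class band-power effect (gamma strong,
# beta weak) on the lateral ring electrodes.

library(eegemo)

seed <- 1
out <- "scratch/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- dataset_config(n_subjects = 6, clips_per_class = 4, duration_s = 8,
                      fs = 250)
ds <- generate_dataset(cfg, seed = seed)

cat(sprintf("subjects: %d, recordings: %d, labeled epochs after the\n",
            cfg$n_subjects, length(ds$recordings)))
cat(sprintf("valence-concordance filter: %d\n", length(ds$epochs)))
labs <- table(vapply(ds$epochs, function(e) e$label, character(1)))
cat(sprintf("class balance: %d positive / %d negative\n",
            labs[["positive"]], labs[["negative"]]))

save_epochs(ds$epochs, file.path(out, "epochs_raw"))

ratings <- do.call(rbind, lapply(names(ds$ratings), function(id)
  cbind(clip = id, ds$ratings[[id]])))
write.csv(ratings, file.path(out, "ratings.csv"), row.names = FALSE)
cat("wrote", file.path(out, "epochs_raw"), "and ratings.csv\n")
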