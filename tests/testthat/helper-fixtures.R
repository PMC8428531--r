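# Shared fixture builders. Everything is generated in code at test time.

# n_per_class 1-s epochs per class from a profile, no preprocessing.
make_epochs <- function(profile, n_per_class, seed = 1, fs = 250,
                        clip_s = 25) {
  eps <- list()
  for (cls in c("positive", "negative")) {
    for (k in seq_len(ceiling(n_per_class / clip_s))) {
      rec <- synthesize_subject_recording(
        profile, cls, clip_s, fs,
        seed = seed * 10000 + match(cls, c("positive", "negative")) * 1000 + k,
        clip_id = paste0(cls, "_", k))
      eps <- c(eps, segment_epochs(rec, 1))
    }
  }
  eps
}

# Minimal labeled epoch wrapped around a plain matrix.
make_epoch <- function(data, fs = 250, label = "positive",
                       subject = "S01", clip = "c1") {
  structure(list(data = data, fs = fs, channel_names = rownames(data),
                 label = label, subject_id = subject, clip_id = clip,
                 epoch_index = 1L),
            class = "eeg_epoch")
}

# A 32-channel recording of plain white noise (no band structure).
white_recording <- function(n = 1000, fs = 250, sd = 5, seed = 1,
                            label = "positive") {
  set.seed(seed)
  eeg_recording(matrix(rnorm(32 * n, sd = sd), 32), fs, montage_32(),
                subject_id = "S01", clip_id = "c1", clip_label = label)
}

# The published per-electrode contribution rates used as a fixture for the
# threshold scheme rules (32 electrodes, rates summing to ~0.9997).
published_contributions <- function() {
  df <- data.frame(
    electrode = c("TP9", "Fp2", "T7", "Fp1", "TP10", "O1", "T8", "CP1",
                  "O2", "Iz", "C4", "C3", "P8", "F7", "CP6", "P4", "F3",
                  "FC5", "FT10", "FC2", "FC6", "CP5", "P7", "FC1", "FT9",
                  "Pz", "Cz", "F4", "F8", "P3", "Fz", "CP2"),
    contribution_rate = c(0.1383, 0.1215, 0.1013, 0.0758, 0.0682, 0.0589,
                          0.0542, 0.0387, 0.0365, 0.0330, 0.0320, 0.0309,
                          0.0197, 0.0194, 0.0194, 0.0179, 0.0175, 0.0173,
                          0.0143, 0.0124, 0.0103, 0.0089, 0.0088, 0.0082,
                          0.0082, 0.0070, 0.0065, 0.0049, 0.0038, 0.0037,
                          0.0019, 0.0003))
  class(df) <- c("contribution_table", "data.frame")
  df
}
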