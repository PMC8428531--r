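test_that("synthesis is deterministic and respects the montage", {
  p <- subject_profile()
  r1 <- synthesize_subject_recording(p, "positive", 2, 250, seed = 7)
  r2 <- synthesize_subject_recording(p, "positive", 2, 250, seed = 7)
  expect_identical(r1$data, r2$data)
  r3 <- synthesize_subject_recording(p, "positive", 2, 250, seed = 8)
  expect_false(identical(r1$data, r3$data))
  expect_equal(dim(r1$data), c(32L, 500L))
  expect_identical(r1$channel_names, montage_32())
  expect_false(anyNA(r1$data))
  expect_error(subject_profile(effect_channels = "NotAnElectrode"),
               "montage")
  expect_error(synthesize_subject_recording(p, "positive", 0, 250), "duration")
})

test_that("a gamma effect scales Fp1 band variance but not Cz", {
  p <- subject_profile(effect_channels = "Fp1", effect_bands = "gamma",
                       effect_size = 4)
  gb <- eeg_bands()$gamma
  pow <- function(cls, ch, i) {
    r <- synthesize_subject_recording(p, cls, 1, 250,
                                      seed = 5000 * (cls == "positive") + i)
    band_energy(r$data[ch, ], 250, gb)
  }
  n <- 100
  ratio_fp1 <- mean(sapply(1:n, pow, cls = "positive", ch = "Fp1")) /
    mean(sapply(1:n, pow, cls = "negative", ch = "Fp1"))
  ratio_cz <- mean(sapply(1:n, pow, cls = "positive", ch = "Cz")) /
    mean(sapply(1:n, pow, cls = "negative", ch = "Cz"))
  expect_gt(ratio_fp1, 3)
  expect_lt(ratio_fp1, 5)
  expect_gt(ratio_cz, 0.8)
  expect_lt(ratio_cz, 1.25)
})

test_that("with no effect the class band variances are indistinguishable", {
  p <- subject_profile(effect_size = 1, effect_bands = "gamma")
  gb <- eeg_bands()$gamma
  pow <- function(cls, i) {
    r <- synthesize_subject_recording(p, cls, 1, 250,
                                      seed = 7000 * (cls == "positive") + i)
    log(band_energy(r$data["Fp1", ], 250, gb))
  }
  pos <- sapply(1:60, pow, cls = "positive")
  neg <- sapply(1:60, pow, cls = "negative")
  expect_gt(t.test(pos, neg)$p.value, 0.01)
})

test_that("generated band variances track the requested powers within 10%", {
  p <- subject_profile(noise_power = 0)  # oscillations only
  bands <- eeg_bands()
  target <- p$baseline_band_power
  est <- sapply(names(bands), function(b) {
    mean(sapply(1:200, function(i) {
      r <- synthesize_subject_recording(p, "negative", 1, 250, seed = i)
      band_energy(r$data["Pz", ], 250, bands[[b]]) / 250
    }))
  })
  expect_true(all(abs(est - target) / target < 0.1))
})

test_that("ratings follow the valence threshold rule and its noise model", {
  p0 <- subject_profile(rating_noise_sd = 0)
  expect_gt(generate_ratings(p0, "positive", seed = 1)$valence, 4.5)
  expect_lt(generate_ratings(p0, "negative", seed = 1)$valence, 4.5)
  # tail probability against the closed-form normal CDF
  p3 <- subject_profile(rating_noise_sd = 3)
  vals <- sapply(1:1000, function(i)
    generate_ratings(p3, "positive", seed = i)$valence)
  expect_true(all(vals >= 1 & vals <= 9))
  expect_lt(abs(mean(vals <= 4.5) - pnorm(4.5, 7, 3)), 0.03)
})

test_that("label filter deletes epochs of non-concordant clips", {
  p <- subject_profile(rating_noise_sd = 0)
  eps <- list()
  ratings <- list()
  for (cls in c("positive", "negative")) for (k in 1:4) {
    id <- paste0(cls, "_", k)
    rec <- synthesize_subject_recording(p, cls, 6, 100, seed = k,
                                        clip_id = id)
    eps <- c(eps, segment_epochs(rec, 1))
    ratings[[id]] <- generate_ratings(p, cls, seed = k)
  }
  expect_length(apply_label_filter(eps, ratings), 48)
  # one positive clip rated low valence -> its epochs removed
  ratings[["positive_2"]]$valence <- 4.0
  expect_length(apply_label_filter(eps, ratings), 42)
  # exact 4.5 counts as mismatch
  ratings[["positive_3"]]$valence <- 4.5
  expect_length(apply_label_filter(eps, ratings), 36)
  expect_length(apply_label_filter(list(), ratings), 0)
  bad <- eps[1:2]
  bad[[1]]$clip_id <- "missing_clip"
  expect_error(apply_label_filter(bad, ratings), "no rating")
})

test_that("increasing rating noise never increases retained epochs", {
  retained <- sapply(c(0, 1.5, 3), function(sd_r) {
    mean(sapply(1:20, function(s) {
      p <- subject_profile(rating_noise_sd = sd_r)
      sum(sapply(c("positive", "negative"), function(cls)
        sapply(1:4, function(k) {
          r <- generate_ratings(p, cls, seed = s * 100 + k +
                                  1000 * (cls == "positive"))
          if (cls == "positive") r$valence > 4.5 else r$valence < 4.5
        })))
    }))
  })
  expect_true(all(diff(retained) <= 0))
})

test_that("generate_dataset yields the expected epoch counts", {
  cfg <- dataset_config(n_subjects = 1, clips_per_class = 4,
                        duration_s = 60, fs = 100,
                        profile = subject_profile(rating_noise_sd = 0))
  ds <- generate_dataset(cfg, seed = 3)
  expect_length(ds$recordings, 8)
  expect_length(ds$epochs, 480)
  labs <- table(vapply(ds$epochs, function(e) e$label, character(1)))
  expect_equal(unname(labs[["positive"]]), 240)
  expect_equal(unname(labs[["negative"]]), 240)
  # determinism of the full dataset
  ds2 <- generate_dataset(cfg, seed = 3)
  expect_identical(ds$epochs[[17]]$data, ds2$epochs[[17]]$data)
  expect_error(dataset_config(n_subjects = 0), "positive")
})
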