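test_that("band-pass plus notch suppresses 50 Hz and DC, keeps 20 Hz", {
  fs <- 250
  t <- seq_len(4 * fs) / fs
  x10 <- sin(2 * pi * 10 * t)
  x50 <- sin(2 * pi * 50 * t)
  rec <- eeg_recording(rbind(a = x10 + x50, b = x10 - x50), fs, c("a", "b"))
  f <- bandpass_notch_filter(rec)
  pg <- epoch_periodogram(f$data[1, ], fs)
  p10 <- sum(pg$power[pg$freq > 9 & pg$freq < 11])
  p50 <- sum(pg$power[pg$freq > 49 & pg$freq < 51])
  expect_lt(p50 / p10, 0.01)

  dc <- eeg_recording(matrix(100, 2, 1000), fs, c("a", "b"))
  expect_lt(mean(abs(bandpass_notch_filter(dc)$data)), 1)

  x20 <- sin(2 * pi * 20 * t)
  r20 <- eeg_recording(rbind(a = x20, b = -x20), fs, c("a", "b"))
  f20 <- bandpass_notch_filter(r20)
  mid <- 200:800  # avoid zero-phase edge transients
  expect_lt(abs(sd(f20$data[1, mid]) / sd(x20[mid]) - 1), 0.05)

  # notch band above Nyquist must be rejected
  expect_error(bandpass_notch_filter(
    eeg_recording(matrix(rnorm(200), 2), 100, c("a", "b"))), "notch|low")
})

test_that("average re-reference zeroes the channel mean and is idempotent", {
  rec <- eeg_recording(matrix(c(5, -5), 2, 100), 250, c("a", "b"))
  expect_equal(rereference_average(rec)$data, rec$data)
  same <- eeg_recording(matrix(3, 32, 50), 250, montage_32())
  expect_true(all(rereference_average(same)$data == 0))
  rnd <- white_recording(n = 1000, seed = 4)
  ref <- rereference_average(rnd)
  expect_lt(max(abs(colMeans(ref$data))), 1e-9)
  expect_equal(rereference_average(ref)$data, ref$data)
  one <- eeg_recording(matrix(1, 1, 10), 250, "a")
  expect_warning(out <- rereference_average(one), "skipped")
  expect_identical(out$data, one$data)
})

test_that("segmentation cuts exact windows and drops the remainder", {
  p <- subject_profile()
  r60 <- synthesize_subject_recording(p, "positive", 60, 100, seed = 1)
  expect_length(segment_epochs(r60, 1), 60)
  r87 <- synthesize_subject_recording(p, "negative", 8.7, 250, seed = 2)
  eps <- segment_epochs(r87, 1)
  expect_length(eps, 8)
  expect_true(all(vapply(eps, function(e) ncol(e$data) == 250, logical(1))))
  expect_identical(eps[[3]]$label, "negative")
  # concatenating the epochs reproduces the leading samples exactly
  expect_identical(do.call(cbind, lapply(eps, function(e) e$data)),
                   r87$data[, 1:2000])
  short <- synthesize_subject_recording(p, "positive", 0.5, 250, seed = 3)
  expect_length(segment_epochs(short, 1), 0)
})

test_that("amplitude rejection removes exactly the contaminated epochs", {
  base <- matrix(rnorm(32 * 250, sd = 3), 32)
  rownames(base) <- montage_32()
  eps <- lapply(1:100, function(i) make_epoch(base, clip = paste0("c", i)))
  spiked <- sample(100, 7)
  for (i in spiked) eps[[i]]$data[4, 100] <- 81
  kept <- reject_amplitude(eps, 80)
  expect_length(kept, 93)
  expect_true(all(vapply(kept, function(e) max(abs(e$data)) <= 80,
                         logical(1))))
  # order preserved
  ids <- vapply(kept, function(e) e$clip_id, character(1))
  expect_identical(ids, paste0("c", setdiff(1:100, sort(spiked))))
  expect_length(reject_amplitude(eps, 1000), 100)
  expect_error(reject_amplitude(eps, -1), "> 0")
})

test_that("the full pipeline emits epochs satisfying the amplitude bound", {
  p <- subject_profile(artifact_rate = 12)
  rec <- synthesize_subject_recording(p, "positive", 8, 250, seed = 9,
                                      clip_id = "c1")
  eps <- preprocess_recording(rec, preprocess_config(reject_uV = 80))
  expect_gt(length(eps), 0)
  expect_true(all(vapply(eps, function(e) max(abs(e$data)) <= 80,
                         logical(1))))
  expect_true(all(vapply(eps, function(e) ncol(e$data) == 250, logical(1))))
})
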