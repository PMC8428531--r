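# Independent O(N^2) template-counting oracle for sample entropy, written
# directly from the definition (Chebyshev distance, self-matches excluded).
sampen_oracle <- function(x, m, r) {
  n <- length(x)
  count <- function(mm) {
    np <- n - m  # common number of templates so A/B is the standard ratio
    c <- 0
    for (i in 1:(np - 1)) for (j in (i + 1):np) {
      if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) c <- c + 1
    }
    c
  }
  -log(count(m + 1) / count(m))
}

test_that("band energy honors Parseval and splits linearly over bands", {
  fs <- 250
  t <- seq_len(fs) / fs
  x <- sin(2 * pi * 10 * t)
  pg <- epoch_periodogram(x, fs)
  alpha <- eeg_bands()$alpha
  expect_lt(abs(band_energy(x, fs, alpha, pg) -
                  band_energy(x, fs, band_definition("full", 0, fs / 2))) /
              band_energy(x, fs, alpha, pg), 1e-6)
  for (b in eeg_bands()[c("delta", "theta", "beta", "gamma")])
    expect_lt(band_energy(x, fs, b, pg), 1e-9 * band_energy(x, fs, alpha))

  # exact Parseval identity for arbitrary signals
  set.seed(2)
  for (sig in list(rnorm(250), rnorm(333), sin(2 * pi * 7 * t) + rnorm(250))) {
    full <- band_definition("full", 0, fs / 2)
    expect_lt(abs(band_energy(sig, fs, full) - sum(sig^2)) / sum(sig^2),
              1e-9)
  }

  # white noise: mean band energy proportional to bandwidth
  set.seed(3)
  bands <- eeg_bands()
  est <- rowMeans(sapply(1:200, function(i) {
    w <- rnorm(250)
    sapply(bands, function(b) band_energy(w, fs, b))
  }))
  widths <- sapply(bands, function(b) b$f_hi - b$f_lo)
  norm <- (est / widths) / mean(est / widths)
  expect_true(all(abs(norm - 1) < 0.1))

  expect_error(band_energy(x, fs, band_definition("tiny", 10.1, 10.2)),
               "no DFT bins")
})

test_that("band ratios are normalized and reflect tone placement", {
  fs <- 250
  t <- seq_len(fs) / fs
  x <- sin(2 * pi * 10 * t)
  expect_gt(band_energy_ratio(x, fs, eeg_bands()$alpha), 0.99)
  five <- rowSums(sapply(c(2, 6, 10, 20, 38), function(f)
    sin(2 * pi * f * t)))
  r5 <- sapply(eeg_bands(), function(b) band_energy_ratio(five, fs, b))
  expect_true(all(abs(r5 - 0.2) < 0.01))
  set.seed(4)
  for (i in 1:20) {
    w <- rnorm(250)
    expect_lt(abs(sum(sapply(eeg_bands(), function(b)
      band_energy_ratio(w, fs, b))) - 1), 1e-9)
  }
  # sub-band energies add up to their parent band
  w <- rnorm(250)
  subs <- eeg_sub_bands()
  expect_lt(abs(band_energy(w, fs, subs$low_gamma) +
                  band_energy(w, fs, subs$high_gamma) -
                  band_energy(w, fs, eeg_bands()$gamma)) /
              band_energy(w, fs, eeg_bands()$gamma), 1e-6)
})

test_that("differential entropy matches the Gaussian closed form", {
  fs <- 250
  n <- 250
  gb <- eeg_bands()$gamma
  # scale equivariance: h(aX) = h(X) + log a
  set.seed(5)
  x <- rnorm(n)
  for (a in c(0.1, 3, 100))
    expect_equal(differential_entropy(a * x, fs, gb),
                 differential_entropy(x, fs, gb) + log(a), tolerance = 1e-9)

  # band-limited Gaussian with known variance: 1/2 log P should equal
  # 1/2 log(2 pi e sigma^2) - 1/2 log(2 pi e / N) on average
  sigma2 <- 4
  set.seed(6)
  de <- sapply(1:100, function(i) {
    g <- eegemo:::band_limited_noise(n, fs, 30, 45, sigma2)
    differential_entropy(g, fs, gb)
  })
  closed <- 0.5 * log(2 * pi * exp(1) * sigma2) -
    0.5 * log(2 * pi * exp(1) / n)
  expect_lt(abs(mean(de) - closed), 0.05)

  # multiplicative variance ratio 4 -> DE difference log(4)/2
  set.seed(7)
  de4 <- sapply(1:100, function(i) {
    g <- eegemo:::band_limited_noise(n, fs, 30, 45, 4 * sigma2)
    differential_entropy(g, fs, gb)
  })
  expect_lt(abs(mean(de4) - mean(de) - 0.5 * log(4)), 0.05)

  expect_error(differential_entropy(rep(0, n), fs, gb), "zero")
})

test_that("Hjorth parameters match the sinusoid closed form", {
  fs <- 250
  t <- seq_len(10 * fs) / fs
  for (f in c(2, 5, 10)) {
    x <- sin(2 * pi * f * t + 0.3)
    h <- hjorth_parameters(x)
    expect_equal(unname(h["mobility"]), 2 * sin(pi * f / fs),
                 tolerance = 0.01)
    expect_equal(unname(h["complexity"]), 1, tolerance = 0.01)
  }
  x <- sin(2 * pi * 4 * t)
  expect_equal(hjorth_parameters(2 * x), hjorth_parameters(x),
               tolerance = 1e-12)
  expect_error(hjorth_parameters(rep(1, 100)), "constant")
})

test_that("time-domain statistics follow their definitions", {
  con <- time_domain_stats(rep(5, 100))
  expect_equal(unname(con[c("mean", "sd", "zero_crossings", "amplitude")]),
               c(5, 0, 0, 0))
  fs <- 250
  k <- 4
  x <- sin(2 * pi * k * seq_len(fs) / fs + 0.1)  # k whole periods
  s <- time_domain_stats(x)
  expect_equal(unname(s["zero_crossings"]), 2 * k)
  expect_lt(abs(s["skewness"]), 0.05)
  set.seed(8)
  g <- rnorm(1e4)
  sg <- time_domain_stats(g)
  expect_lt(abs(sg["kurtosis"]), 0.2)
  expect_equal(unname(sg["squared_difference"]), mean(diff(g)^2))
  expect_equal(unname(sg["amplitude"]), max(g) - min(g))
})

test_that("spectral centroid and variability follow point-mass logic", {
  fs <- 250
  t <- seq_len(fs) / fs
  full <- analysis_band()
  d10 <- spectral_descriptors(sin(2 * pi * 10 * t), fs, full)
  expect_lt(abs(d10["centroid"] - 10), 0.5)
  expect_lt(d10["variability"], 0.5)
  two <- sin(2 * pi * 8 * t) + sin(2 * pi * 12 * t)
  d2 <- spectral_descriptors(two, fs, full)
  expect_lt(abs(d2["centroid"] - 10), 0.5)
  expect_lt(abs(d2["variability"] - 2), 0.3)
  set.seed(9)
  cents <- sapply(1:100, function(i)
    spectral_descriptors(rnorm(250), fs, full)["centroid"])
  expect_lt(abs(mean(cents) - 22.75), 1)
})

test_that("signal entropies behave as concentration measures", {
  expect_equal(permutation_entropy(1:200), 0)
  fs <- 250
  t <- seq_len(4 * fs) / fs
  expect_lt(spectral_entropy(sin(2 * pi * 10 * t), fs), 0.2)
  set.seed(10)
  w <- rnorm(1000)
  expect_gt(spectral_entropy(w, fs), 0.9)
  # SampEn against the brute-force counting oracle
  r <- 0.2 * sd(w)
  expect_lt(abs(sample_entropy(w, 2, r) - sampen_oracle(w, 2, r)), 0.15)
  # amplitude-scale invariance with r bound to the SD
  p <- entropy_params()
  e1 <- signal_entropies(w, fs, p)
  e2 <- signal_entropies(10 * w, fs, p)
  expect_equal(e1, e2, tolerance = 1e-9)
  expect_error(sample_entropy(w, 2, r = 0), "> 0")
})

test_that("fractal dimension spans the smooth-to-noise range", {
  set.seed(12)
  line <- seq(0, 1, length.out = 500) + 1e-9 * rnorm(500)
  expect_lt(abs(fractal_dimension(line) - 1), 0.05)
  w <- rnorm(2000)
  expect_lt(abs(fractal_dimension(w) - 2), 0.15)
  expect_equal(fractal_dimension(5 * w), fractal_dimension(w),
               tolerance = 1e-9)
})

test_that("instability index flags variance shifts against a null", {
  set.seed(13)
  null_vals <- sapply(1:200, function(i) instability_index(rnorm(1000)))
  expect_lt(median(null_vals), 0.5)
  q99 <- quantile(null_vals, 0.99)
  step <- c(rnorm(500, sd = 1), rnorm(500, sd = sqrt(10)))
  expect_gt(instability_index(step), q99)
  expect_equal(instability_index(3 * step), instability_index(step),
               tolerance = 1e-9)
})

test_that("the baseline extractor yields 59 stable named features", {
  rec <- white_recording(n = 250, seed = 14)
  ep <- segment_epochs(rec, 1)[[1]]
  f <- extract_baseline_features(ep, "Fp1")
  expect_length(f, 59)
  expect_false(anyDuplicated(names(f)) > 0)
  expect_true(all(is.finite(f)))
  f2 <- extract_baseline_features(ep, "Fp1")
  expect_identical(names(f), names(f2))
  expect_error(extract_baseline_features(ep, "XX"), "unknown channel")
})

test_that("feature matrices have the documented dimensionality", {
  rec <- white_recording(n = 500, seed = 15)
  eps <- segment_epochs(rec, 1)
  expect_equal(ncol(build_feature_matrix(eps, "baseline")$x), 1888)
  expect_equal(ncol(build_feature_matrix(eps, "ratio_de")$x), 320)
  expect_equal(ncol(build_feature_matrix(eps, "de")$x), 160)
  expect_equal(ncol(build_feature_matrix(eps, "ratio")$x), 160)
  expect_equal(ncol(build_feature_matrix(eps, "de_gamma")$x), 32)
  expect_equal(ncol(build_feature_matrix(eps, "dual20")$x), 20)
  fm10 <- build_feature_matrix(eps, "ratio_de", channels = c("Fp1", "Fp2"))
  expect_equal(ncol(fm10$x), 20)
  bg <- build_feature_matrix(eps, "de_bands", channels = "Cz",
                             bands = c("beta", "gamma"))
  expect_equal(colnames(bg$x), c("Cz.de_beta", "Cz.de_gamma"))
  expect_error(build_feature_matrix(eps, "nope"), "unknown feature set")
  expect_error(build_feature_matrix(eps, "de", channels = "QQ"), "not in")
})

test_that("normalization modes satisfy their contracts", {
  rec <- white_recording(n = 500, seed = 16)
  fm <- build_feature_matrix(segment_epochs(rec, 1), "de_gamma")
  expect_identical(normalize_features(fm, "none")$x, fm$x)
  z <- normalize_features(fm, "zscore")$x
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-9))
  m <- normalize_features(fm, "minmax01")
  expect_true(all(m$x >= 0 & m$x <= 1))
  expect_equal(normalize_features(m, "minmax01")$x, m$x, tolerance = 1e-12)
  # zero-variance column warning
  fm$x[, 1] <- 7
  expect_warning(normalize_features(fm, "zscore"), "zero-variance")
})

test_that("feature matrices round-trip through CSV", {
  rec <- white_recording(n = 500, seed = 17)
  fm <- build_feature_matrix(segment_epochs(rec, 1), "de_gamma")
  path <- tempfile(fileext = ".csv")
  write_feature_csv(fm, path)
  back <- read_feature_csv(path, feature_set = "de_gamma")
  expect_equal(back$x, fm$x, tolerance = 1e-12)
  expect_identical(as.character(back$label), as.character(fm$label))
  expect_identical(colnames(back$x), colnames(fm$x))
})
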