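#' One-sided periodogram of a single-channel epoch
#'
#' Plain DFT periodogram (no windowing) folded onto non-negative
#' frequencies, scaled so that the sum of `power` over all bins equals the
#' time-domain sum of squares exactly (Parseval identity).
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @return List with `freq` (Hz) and `power` per bin.
#' @export
epoch_periodogram <- function(x, fs) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  p <- Mod(stats::fft(x))^2 / n
  half <- floor(n / 2)
  freq <- (0:half) * fs / n
  power <- p[1:(half + 1)]
  if (n %% 2 == 0) {
    # interior bins carry both +f and -f power; DC and Nyquist are unique
    if (half >= 2) power[2:half] <- power[2:half] + p[n:(n - half + 2)]
  } else {
    power[2:(half + 1)] <- power[2:(half + 1)] + p[n:(n - half + 1)]
  }
  list(freq = freq, power = power)
}

# Bin selector for a band: f_lo <= f < f_hi, with the Nyquist bin included
# when f_hi reaches it (so a full-range band covers every bin).
band_bins <- function(freq, fs, band) {
  sel <- freq >= band$f_lo & freq < band$f_hi
  if (band$f_hi >= fs / 2) sel <- sel | freq == fs / 2
  which(sel)
}

#' Band energy of an epoch
#'
#' Sum of periodogram power over the DFT bins falling in the band. A band
#' covering the whole frequency axis returns the time-domain sum of squares
#' (Parseval).
#'
#' @param x Numeric vector (single-channel epoch).
#' @param fs Sampling rate (Hz).
#' @param band A [band_definition()].
#' @param pg Optional precomputed [epoch_periodogram()].
#' @return Band energy (uV^2 scale).
#' @export
band_energy <- function(x, fs, band, pg = NULL) {
  if (is.null(pg)) pg <- epoch_periodogram(x, fs)
  idx <- band_bins(pg$freq, fs, band)
  if (length(idx) == 0)
    stop("band '", band$name, "' contains no DFT bins at this fs/N")
  sum(pg$power[idx])
}

#' Band energy ratio
#'
#' Fraction of the analysis-band energy falling in `band`. The five main
#' bands partition the analysis band, so their ratios sum to 1.
#'
#' @inheritParams band_energy
#' @param total_band Denominator band (default [analysis_band()]).
#' @return Ratio in [0, 1].
#' @export
band_energy_ratio <- function(x, fs, band, total_band = analysis_band(),
                              pg = NULL) {
  if (is.null(pg)) pg <- epoch_periodogram(x, fs)
  tot <- band_energy(x, fs, total_band, pg)
  if (tot <= 0) stop("total band energy is zero; ratio undefined")
  band_energy(x, fs, band, pg) / tot
}

#' Band-wise differential entropy
#'
#' For a band-limited Gaussian signal the differential entropy is
#' `log(2*pi*e*sigma^2)/2`; with the band variance estimated through the
#' band energy P (Parseval) this equals `log(P)/2` plus a constant that
#' depends only on the epoch length, so `log(P)/2` is used as the feature.
#' Natural logarithm throughout.
#'
#' @inheritParams band_energy
#' @return Differential entropy `log(P)/2` (log-energy units).
#' @export
differential_entropy <- function(x, fs, band, pg = NULL) {
  p <- band_energy(x, fs, band, pg)
  if (p <= 0) stop("band energy is zero; differential entropy undefined")
  0.5 * log(p)
}

#' Hjorth mobility and complexity
#'
#' Mobility is `sqrt(var(diff(x))/var(x))`; complexity is the mobility of
#' the first difference divided by the mobility of the signal. Both are
#' amplitude-scale invariant.
#'
#' @param x Numeric vector with at least 3 samples and nonzero variance.
#' @return Named vector `c(mobility, complexity)`.
#' @export
hjorth_parameters <- function(x) {
  if (length(x) < 3) stop("need at least 3 samples")
  v0 <- stats::var(x)
  if (v0 == 0) stop("constant signal: Hjorth parameters undefined")
  d1 <- diff(x)
  d2 <- diff(d1)
  v1 <- stats::var(d1)
  v2 <- stats::var(d2)
  mob <- sqrt(v1 / v0)
  comp <- sqrt(v2 / v1) / mob
  c(mobility = mob, complexity = comp)
}

#' Time-domain descriptive statistics (14 values)
#'
#' Mean, mean squared first difference, SD, max, min, median, skewness,
#' excess kurtosis, zero-crossing count, peak-to-peak amplitude, mean
#' absolute first difference (raw and SD-normalized), mean absolute second
#' difference (raw and SD-normalized).
#'
#' @param x Numeric vector with at least 3 samples.
#' @return Named numeric vector of length 14.
#' @export
time_domain_stats <- function(x) {
  if (length(x) < 3) stop("need at least 3 samples")
  s <- stats::sd(x)
  d1 <- diff(x)
  d2 <- diff(x, differences = 2)
  nz <- x[x != 0]
  zc <- if (length(nz) < 2) 0L else sum(diff(sign(nz)) != 0)
  c(mean = mean(x),
    squared_difference = mean(d1^2),
    sd = s,
    max = max(x),
    min = min(x),
    median = stats::median(x),
    skewness = if (s == 0) 0 else e1071::skewness(x),
    kurtosis = if (s == 0) 0 else e1071::kurtosis(x),
    zero_crossings = zc,
    amplitude = max(x) - min(x),
    first_diff_mean = mean(abs(d1)),
    first_diff_norm = if (s == 0) 0 else mean(abs(d1)) / s,
    second_diff_mean = mean(abs(d2)),
    second_diff_norm = if (s == 0) 0 else mean(abs(d2)) / s)
}

#' Spectral centroid and frequency variability of a band
#'
#' Centroid is the power-weighted mean frequency over the band bins;
#' variability is the power-weighted standard deviation around it.
#'
#' @inheritParams band_energy
#' @return Named vector `c(centroid, variability)` in Hz.
#' @export
spectral_descriptors <- function(x, fs, band, pg = NULL) {
  if (is.null(pg)) pg <- epoch_periodogram(x, fs)
  idx <- band_bins(pg$freq, fs, band)
  if (length(idx) == 0) stop("band '", band$name, "' contains no DFT bins")
  p <- pg$power[idx]
  tot <- sum(p)
  if (tot <= 0) stop("zero band energy; spectral descriptors undefined")
  f <- pg$freq[idx]
  cent <- sum(f * p) / tot
  vari <- sqrt(sum((f - cent)^2 * p) / tot)
  c(centroid = cent, variability = vari)
}

#' Entropy parameters for the embedding entropies
#'
#' @param m Embedding dimension (SampEn/ApEn/FuzzyEn).
#' @param r_factor Tolerance as a fraction of the signal SD; binding r to
#'   the SD makes the embedding entropies amplitude-scale invariant.
#' @param fuzzy_n Exponent of the fuzzy exponential membership.
#' @param perm_order,perm_delay Ordinal pattern order and delay.
#' @return List of parameters.
#' @export
entropy_params <- function(m = 2, r_factor = 0.2, fuzzy_n = 2,
                           perm_order = 3, perm_delay = 1) {
  if (r_factor <= 0) stop("r_factor must be > 0")
  list(m = m, r_factor = r_factor, fuzzy_n = fuzzy_n,
       perm_order = perm_order, perm_delay = perm_delay)
}

#' Sample entropy
#'
#' SampEn(m, r) with Chebyshev distance and self-matches excluded. When no
#' template pair matches at either length the value is capped at
#' `log((N-m)*(N-m-1))` with a warning (the conventional upper bound for
#' the number of countable pairs).
#'
#' @param x Numeric vector (N >= 100 recommended).
#' @param m Embedding dimension.
#' @param r Tolerance (absolute units).
#' @return Sample entropy (dimensionless).
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  if (r <= 0) stop("r must be > 0")
  cnt <- .sampen_counts_cpp(as.numeric(x), as.integer(m), r)
  a <- cnt[1]; b <- cnt[2]
  n <- length(x)
  cap <- log((n - m) * (n - m - 1))
  if (b == 0 || a == 0) {
    warning("no template matches; sample entropy capped")
    return(cap)
  }
  -log(a / b)
}

#' Approximate entropy
#' @inheritParams sample_entropy
#' @export
approximate_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  if (r <= 0) stop("r must be > 0")
  .apen_cpp(as.numeric(x), as.integer(m), r)
}

#' Fuzzy entropy
#'
#' FuzzyEn(m, r, n) with mean-removed templates and exponential membership
#' `exp(-(d/r)^n)`.
#'
#' @inheritParams sample_entropy
#' @param n Membership exponent.
#' @export
fuzzy_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x), n = 2) {
  if (r <= 0) stop("r must be > 0")
  .fuzzyen_cpp(as.numeric(x), as.integer(m), r, n)
}

#' Permutation entropy (normalized)
#'
#' Shannon entropy of the ordinal-pattern distribution of order `order` and
#' delay `delay`, normalized by `log(order!)` to [0, 1]. A strictly
#' monotone signal exhibits a single pattern and returns 0.
#'
#' @param x Numeric vector.
#' @param order Pattern order (default 3).
#' @param delay Pattern delay (default 1).
#' @export
permutation_entropy <- function(x, order = 3, delay = 1) {
  n <- length(x)
  k <- n - (order - 1) * delay
  if (k < 2) stop("signal too short for the requested order/delay")
  emb <- vapply(0:(order - 1),
                function(j) x[(1 + j * delay):(k + j * delay)],
                numeric(k))
  # encode each row's ordinal pattern as an integer: count of pairwise
  # "less than" outcomes uniquely identifies the permutation
  code <- integer(k)
  b <- 1L
  for (i in 1:(order - 1)) for (j in (i + 1):order) {
    code <- code + b * (emb[, i] > emb[, j])
    b <- b * 2L
  }
  p <- tabulate(code + 1L, b) / k
  p <- p[p > 0]
  h <- -sum(p * log(p))
  h / log(factorial(order))
}

#' Spectral entropy (normalized)
#'
#' Shannon entropy of the normalized periodogram over the analysis band,
#' divided by the log of the number of band bins. Near 0 for a pure tone,
#' near 1 for white noise.
#'
#' @inheritParams band_energy
#' @export
spectral_entropy <- function(x, fs, band = analysis_band(), pg = NULL) {
  if (is.null(pg)) pg <- epoch_periodogram(x, fs)
  idx <- band_bins(pg$freq, fs, band)
  p <- pg$power[idx]
  tot <- sum(p)
  if (tot <= 0) stop("zero band energy; spectral entropy undefined")
  p <- p / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(idx))
}

#' The five signal entropies
#'
#' @param x Numeric vector (N >= 100 for the embedding entropies).
#' @param fs Sampling rate (Hz).
#' @param params An [entropy_params()] list.
#' @param pg Optional precomputed periodogram.
#' @return Named vector: sampen, apen, fuzzyen, perment, specent.
#' @export
signal_entropies <- function(x, fs, params = entropy_params(), pg = NULL) {
  r <- params$r_factor * stats::sd(x)
  c(sampen = suppressWarnings(sample_entropy(x, params$m, r)),
    apen = approximate_entropy(x, params$m, r),
    fuzzyen = fuzzy_entropy(x, params$m, r, params$fuzzy_n),
    perment = permutation_entropy(x, params$perm_order, params$perm_delay),
    specent = spectral_entropy(x, fs, pg = pg))
}

#' Higuchi fractal dimension
#'
#' @param x Numeric vector (N >= 100).
#' @param k_max Maximum curve-length scale (default 10).
#' @return Fractal dimension (~1 for a smooth curve, ~2 for white noise).
#' @export
fractal_dimension <- function(x, k_max = 10) {
  if (length(x) < 100) stop("need at least 100 samples")
  if (stats::sd(x) == 0) stop("constant signal: fractal dimension undefined")
  .higuchi_cpp(as.numeric(x), as.integer(k_max))
}

#' Instability index
#'
#' Nonstationarity score: the signal is split into `n_segments` equal
#' parts and the variance of the per-segment variances is divided by the
#' squared overall variance. Near 0 for stationary signals,
#' amplitude-scale invariant.
#'
#' @param x Numeric vector.
#' @param n_segments Number of segments (default 4).
#' @export
instability_index <- function(x, n_segments = 4) {
  n <- length(x)
  if (n_segments < 2 || n_segments > n)
    stop("n_segments must be in [2, length(x)]")
  v0 <- stats::var(x)
  if (v0 == 0) stop("constant signal: instability index undefined")
  len <- n %/% n_segments
  vs <- vapply(seq_len(n_segments), function(i)
    stats::var(x[((i - 1) * len + 1):(i * len)]), numeric(1))
  stats::var(vs) / v0^2
}

# canonical per-channel feature name order (59 features)
baseline_feature_names <- function() {
  bands <- c("delta", "theta", "alpha", "beta", "gamma")
  c(names(time_domain_stats(c(0, 1, 0))),
    "hjorth_mobility", "hjorth_complexity",
    "fractal_dimension", "instability_index",
    "energy_total",
    "energy_low_delta", "energy_high_delta", "energy_delta",
    "energy_theta",
    "energy_low_alpha", "energy_high_alpha", "energy_alpha",
    "energy_low_beta", "energy_high_beta", "energy_beta",
    "energy_low_gamma", "energy_high_gamma", "energy_gamma",
    paste0("ratio_", bands),
    paste0("de_", bands),
    "centroid_total", paste0("centroid_", bands),
    "fvar_total", paste0("fvar_", bands),
    "sampen", "apen", "fuzzyen", "perment", "specent")
}

#' Extract the 59-feature baseline descriptor set for one channel
#'
#' Computes, in a fixed order: 14 time-domain statistics, the two Hjorth
#' parameters, Higuchi fractal dimension, instability index, total energy,
#' 13 band/sub-band energies, the 5 main-band energy ratios, the 5
#' band-wise differential entropies, 6 spectral centroids and 6 frequency
#' variabilities (total band + 5 bands), and 5 signal entropies.
#'
#' @param epoch An `eeg_epoch` (or a list with `data`, `fs`,
#'   `channel_names`).
#' @param channel Channel name.
#' @param params [entropy_params()] for the entropy block.
#' @return Named numeric vector of length 59; an error is raised if any
#'   feature is non-finite.
#' @export
extract_baseline_features <- function(epoch, channel,
                                      params = entropy_params()) {
  ci <- match(channel, epoch$channel_names)
  if (is.na(ci)) stop("unknown channel '", channel, "'")
  x <- epoch$data[ci, ]
  fs <- epoch$fs
  pg <- epoch_periodogram(x, fs)
  bands <- eeg_bands()
  subs <- eeg_sub_bands()
  tot <- analysis_band()
  td <- time_domain_stats(x)
  hj <- hjorth_parameters(x)
  energies <- c(
    energy_total = band_energy(x, fs, tot, pg),
    energy_low_delta = band_energy(x, fs, subs$low_delta, pg),
    energy_high_delta = band_energy(x, fs, subs$high_delta, pg),
    energy_delta = band_energy(x, fs, bands$delta, pg),
    energy_theta = band_energy(x, fs, bands$theta, pg),
    energy_low_alpha = band_energy(x, fs, subs$low_alpha, pg),
    energy_high_alpha = band_energy(x, fs, subs$high_alpha, pg),
    energy_alpha = band_energy(x, fs, bands$alpha, pg),
    energy_low_beta = band_energy(x, fs, subs$low_beta, pg),
    energy_high_beta = band_energy(x, fs, subs$high_beta, pg),
    energy_beta = band_energy(x, fs, bands$beta, pg),
    energy_low_gamma = band_energy(x, fs, subs$low_gamma, pg),
    energy_high_gamma = band_energy(x, fs, subs$high_gamma, pg),
    energy_gamma = band_energy(x, fs, bands$gamma, pg))
  ratios <- vapply(bands, function(b)
    band_energy_ratio(x, fs, b, tot, pg), numeric(1))
  names(ratios) <- paste0("ratio_", names(bands))
  des <- vapply(bands, function(b)
    differential_entropy(x, fs, b, pg), numeric(1))
  names(des) <- paste0("de_", names(bands))
  cent_tot <- spectral_descriptors(x, fs, tot, pg)
  cents <- vapply(bands, function(b)
    spectral_descriptors(x, fs, b, pg)[["centroid"]], numeric(1))
  fvars <- vapply(bands, function(b)
    spectral_descriptors(x, fs, b, pg)[["variability"]], numeric(1))
  names(cents) <- paste0("centroid_", names(bands))
  names(fvars) <- paste0("fvar_", names(bands))
  ents <- signal_entropies(x, fs, params, pg)
  out <- c(td, hj, fractal_dimension = fractal_dimension(x),
           instability_index = instability_index(x),
           energies, ratios, des,
           centroid_total = cent_tot[["centroid"]], cents,
           fvar_total = cent_tot[["variability"]], fvars,
           ents)
  names(out) <- baseline_feature_names()
  bad <- !is.finite(out)
  if (any(bad))
    stop("non-finite feature(s): ", paste(names(out)[bad], collapse = ", "))
  out
}

# per-channel feature extractor for the focused feature sets
focused_features <- function(x, fs, set) {
  pg <- epoch_periodogram(x, fs)
  bands <- eeg_bands()
  tot <- analysis_band()
  ratio <- function() {
    r <- vapply(bands, function(b)
      band_energy_ratio(x, fs, b, tot, pg), numeric(1))
    stats::setNames(r, paste0("ratio_", names(bands)))
  }
  de <- function() {
    d <- vapply(bands, function(b)
      differential_entropy(x, fs, b, pg), numeric(1))
    stats::setNames(d, paste0("de_", names(bands)))
  }
  if (set == "ratio_de") return(c(ratio(), de()))
  if (set == "ratio") return(ratio())
  if (set == "de") return(de())
  if (grepl("^de_", set)) {
    b <- sub("^de_", "", set)
    if (!b %in% names(bands)) stop("unknown band in feature set '", set, "'")
    return(stats::setNames(differential_entropy(x, fs, bands[[b]], pg), set))
  }
  stop("unknown feature set '", set, "'")
}

#' Build an epochs-x-features matrix
#'
#' @param epochs List of labeled epochs.
#' @param feature_set One of `"baseline"` (59 per channel), `"ratio_de"`
#'   (10), `"de"` (5), `"ratio"` (5), `"de_<band>"` (1, e.g. `"de_gamma"`),
#'   `"de_bands"` with a `bands` argument, or `"dual20"` (ratio_de on Fp1
#'   and Fp2, 20 columns total).
#' @param channels Channels to include (default: full montage; `"dual20"`
#'   forces `c("Fp1", "Fp2")`).
#' @param bands For multi-band DE subsets: band names, e.g.
#'   `c("beta", "gamma")`.
#' @param params [entropy_params()] for the baseline set.
#' @return A `feature_matrix` object: list with `x` (numeric matrix,
#'   channel-qualified column names), `label` (factor), `subject`, `clip`.
#' @export
build_feature_matrix <- function(epochs, feature_set = "de",
                                 channels = montage_32(), bands = NULL,
                                 params = entropy_params()) {
  stopifnot(length(epochs) > 0)
  if (feature_set == "dual20") channels <- c("Fp1", "Fp2")
  unknown <- setdiff(channels, epochs[[1]]$channel_names)
  if (length(unknown) > 0)
    stop("channel(s) not in the data: ", paste(unknown, collapse = ", "))
  set <- if (feature_set == "dual20") "ratio_de" else feature_set
  per_channel <- function(ep, ch) {
    ci <- match(ch, ep$channel_names)
    if (set == "baseline") extract_baseline_features(ep, ch, params)
    else if (set == "de_bands") {
      if (is.null(bands)) stop("feature set 'de_bands' requires bands")
      unlist(lapply(bands, function(b)
        focused_features(ep$data[ci, ], ep$fs, paste0("de_", b))))
    } else focused_features(ep$data[ci, ], ep$fs, set)
  }
  rows <- lapply(epochs, function(ep) {
    v <- unlist(lapply(channels, function(ch) {
      f <- per_channel(ep, ch)
      stats::setNames(f, paste0(ch, ".", names(f)))
    }))
    v
  })
  x <- do.call(rbind, rows)
  structure(list(
    x = x,
    label = factor(vapply(epochs, function(e) e$label, character(1)),
                   levels = c("negative", "positive")),
    subject = vapply(epochs, function(e) e$subject_id, character(1)),
    clip = vapply(epochs, function(e) e$clip_id, character(1)),
    feature_set = feature_set, channels = channels),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d epochs x %d features (%s; %d channels)\n",
              nrow(x$x), ncol(x$x), x$feature_set, length(x$channels)))
  print(table(x$label))
  invisible(x)
}

#' Fit a column normalizer on a training set
#'
#' @param x Numeric matrix (training rows only, to keep the transform
#'   leak-free).
#' @param mode `"none"`, `"zscore"`, or `"minmax01"`.
#' @return A `feature_normalizer` to pass to [normalize_apply()].
#' @export
normalize_fit <- function(x, mode = c("none", "zscore", "minmax01")) {
  mode <- match.arg(mode)
  out <- list(mode = mode)
  if (mode == "zscore") {
    out$center <- colMeans(x)
    out$scale <- apply(x, 2, stats::sd)
    if (any(out$scale == 0)) {
      warning("zero-variance column(s) left at 0 under zscore")
      out$scale[out$scale == 0] <- 1
    }
  } else if (mode == "minmax01") {
    out$min <- apply(x, 2, min)
    rng <- apply(x, 2, max) - out$min
    rng[rng == 0] <- 1
    out$range <- rng
  }
  structure(out, class = "feature_normalizer")
}

#' Apply a fitted normalizer to a matrix
#' @param x Numeric matrix.
#' @param fit A [normalize_fit()] result.
#' @export
normalize_apply <- function(x, fit) {
  switch(fit$mode,
         none = x,
         zscore = sweep(sweep(x, 2, fit$center), 2, fit$scale, "/"),
         minmax01 = sweep(sweep(x, 2, fit$min), 2, fit$range, "/"))
}

#' Normalize a feature matrix (fit and apply on the same set)
#'
#' For cross-validation use [normalize_fit()] on the training rows and
#' [normalize_apply()] on both sets; this convenience wrapper fits on the
#' whole matrix.
#'
#' @param fm A `feature_matrix`.
#' @param mode `"none"`, `"zscore"`, or `"minmax01"`.
#' @export
normalize_features <- function(fm, mode = c("none", "zscore", "minmax01")) {
  mode <- match.arg(mode)
  fm$x <- normalize_apply(fm$x, normalize_fit(fm$x, mode))
  fm
}

#' Write a feature matrix to CSV
#'
#' Header: label, subject, clip, then the channel-qualified feature names.
#' @param fm A `feature_matrix`.
#' @param path Output file.
#' @export
write_feature_csv <- function(fm, path) {
  df <- data.frame(label = as.character(fm$label), subject = fm$subject,
                   clip = fm$clip, fm$x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_csv()]
#' @param path CSV file.
#' @param feature_set Optional feature-set tag to restore.
#' @export
read_feature_csv <- function(path, feature_set = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE)
  x <- as.matrix(df[, -(1:3), drop = FALSE])
  channels <- unique(sub("\\..*$", "", colnames(x)))
  structure(list(x = x,
                 label = factor(df$label,
                                levels = c("negative", "positive")),
                 subject = df$subject, clip = df$clip,
                 feature_set = feature_set, channels = channels),
            class = "feature_matrix")
}
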