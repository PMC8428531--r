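#' Subject profile for the synthetic EEG generator
#'
#' Describes one simulated participant: baseline oscillatory power per band,
#' which channels and bands carry the class effect, the multiplicative power
#' ratio applied to the positive class, artifact rate, and self-report noise.
#'
#' The class effect is a multiplicative scaling of band-limited oscillation
#' variance: for epochs from positive clips the oscillation variance in each
#' effect band on each effect channel is multiplied by the band's effect
#' size. This makes differential-entropy separability analytically
#' predictable (a variance ratio r shifts band DE by log(r)/2).
#'
#' @param subject_id Subject identifier.
#' @param baseline_band_power Named numeric vector of oscillation variances
#'   (uV^2) for the five main bands.
#' @param noise_power Total variance (uV^2) of the 1/f-shaped broadband
#'   background over 0.5-45 Hz.
#' @param effect_channels Channels carrying the class effect (subset of
#'   [montage_32()]).
#' @param effect_bands Bands carrying the class effect.
#' @param effect_size Multiplicative power ratio (>= 1) applied in
#'   `effect_bands` on `effect_channels` for positive clips. Either a single
#'   number or a named vector aligned with `effect_bands` for band-specific
#'   ratios.
#' @param artifact_rate Ocular/muscle artifact events per minute (0 = clean).
#' @param rating_noise_sd SD of the 9-point self-report ratings.
#' @return A `subject_profile` object.
#' @export
subject_profile <- function(subject_id = "S01",
                            baseline_band_power = c(delta = 30, theta = 15,
                                                    alpha = 20, beta = 10,
                                                    gamma = 5),
                            noise_power = 10,
                            effect_channels = c("Fp1", "Fp2", "T7", "T8",
                                                "TP9", "TP10", "O1", "O2",
                                                "Iz"),
                            effect_bands = c("gamma", "beta"),
                            effect_size = c(gamma = 1.6, beta = 1.15),
                            artifact_rate = 0,
                            rating_noise_sd = 1) {
  bands <- names(eeg_bands())
  stopifnot(all(names(baseline_band_power) %in% bands),
            all(effect_bands %in% bands))
  bad <- setdiff(effect_channels, montage_32())
  if (length(bad) > 0)
    stop("unknown channel name(s) in montage: ", paste(bad, collapse = ", "))
  if (is.null(names(effect_size)) && length(effect_size) == 1L)
    effect_size <- stats::setNames(rep(effect_size, length(effect_bands)),
                                   effect_bands)
  if (!all(effect_bands %in% names(effect_size)))
    stop("effect_size must cover every effect band")
  if (any(effect_size < 1)) stop("effect_size must be >= 1")
  if (rating_noise_sd < 0) stop("rating_noise_sd must be >= 0")
  structure(list(subject_id = subject_id,
                 baseline_band_power = baseline_band_power,
                 noise_power = noise_power,
                 effect_channels = effect_channels,
                 effect_bands = effect_bands,
                 effect_size = effect_size,
                 artifact_rate = artifact_rate,
                 rating_noise_sd = rating_noise_sd),
            class = "subject_profile")
}

#' Construct an EEG recording object
#'
#' @param data Numeric matrix, channels x samples (uV).
#' @param fs Sampling rate (Hz).
#' @param channel_names Character vector, one name per row of `data`.
#' @param subject_id,clip_id Identifiers.
#' @param clip_label `"positive"`, `"negative"`, or `NA` for unlabeled data.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, fs, channel_names, subject_id = NA_character_,
                          clip_id = NA_character_,
                          clip_label = NA_character_) {
  data <- as.matrix(data)
  if (length(channel_names) != nrow(data))
    stop("channel_names length must equal the number of data rows")
  if (anyNA(data)) stop("recording data must not contain NA")
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 subject_id = subject_id, clip_id = clip_id,
                 clip_label = clip_label),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  subject: %s  clip: %s  label: %s\n",
              x$subject_id, x$clip_id, x$clip_label))
  invisible(x)
}

# Synthesize one band-limited Gaussian component by spectral shaping:
# complex-normal Fourier coefficients on the in-band bins, scaled so the
# expected time-domain variance equals `variance`.
band_limited_noise <- function(n, fs, f_lo, f_hi, variance) {
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs > 0 & freqs <= fs / 2
  sel <- which(half & freqs >= f_lo & freqs < f_hi)
  if (length(sel) == 0) return(numeric(n))
  shape_spectrum(n, sel, rep(1, length(sel)), variance)
}

# 1/f-shaped broadband background over [f_lo, f_hi] (power ~ 1/f).
pink_noise <- function(n, fs, f_lo = 0.5, f_hi = 45, variance = 10) {
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs > 0 & freqs <= fs / 2
  sel <- which(half & freqs >= f_lo & freqs < f_hi)
  if (length(sel) == 0) return(numeric(n))
  shape_spectrum(n, sel, 1 / freqs[sel], variance)
}

# Build a real signal from complex-normal coefficients with the given power
# shape on the selected positive-frequency bins. Scaled so the EXPECTED
# time-domain variance equals `variance`; the realized band power keeps its
# natural chi-square fluctuation around that target.
shape_spectrum <- function(n, sel, power_shape, variance) {
  amp <- sqrt(power_shape / sum(power_shape))
  coef <- complex(real = stats::rnorm(length(sel)),
                  imaginary = stats::rnorm(length(sel))) * amp
  spec <- complex(real = rep(0, n), imaginary = rep(0, n))
  spec[sel] <- coef
  # Hermitian symmetry for a real inverse transform
  conj_idx <- n - sel + 2L
  ok <- conj_idx >= 1 & conj_idx <= n & conj_idx != sel
  spec[conj_idx[ok]] <- Conj(coef[ok])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  # E[sum_t x^2] = 2 * E[sum |coef|^2] / n = 4/n after amp normalization
  x * sqrt(variance) * n / 2
}

# One blink-like transient: raised-cosine bump, ~400 ms.
blink_waveform <- function(fs, amplitude = 80) {
  n <- max(4L, round(0.4 * fs))
  amplitude * (0.5 - 0.5 * cos(2 * pi * seq_len(n) / n))^2
}

# One muscle burst: 30-45 Hz noise, ~250 ms.
muscle_waveform <- function(fs, amplitude = 30) {
  n <- max(8L, round(0.25 * fs))
  w <- band_limited_noise(n, fs, 30, min(45, fs / 2 - 1), 1)
  s <- stats::sd(w)
  if (s == 0) return(rep(0, n))
  amplitude * w / s * sin(pi * seq_len(n) / n)
}

#' Synthesize one evoked EEG recording for a subject
#'
#' Each channel is the sum of a 1/f-shaped broadband background and five
#' independent band-limited Gaussian oscillations (delta, theta, alpha,
#' beta, gamma). For positive-clip recordings the oscillation variance in
#' the profile's effect bands is multiplied by the profile's effect size on
#' the effect channels. Optional ocular (low-frequency, frontally weighted)
#' and muscle (30-45 Hz burst) transients occur at `artifact_rate` events
#' per minute.
#'
#' @param profile A [subject_profile()].
#' @param clip_label `"positive"` or `"negative"`.
#' @param duration_s Clip length in seconds (> 0).
#' @param fs Sampling rate in Hz (>= 100).
#' @param seed Integer seed; identical inputs give bit-identical data.
#' @param clip_id Optional clip identifier.
#' @return An [eeg_recording()].
#' @export
synthesize_subject_recording <- function(profile, clip_label, duration_s,
                                         fs = 250, seed = 1,
                                         clip_id = NA_character_) {
  stopifnot(inherits(profile, "subject_profile"))
  if (!clip_label %in% c("positive", "negative"))
    stop("clip_label must be 'positive' or 'negative'")
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (fs < 100) stop("fs must be >= 100")
  channels <- montage_32()
  n <- round(duration_s * fs)
  bands <- eeg_bands()
  with_seed(seed, {
    data <- matrix(0, nrow = length(channels), ncol = n,
                   dimnames = list(channels, NULL))
    for (ci in seq_along(channels)) {
      ch <- channels[ci]
      x <- pink_noise(n, fs, variance = profile$noise_power)
      for (b in names(bands)) {
        v <- profile$baseline_band_power[[b]]
        if (is.null(v) || v <= 0) next
        if (clip_label == "positive" && b %in% profile$effect_bands &&
            ch %in% profile$effect_channels)
          v <- v * profile$effect_size[[b]]
        bd <- bands[[b]]
        x <- x + band_limited_noise(n, fs, bd$f_lo, min(bd$f_hi, fs / 2), v)
      }
      data[ci, ] <- x
    }
    if (profile$artifact_rate > 0) {
      n_events <- stats::rpois(1, profile$artifact_rate * duration_s / 60)
      frontal_w <- ifelse(channels %in% c("Fp1", "Fp2"), 1,
                          ifelse(channels %in% frontal_channels(), 0.4, 0.05))
      for (ev in seq_len(n_events)) {
        kind <- sample(c("ocular", "muscle"), 1)
        w <- if (kind == "ocular") blink_waveform(fs) else muscle_waveform(fs)
        start <- sample.int(max(1L, n - length(w)), 1)
        idx <- start:(start + length(w) - 1L)
        if (kind == "ocular") {
          data[, idx] <- data[, idx] + outer(frontal_w, w)
        } else {
          temporal_w <- ifelse(channels %in% c("T7", "T8", "FT9", "FT10"),
                               1, 0.1)
          data[, idx] <- data[, idx] + outer(temporal_w, w)
        }
      }
    }
    eeg_recording(data, fs, channels, profile$subject_id, clip_id, clip_label)
  })
}

#' Generate a self-report rating record for one clip
#'
#' Valence is drawn around 7 for positive clips and 3 for negative clips
#' with SD `rating_noise_sd`; arousal around 6 for both; dominance and
#' liking around 5. All four are clipped to the 9-point scale (1-9).
#'
#' @param profile A [subject_profile()].
#' @param clip_label `"positive"` or `"negative"`.
#' @param seed Integer seed.
#' @return A one-row data frame with columns valence, arousal, dominance,
#'   liking.
#' @export
generate_ratings <- function(profile, clip_label, seed = 1) {
  if (!clip_label %in% c("positive", "negative"))
    stop("clip_label must be 'positive' or 'negative'")
  sd <- profile$rating_noise_sd
  with_seed(seed, {
    v <- stats::rnorm(1, if (clip_label == "positive") 7 else 3, sd)
    a <- stats::rnorm(1, 6, sd)
    d <- stats::rnorm(1, 5, sd)
    l <- stats::rnorm(1, 5, sd)
    data.frame(valence = min(9, max(1, v)), arousal = min(9, max(1, a)),
               dominance = min(9, max(1, d)), liking = min(9, max(1, l)))
  })
}

#' Delete epochs whose self-report contradicts the stimulus tag
#'
#' A clip is concordant when its valence rating classifies on the same side
#' of 4.5 as its stimulus tag: strictly greater than 4.5 for positive clips,
#' strictly less for negative clips. Epochs from non-concordant clips
#' (including a rating of exactly 4.5) are deleted.
#'
#' @param epochs List of epochs from [segment_epochs()].
#' @param ratings Named list (or data frame keyed by `clip_id`) mapping each
#'   clip id to its rating record.
#' @return The concordant subset of `epochs`.
#' @export
apply_label_filter <- function(epochs, ratings) {
  if (length(epochs) == 0) return(epochs)
  keep <- vapply(epochs, function(ep) {
    r <- ratings[[ep$clip_id]]
    if (is.null(r)) stop("no rating for clip '", ep$clip_id, "'")
    if (ep$label == "positive") r$valence > 4.5 else r$valence < 4.5
  }, logical(1))
  epochs[keep]
}

#' Configuration for a synthetic emotional-EEG dataset
#'
#' @param n_subjects Number of subjects.
#' @param clips_per_class Clips per emotion class per subject.
#' @param duration_s Clip length (s).
#' @param fs Sampling rate (Hz).
#' @param profile Template [subject_profile()]; one copy per subject with
#'   the subject id substituted (or pass `profiles`, a list of per-subject
#'   profiles, for heterogeneous populations).
#' @param profiles Optional list of per-subject profiles overriding
#'   `profile`.
#' @return A `dataset_config` object.
#' @export
dataset_config <- function(n_subjects = 6, clips_per_class = 4,
                           duration_s = 8, fs = 250,
                           profile = subject_profile(),
                           profiles = NULL) {
  if (n_subjects <= 0 || clips_per_class <= 0 || duration_s <= 0)
    stop("counts and durations must be positive")
  if (!is.null(profiles) && length(profiles) != n_subjects)
    stop("profiles must have one entry per subject")
  structure(list(n_subjects = n_subjects, clips_per_class = clips_per_class,
                 duration_s = duration_s, fs = fs, profile = profile,
                 profiles = profiles),
            class = "dataset_config")
}

#' Full-scale dataset configuration
#'
#' The acquisition geometry of the emulated study: 26 subjects, 4 positive
#' and 4 negative 60-s clips at 1000 Hz. Expressible but heavy; the desk
#' default of [dataset_config()] (6 subjects, 8-s clips at 250 Hz) is used
#' for routine work.
#'
#' @param ... Overrides passed to [dataset_config()].
#' @export
full_scale_config <- function(...) {
  args <- list(n_subjects = 26, clips_per_class = 4, duration_s = 60,
               fs = 1000)
  do.call(dataset_config, utils::modifyList(args, list(...)))
}

#' Generate a complete synthetic dataset
#'
#' Produces per-clip recordings, per-clip ratings, and 1-s labeled epochs.
#' Epochs are cut with [segment_epochs()] and filtered with
#' [apply_label_filter()]; no filtering/rejection beyond the label filter is
#' applied here (see [preprocess_recording()] for the cleaning pipeline).
#'
#' @param config A [dataset_config()].
#' @param seed Integer seed; identical (config, seed) give identical output.
#' @param epoch_length_s Epoch length for segmentation (default 1 s).
#' @param label_filter Apply the valence concordance filter (default TRUE).
#' @return List with `recordings` (list of [eeg_recording()]), `ratings`
#'   (named list keyed by clip id), and `epochs` (list of labeled epochs).
#' @export
generate_dataset <- function(config, seed = 1, epoch_length_s = 1,
                             label_filter = TRUE) {
  stopifnot(inherits(config, "dataset_config"))
  recordings <- list()
  ratings <- list()
  epochs <- list()
  for (si in seq_len(config$n_subjects)) {
    prof <- if (!is.null(config$profiles)) config$profiles[[si]]
            else config$profile
    prof$subject_id <- sprintf("S%02d", si)
    for (cls in c("positive", "negative")) {
      for (ki in seq_len(config$clips_per_class)) {
        clip_id <- sprintf("%s_%s_%02d", prof$subject_id, cls, ki)
        cls_i <- if (cls == "positive") 1L else 2L
        rec <- synthesize_subject_recording(
          prof, cls, config$duration_s, config$fs,
          seed = child_seed(seed, si, cls_i, ki, 1L), clip_id = clip_id)
        recordings[[clip_id]] <- rec
        ratings[[clip_id]] <- generate_ratings(
          prof, cls, seed = child_seed(seed, si, cls_i, ki, 2L))
        epochs <- c(epochs, segment_epochs(rec, epoch_length_s))
      }
    }
  }
  if (label_filter) epochs <- apply_label_filter(epochs, ratings)
  list(recordings = recordings, ratings = ratings, epochs = epochs)
}
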