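#' Standard 32-channel 10-20 montage
#'
#' Electrode names of the 32-channel extended 10-20 cap assumed throughout
#' the package, in conventional anterior-to-posterior order.
#'
#' @return Character vector of 32 electrode names.
#' @export
montage_32 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FT9", "FC5", "FC1", "FC2", "FC6", "FT10",
    "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8",
    "O1", "O2", "Iz")
}

#' Frontal electrodes used to build the ocular reference template
#' @keywords internal
frontal_channels <- function() c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8")

#' Define a frequency band
#'
#' @param name Band name (e.g. "alpha").
#' @param f_lo,f_hi Band edges in Hz; bins are selected as
#'   `f_lo <= f < f_hi` (the Nyquist bin is included when `f_hi` reaches it).
#' @return A `band_definition` object.
#' @export
band_definition <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(f_lo < f_hi)) stop("band '", name, "': f_lo must be < f_hi")
  if (f_lo < 0) stop("band '", name, "': f_lo must be >= 0")
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi),
            class = "band_definition")
}

#' Canonical EEG frequency bands
#'
#' The five clinical bands partitioning the 0.5-45 Hz analysis range:
#' delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-45 Hz.
#'
#' @return Named list of [band_definition()] objects.
#' @export
eeg_bands <- function() {
  list(
    delta = band_definition("delta", 0.5, 4),
    theta = band_definition("theta", 4, 8),
    alpha = band_definition("alpha", 8, 13),
    beta  = band_definition("beta", 13, 30),
    gamma = band_definition("gamma", 30, 45)
  )
}

#' Low/high sub-band splits of the main bands
#'
#' Delta splits at 2 Hz, alpha at 10 Hz, beta at 20 Hz, gamma at 38 Hz;
#' theta is not split.
#'
#' @return Named list of [band_definition()] objects.
#' @export
eeg_sub_bands <- function() {
  list(
    low_delta  = band_definition("low_delta", 0.5, 2),
    high_delta = band_definition("high_delta", 2, 4),
    low_alpha  = band_definition("low_alpha", 8, 10),
    high_alpha = band_definition("high_alpha", 10, 13),
    low_beta   = band_definition("low_beta", 13, 20),
    high_beta  = band_definition("high_beta", 20, 30),
    low_gamma  = band_definition("low_gamma", 30, 38),
    high_gamma = band_definition("high_gamma", 38, 45)
  )
}

#' Full analysis band (0.5-45 Hz)
#' @return A [band_definition()].
#' @export
analysis_band <- function() band_definition("total", 0.5, 45)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed below 2^31 from a parent seed and stream indices.
# Multiplier kept small so every product stays below 2^53 and the modular
# arithmetic is exact in doubles.
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in c(idx, 1)) {
    s <- (s * 69069 + 12345 + as.double(k)) %% 2147483647
    s <- (s * 69069 + 1) %% 2147483647
  }
  as.integer(s)
}
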