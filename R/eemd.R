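#' Empirical mode decomposition of a single signal
#'
#' Standard sifting with natural-cubic-spline envelopes through the local
#' extrema (endpoints clamped), stopping a sift when the envelope-mean
#' energy falls below `sd_tol^2` of the signal energy or after `max_sift`
#' iterations. The residue is the input minus the sum of IMFs, so the
#' decomposition is complete by construction.
#'
#' @param x Numeric vector.
#' @param max_imf Maximum number of IMFs.
#' @param sd_tol Sifting stop tolerance.
#' @param max_sift Maximum sifting iterations per IMF.
#' @return Matrix with one row per IMF plus a final residue row.
#' @export
emd_decompose <- function(x, max_imf = 10, sd_tol = 0.2, max_sift = 10) {
  stopifnot(is.numeric(x), length(x) >= 8)
  .emd_decompose_cpp(as.numeric(x), as.integer(max_imf), sd_tol,
                     as.integer(max_sift))
}

#' Ensemble empirical mode decomposition (EEMD)
#'
#' Noise-assisted EMD: `n_ensembles` white-noise realizations of standard
#' deviation `noise_sd * sd(x)` are added to the signal, each copy is
#' decomposed by [emd_decompose()], and the IMFs are averaged across the
#' ensemble (rows padded with zeros when members yield fewer IMFs). The
#' averaged rows sum to the signal plus the ensemble-mean noise, so the
#' reconstruction error shrinks as `noise_sd/sqrt(n_ensembles)`.
#'
#' @param x Numeric vector.
#' @param n_ensembles Ensemble size (default 100).
#' @param noise_sd Added-noise SD as a fraction of `sd(x)` (default 0.2).
#' @param seed Integer seed.
#' @param ... Passed to [emd_decompose()].
#' @return Matrix of averaged IMFs with a final residue row.
#' @export
eemd_decompose <- function(x, n_ensembles = 100, noise_sd = 0.2, seed = 1,
                           ...) {
  stopifnot(n_ensembles >= 1, noise_sd >= 0)
  s <- stats::sd(x)
  if (noise_sd == 0 || n_ensembles == 1 || s == 0)
    return(emd_decompose(x, ...))
  n <- length(x)
  with_seed(seed, {
    decs <- lapply(seq_len(n_ensembles), function(e)
      emd_decompose(x + stats::rnorm(n, 0, noise_sd * s), ...))
    max_rows <- max(vapply(decs, nrow, integer(1)))
    acc <- matrix(0, max_rows, n)
    for (d in decs) {
      k <- nrow(d)
      # keep the residue in the last row; pad missing IMF rows with zeros
      if (k > 1) acc[seq_len(k - 1), ] <- acc[seq_len(k - 1), ] +
          d[seq_len(k - 1), , drop = FALSE]
      acc[max_rows, ] <- acc[max_rows, ] + d[k, ]
    }
    acc / n_ensembles
  })
}

#' Clean a dual-frontal recording by EEMD + ICA
#'
#' The dual-channel artifact-removal path for recordings with too few
#' channels for direct ICA: each channel is decomposed into IMFs by EEMD,
#' ICA is run on the pooled IMF set of both channels, components whose
#' correlation with a low-frequency ocular template exceeds `threshold` are
#' removed, the IMFs are reconstructed from the retained components, and
#' each channel is rebuilt by summing its cleaned IMFs and residue.
#'
#' @param recording An [eeg_recording()] with exactly 2 channels
#'   (Fp1, Fp2).
#' @param n_ensembles,noise_sd EEMD controls (defaults 100 and 0.2).
#' @param threshold Ocular-correlation flagging threshold (default 0.8).
#' @param seed Integer seed.
#' @return The cleaned 2-channel recording.
#' @export
eemd_clean_dual_channel <- function(recording, n_ensembles = 100,
                                    noise_sd = 0.2, threshold = 0.8,
                                    seed = 1) {
  if (nrow(recording$data) != 2)
    stop("dual-channel cleaning requires exactly 2 channels")
  n <- ncol(recording$data)
  decs <- lapply(1:2, function(ci)
    eemd_decompose(recording$data[ci, ], n_ensembles, noise_sd,
                   seed = child_seed(seed, ci)))
  rows_per_ch <- vapply(decs, nrow, integer(1))
  pooled <- do.call(rbind, decs)
  # drop near-constant rows (deep residues) from the ICA but keep them for
  # reconstruction
  sds <- apply(pooled, 1, stats::sd)
  active <- which(sds > 1e-9 * max(sds))
  cleaned <- pooled
  if (length(active) >= 2) {
    dec <- fastica_decompose(pooled[active, , drop = FALSE],
                             seed = child_seed(seed, 99L))
    templ <- ocular_template(recording$data, recording$channel_names,
                             recording$fs)
    r <- apply(dec$sources, 1, function(s)
      if (stats::sd(s) == 0) 0 else abs(stats::cor(s, templ)))
    flagged <- which(r > threshold)
    if (length(flagged) > 0) {
      keep <- setdiff(seq_len(nrow(dec$sources)), flagged)
      cleaned[active, ] <- dec$mixing[, keep, drop = FALSE] %*%
        dec$sources[keep, , drop = FALSE] + dec$means
    }
  }
  out <- recording$data
  split_at <- rows_per_ch[1]
  out[1, ] <- colSums(cleaned[seq_len(split_at), , drop = FALSE])
  out[2, ] <- colSums(cleaned[(split_at + 1):nrow(cleaned), , drop = FALSE])
  recording$data <- out
  recording
}
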