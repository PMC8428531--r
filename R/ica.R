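#' FastICA decomposition of a channels-x-samples matrix
#'
#' Symmetric FastICA with the tanh contrast: the data are centered and
#' whitened by eigendecomposition of the covariance, then the unmixing
#' matrix is estimated by fixed-point iteration with symmetric
#' decorrelation. Deterministic for a given seed.
#'
#' @param x Numeric matrix, channels x samples.
#' @param n_components Number of components. The default (`NULL`) uses the
#'   effective rank of the data covariance, so rank-deficient inputs (e.g.
#'   average-referenced recordings, whose channels sum to zero) decompose
#'   without error.
#' @param max_iter,tol Fixed-point iteration controls.
#' @param seed Seed for the random orthogonal initialization.
#' @return List with `sources` (components x samples), `mixing`
#'   (channels x components), `means` (channel means), such that
#'   `mixing %*% sources + means` reconstructs `x`.
#' @export
fastica_decompose <- function(x, n_components = NULL, max_iter = 200,
                              tol = 1e-6, seed = 1) {
  if (nrow(x) < 2) stop("ICA needs at least 2 observed signals")
  if (!is.null(n_components) && n_components > nrow(x))
    stop("cannot extract more components than observed signals")
  n <- ncol(x)
  means <- rowMeans(x)
  xc <- x - means
  cov <- tcrossprod(xc) / n
  eig <- eigen(cov, symmetric = TRUE)
  rank <- sum(eig$values > 1e-10 * max(eig$values))
  if (is.null(n_components)) n_components <- rank
  if (n_components > rank)
    stop("data rank below the requested number of components")
  d <- eig$values[seq_len(n_components)]
  E <- eig$vectors[, seq_len(n_components), drop = FALSE]
  whiten <- diag(1 / sqrt(d), n_components) %*% t(E)
  dewhiten <- E %*% diag(sqrt(d), n_components)
  z <- whiten %*% xc
  W <- with_seed(seed, {
    m <- matrix(stats::rnorm(n_components^2), n_components)
    qr.Q(qr(m))
  })
  sym_decorrelate <- function(W) {
    s <- W %*% t(W)
    e <- eigen(s, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)),
                       n_components) %*% t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    wz <- W %*% z
    g <- tanh(wz)
    gp <- 1 - g^2
    W_new <- (g %*% t(z)) / n - diag(rowMeans(gp), n_components) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(rowSums(W_new * W)) - 1))
    W <- W_new
    if (delta < tol) break
  }
  sources <- W %*% z
  mixing <- dewhiten %*% t(W)
  list(sources = sources, mixing = mixing, means = means)
}

# Ocular reference template: 0.5-4 Hz band of the mean of the available
# frontal channels (falls back to the overall mean if none are present).
ocular_template <- function(data, channel_names, fs) {
  fr <- intersect(frontal_channels(), channel_names)
  base <- if (length(fr) > 0) colMeans(data[fr, , drop = FALSE])
          else colMeans(data)
  nyq <- fs / 2
  lp <- signal::butter(4, c(0.5, 4) / nyq, type = "pass")
  signal::filtfilt(lp, base - mean(base))
}

#' Remove ocular components from a multi-channel recording by ICA
#'
#' Decomposes the recording into independent components, flags components
#' whose absolute correlation with a frontally weighted low-frequency
#' ocular template exceeds `threshold`, and reconstructs the recording
#' without them. With no flagged component the reconstruction is
#' numerically identical to the input.
#'
#' @param recording An [eeg_recording()] with at least 8 channels (the
#'   dual-frontal path must use [eemd_clean_dual_channel()] instead).
#' @param threshold Absolute correlation threshold for flagging (default
#'   0.8).
#' @param n_components Components to extract (default: channel count).
#' @param seed ICA initialization seed.
#' @return The cleaned recording.
#' @export
remove_ocular_ica <- function(recording, threshold = 0.8,
                              n_components = NULL, seed = 1) {
  nch <- nrow(recording$data)
  if (nch < 8)
    stop("ICA ocular correction needs >= 8 channels; ",
         "use eemd_clean_dual_channel() for dual-frontal recordings")
  dec <- fastica_decompose(recording$data, n_components, seed = seed)
  templ <- ocular_template(recording$data, recording$channel_names,
                           recording$fs)
  r <- apply(dec$sources, 1, function(s)
    if (stats::sd(s) == 0) 0 else abs(stats::cor(s, templ)))
  flagged <- which(r > threshold)
  if (length(flagged) == 0) return(recording)
  keep <- setdiff(seq_len(nrow(dec$sources)), flagged)
  recon <- dec$mixing[, keep, drop = FALSE] %*%
    dec$sources[keep, , drop = FALSE] + dec$means
  dimnames(recon) <- dimnames(recording$data)
  recording$data <- recon
  recording
}
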