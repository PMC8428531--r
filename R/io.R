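#' Save labeled epochs as a portable directory container
#'
#' Writes `data.csv` (one row per epoch, columns `<channel>_t<sample>`)
#' plus a sidecar `meta.json` holding the channel names, sampling rate,
#' samples per epoch, and the per-epoch labels/subjects/clips.
#'
#' @param epochs List of `eeg_epoch` objects with identical geometry.
#' @param dir Output directory (created if missing).
#' @export
save_epochs <- function(epochs, dir) {
  stopifnot(length(epochs) > 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ch <- epochs[[1]]$channel_names
  n <- ncol(epochs[[1]]$data)
  mat <- t(vapply(epochs, function(ep) as.numeric(t(ep$data)),
                  numeric(length(ch) * n)))
  colnames(mat) <- paste0(rep(ch, each = n), "_t", rep(seq_len(n), length(ch)))
  utils::write.csv(mat, file.path(dir, "data.csv"), row.names = FALSE)
  meta <- list(
    channel_names = ch, fs = epochs[[1]]$fs, n_samples = n,
    label = vapply(epochs, function(e) e$label, character(1)),
    subject_id = vapply(epochs, function(e) e$subject_id, character(1)),
    clip_id = vapply(epochs, function(e) e$clip_id, character(1)))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Load an epoch container written by [save_epochs()]
#' @param dir Container directory.
#' @return List of `eeg_epoch` objects.
#' @export
load_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  mat <- as.matrix(utils::read.csv(file.path(dir, "data.csv")))
  n <- meta$n_samples
  ch <- meta$channel_names
  lapply(seq_len(nrow(mat)), function(i) {
    d <- matrix(mat[i, ], nrow = length(ch), ncol = n, byrow = TRUE,
                dimnames = list(ch, NULL))
    structure(list(data = d, fs = meta$fs, channel_names = ch,
                   label = meta$label[i], subject_id = meta$subject_id[i],
                   clip_id = meta$clip_id[i], epoch_index = i),
              class = "eeg_epoch")
  })
}
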