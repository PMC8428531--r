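#' Suite configuration for an end-to-end experiment run
#'
#' @param dataset A [dataset_config()] (or a path to an epoch container
#'   from [save_epochs()] via `epochs_dir`).
#' @param epochs_dir Optional epoch-container directory used instead of
#'   synthetic generation.
#' @param preprocess A [preprocess_config()].
#' @param experiments Data frame of experiments (see
#'   [study_experiments()]); columns `id`, `feature_set`,
#'   `normalize`, `scheme_rule` (NA or an electrode-scheme rule), `bands`
#'   (comma-separated, for multi-band DE sets).
#' @param classifiers Named list of [classifier_spec()] objects.
#' @param folds Cross-validation folds (default 10).
#' @param seed Master seed for generation, fold splits, and fits.
#' @param eemd_ensembles,eemd_noise_sd Dual-channel EEMD controls.
#' @param out_dir Output directory for report files.
#' @return A `suite_config` object.
#' @export
suite_config <- function(dataset = dataset_config(), epochs_dir = NULL,
                         preprocess = preprocess_config(),
                         experiments = study_experiments(),
                         classifiers = default_classifiers(),
                         folds = 10, seed = 1,
                         eemd_ensembles = 100, eemd_noise_sd = 0.2,
                         out_dir = "results") {
  structure(list(dataset = dataset, epochs_dir = epochs_dir,
                 preprocess = preprocess, experiments = experiments,
                 classifiers = classifiers, folds = folds, seed = seed,
                 eemd_ensembles = eemd_ensembles,
                 eemd_noise_sd = eemd_noise_sd, out_dir = out_dir),
            class = "suite_config")
}

#' Default classifier set (all four kinds)
#' @param seed Seed shared by the specs.
#' @param ... Overrides passed to every [classifier_spec()].
#' @export
default_classifiers <- function(seed = 1, ...) {
  kinds <- c("svm_linear", "dt_c45", "bpnn", "knn_brute")
  stats::setNames(lapply(kinds, function(k)
    classifier_spec(k, seed = seed, ...)), kinds)
}

#' The full experiment grid emulating the source study's structure
#'
#' Experiment families: `1-1` the 59-feature baseline on all channels;
#' `2-1..2-5` the energy-ratio/differential-entropy ablations with
#' normalization variants; `3-1..3-6` per-band DE; `5-1..5-5` gamma-DE on
#' the five electrode schemes; `dual` the 20-feature dual-frontal set.
#'
#' @return Data frame with one row per experiment.
#' @export
study_experiments <- function() {
  data.frame(
    id = c("1-1",
           "2-1", "2-2", "2-3", "2-4", "2-5",
           "3-1", "3-2", "3-3", "3-4", "3-5", "3-6",
           "5-1", "5-2", "5-3", "5-4", "5-5",
           "dual"),
    feature_set = c("baseline",
                    "ratio_de", "ratio_de", "ratio_de", "de", "ratio",
                    "de_gamma", "de_beta", "de_alpha", "de_theta",
                    "de_delta", "de_bands",
                    "de_gamma", "de_gamma", "de_gamma", "de_gamma",
                    "de_gamma",
                    "dual20"),
    normalize = c("none",
                  "none", "zscore", "minmax01", "none", "none",
                  rep("none", 6),
                  rep("none", 5),
                  "none"),
    scheme_rule = c(NA,
                    rep(NA, 5), rep(NA, 6),
                    "forehead", "thr_0.05", "thr_0.03", "head_loop",
                    "half_loop",
                    NA),
    bands = c(NA, rep(NA, 5), rep(NA, 5), "beta,gamma", rep(NA, 5), NA),
    stringsAsFactors = FALSE)
}

#' Desk-scale preset reproducing the whole study structure synthetically
#'
#' 6 subjects, 4+4 clips of 8 s at 250 Hz, all experiment families, all
#' four classifiers, both evaluation schemes.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param ... Overrides forwarded to [suite_config()].
#' @export
full_study <- function(out_dir = "results", seed = 1, ...) {
  suite_config(
    dataset = dataset_config(n_subjects = 6, clips_per_class = 4,
                             duration_s = 8, fs = 250),
    classifiers = default_classifiers(seed = seed, max_hidden = 12,
                                      maxit = 50, inner_folds = 2),
    eemd_ensembles = 30,
    out_dir = out_dir, seed = seed, ...)
}

# config fingerprint: md5 of the canonical JSON serialization
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  ser <- rapply(unclass(config), function(v)
    if (is.function(v)) "<function>" else v, how = "replace")
  jsonlite::write_json(ser, tmp, auto_unbox = TRUE, force = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

write_stamped_csv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a stamped CSV written by [run_suite()]
#' @param path CSV file with a leading `#` provenance line.
#' @export
read_stamped_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}

# Preprocess every recording through the multi-channel path and pool the
# surviving epochs.
preprocess_dataset <- function(recordings, ratings, pp) {
  epochs <- list()
  for (rec in recordings)
    epochs <- c(epochs, preprocess_recording(rec, pp))
  apply_label_filter(epochs, ratings)
}

# The dual-frontal path: Fp1/Fp2 subset, filter, EEMD+ICA clean, segment,
# reject. No average re-reference with two channels.
preprocess_dual <- function(recordings, ratings, pp, n_ensembles, noise_sd,
                            seed) {
  epochs <- list()
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    keep <- match(c("Fp1", "Fp2"), rec$channel_names)
    rec$data <- rec$data[keep, , drop = FALSE]
    rec$channel_names <- c("Fp1", "Fp2")
    rec <- bandpass_notch_filter(rec, pp)
    rec <- eemd_clean_dual_channel(rec, n_ensembles, noise_sd,
                                   seed = child_seed(seed, i))
    eps <- segment_epochs(rec, pp$epoch_length_s)
    epochs <- c(epochs, reject_amplitude(eps, pp$reject_uV))
  }
  apply_label_filter(epochs, ratings)
}

#' Run an end-to-end experiment suite
#'
#' Stages: generate (or load) recordings, preprocess (multi-channel and,
#' when a dual-channel experiment is configured, the EEMD dual-frontal
#' path), extract features per experiment, rank electrodes by GBDT
#' contribution on gamma-band DE, cross-validate every classifier under
#' both the pooled and the per-subject scheme, and write report files:
#' `results.csv`, `contributions.csv`, `summary.txt`, and `run_log.json`
#' (all resolved parameters and seeds; CSVs carry the config hash).
#'
#' @param config A [suite_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `results` (data frame), `contributions`,
#'   and `files`.
#' @export
run_suite <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "suite_config"))
  hash <- config_hash(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  stage <- "generate"
  results <- NULL
  tryCatch({
    if (!is.null(config$epochs_dir)) {
      epochs_raw <- load_epochs(config$epochs_dir)
      recordings <- NULL
      ratings <- NULL
      epochs <- epochs_raw
      dual_epochs <- NULL
    } else {
      say("generating synthetic dataset (%d subjects)...",
          config$dataset$n_subjects)
      ds <- generate_dataset(config$dataset, seed = config$seed,
                             label_filter = FALSE)
      recordings <- ds$recordings
      ratings <- ds$ratings

      stage <- "preprocess"
      say("preprocessing (multi-channel path)...")
      epochs <- preprocess_dataset(recordings, ratings, config$preprocess)
      dual_epochs <- NULL
      if (any(config$experiments$feature_set == "dual20")) {
        say("preprocessing (dual-frontal EEMD path)...")
        dual_epochs <- preprocess_dual(recordings, ratings,
                                       config$preprocess,
                                       config$eemd_ensembles,
                                       config$eemd_noise_sd, config$seed)
      }
    }
    if (length(epochs) == 0) stop("no epochs survived preprocessing")

    stage <- "channel_selection"
    say("ranking electrodes (GBDT on gamma-band DE)...")
    fm_gamma <- build_feature_matrix(epochs, "de_gamma",
                                     channels = epochs[[1]]$channel_names)
    contributions <- fit_gbdt_contributions(fm_gamma, seed = config$seed)

    stage <- "features_classification"
    fm_cache <- list(de_gamma = fm_gamma)
    rows <- list()
    for (e in seq_len(nrow(config$experiments))) {
      ex <- config$experiments[e, ]
      chans <- epochs[[1]]$channel_names
      if (!is.na(ex$scheme_rule))
        chans <- build_scheme(contributions, ex$scheme_rule)$electrodes
      bands <- if (!is.na(ex$bands)) strsplit(ex$bands, ",")[[1]] else NULL
      use_epochs <- epochs
      if (ex$feature_set == "dual20") {
        if (is.null(dual_epochs)) stop("dual-channel epochs unavailable")
        use_epochs <- dual_epochs
      }
      cache_key <- paste(ex$feature_set, paste(chans, collapse = ","),
                         paste(bands, collapse = ","))
      if (is.null(fm_cache[[cache_key]]))
        fm_cache[[cache_key]] <- build_feature_matrix(
          use_epochs, ex$feature_set, channels = chans, bands = bands)
      fm <- fm_cache[[cache_key]]
      say("experiment %s: %s (%d features)...", ex$id, ex$feature_set,
          ncol(fm$x))
      for (cl in names(config$classifiers)) {
        spec <- config$classifiers[[cl]]
        spec$seed <- child_seed(config$seed, e, match(cl,
                                names(config$classifiers)))
        for (scheme in c("whole", "single")) {
          r <- if (scheme == "whole")
            evaluate_whole(spec, fm, normalize = ex$normalize,
                           k = config$folds)
          else
            evaluate_single(spec, fm, normalize = ex$normalize,
                            k = config$folds)
          rows[[length(rows) + 1]] <- data.frame(
            experiment = ex$id, feature_set = ex$feature_set,
            electrode_scheme = ifelse(is.na(ex$scheme_rule), "all",
                                      ex$scheme_rule),
            n_features = ncol(fm$x), normalize = ex$normalize,
            scheme = scheme, classifier = cl,
            train_acc = r$train_acc, test_acc = r$test_acc)
        }
      }
    }
    results <- do.call(rbind, rows)
  }, error = function(err) {
    stop("suite failed at stage '", stage, "': ", conditionMessage(err),
         call. = FALSE)
  })

  files <- report_tables(results, contributions, config, hash)
  say("done: %s", paste(files, collapse = ", "))
  invisible(list(results = results, contributions = contributions,
                 files = files))
}

#' Write the suite report tables
#'
#' @param results Data frame of per-(experiment, scheme, classifier) rows.
#' @param contributions A `contribution_table` (or NULL).
#' @param config The `suite_config` that produced the results.
#' @param hash Config hash (computed from `config` when NULL).
#' @return Character vector of file paths written.
#' @export
report_tables <- function(results, contributions = NULL, config = NULL,
                          hash = NULL) {
  if (is.null(results) || nrow(results) == 0)
    stop("no results to report")
  if (is.null(hash))
    hash <- if (!is.null(config)) config_hash(config) else "unhashed"
  out_dir <- if (!is.null(config)) config$out_dir else "."
  seed <- if (!is.null(config)) config$seed else NA_integer_
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- results[order(results$experiment, results$scheme,
                           results$classifier), ]
  files <- character(0)
  f <- file.path(out_dir, "results.csv")
  write_stamped_csv(results, f, hash, seed)
  files <- c(files, f)
  if (!is.null(contributions)) {
    f <- file.path(out_dir, "contributions.csv")
    write_stamped_csv(as.data.frame(contributions), f, hash, seed)
    files <- c(files, f)
  }
  best <- results[which.max(results$test_acc), ]
  summary_lines <- c(
    sprintf("config_hash: %s  seed: %s", hash, seed),
    sprintf("experiments: %d  rows: %d",
            length(unique(results$experiment)), nrow(results)),
    sprintf("best test accuracy: %.4f (experiment %s, %s scheme, %s, %s)",
            best$test_acc, best$experiment, best$scheme, best$classifier,
            best$feature_set))
  f <- file.path(out_dir, "summary.txt")
  writeLines(summary_lines, f)
  files <- c(files, f)
  if (!is.null(config)) {
    log <- list(config_hash = hash, seed = seed,
                folds = config$folds,
                dataset = unclass(config$dataset$profile)["subject_id"],
                n_subjects = config$dataset$n_subjects,
                clips_per_class = config$dataset$clips_per_class,
                duration_s = config$dataset$duration_s,
                fs = config$dataset$fs,
                eemd_ensembles = config$eemd_ensembles,
                eemd_noise_sd = config$eemd_noise_sd,
                experiments = config$experiments$id,
                classifiers = names(config$classifiers))
    f <- file.path(out_dir, "run_log.json")
    jsonlite::write_json(log, f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  files
}

#' Load a suite configuration from YAML or JSON
#'
#' Reads the documented schema: top-level keys `dataset`, `preprocess`,
#' `folds`, `seed`, `out_dir`, `experiments` (ids into
#' [study_experiments()]), `classifiers` (kinds).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @export
read_suite_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  ds <- do.call(dataset_config, as.list(raw$dataset %||% list()))
  pp <- do.call(preprocess_config, as.list(raw$preprocess %||% list()))
  exps <- study_experiments()
  if (!is.null(raw$experiments))
    exps <- exps[exps$id %in% unlist(raw$experiments), ]
  cls <- default_classifiers(seed = raw$seed %||% 1)
  if (!is.null(raw$classifiers))
    cls <- cls[unlist(raw$classifiers)]
  suite_config(dataset = ds, preprocess = pp, experiments = exps,
               classifiers = cls, folds = raw$folds %||% 10,
               seed = raw$seed %||% 1,
               out_dir = raw$out_dir %||% "results")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
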