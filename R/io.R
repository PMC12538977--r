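#' Write a spectrum set as delimited text
#'
#' Comma-separated, UTF-8, "." decimal: a header row `patient_id,
#' replicate, <wavenumber...>` followed by one spectrum per row. Round
#' trips bit-exactly through [read_spectra()].
#'
#' @param set a [spectrum_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path) {
  stopifnot(inherits(set, "spectrum_set"))
  header <- c("patient_id", "replicate",
              formatC(set$axis, digits = 17, format = "g"))
  rows <- vapply(seq_len(n_spectra(set)), function(i) {
    paste(c(set$patient_id[i], set$replicate[i],
            formatC(set$intensities[i, ], digits = 17, format = "g")),
          collapse = ",")
  }, "")
  writeLines(c(paste(header, collapse = ","), rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read a spectrum set from delimited text
#'
#' Expects the format written by [write_spectra()]. Fails with an
#' informative message (including the offending line) on ragged rows,
#' non-monotone axes or duplicate (patient, replicate) keys.
#'
#' @param path input file.
#' @return A [spectrum_set()].
#' @export
read_spectra <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop_invalid("spectra file is empty: ", path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(header) < 4 || header[1] != "patient_id" ||
      header[2] != "replicate")
    stop_invalid("line 1: header must be patient_id,replicate,<axis...>")
  axis <- suppressWarnings(as.numeric(header[-(1:2)]))
  if (anyNA(axis)) stop_invalid("line 1: non-numeric axis value")
  if (any(diff(axis) <= 0)) stop_invalid("line 1: axis is not monotone")
  n_chan <- length(axis)
  n <- length(lines) - 1L
  pid <- character(n); rep_ <- integer(n)
  Y <- matrix(0, n, n_chan)
  for (i in seq_len(n)) {
    parts <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1]]
    if (length(parts) != n_chan + 2L)
      stop_invalid("line ", i + 1L, ": expected ", n_chan + 2L,
                   " fields, got ", length(parts))
    pid[i] <- parts[1]
    rep_[i] <- as.integer(parts[2])
    vals <- suppressWarnings(as.numeric(parts[-(1:2)]))
    if (anyNA(vals)) stop_invalid("line ", i + 1L, ": non-numeric intensity")
    Y[i, ] <- vals
  }
  key <- paste(pid, rep_)
  if (anyDuplicated(key))
    stop_invalid("duplicate (patient_id, replicate) key: ",
                 key[duplicated(key)][1])
  spectrum_set(Y, axis, pid, rep_)
}

#' Write / read the patient metadata table
#'
#' Plain CSV with columns patient_id, diagnosis, age, sex, abeta42, ptau,
#' total_tau (missing total tau as empty field).
#'
#' @param patients data.frame of patient records.
#' @param path file path.
#' @return `path` / the data.frame.
#' @export
write_patients <- function(patients, path) {
  utils::write.csv(patients, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_patients
#' @export
read_patients <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if (!all(c("patient_id", "diagnosis") %in% names(p)))
    stop_invalid("metadata must contain patient_id and diagnosis columns")
  p
}

#' Write / read a run configuration
#'
#' YAML round trip of the pipeline configuration (paths, stage parameters
#' and all seeds); `read_run_config(write_run_config(cfg, f))` is the
#' identity.
#'
#' @param config a named list of configuration values.
#' @param path file path.
#' @return `path` / the configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Default run configuration
#'
#' @param out_dir artefact output directory.
#' @param seed master seed for all stochastic stages.
#' @param simulate generate a synthetic cohort (TRUE) or read spectra and
#'   metadata from `spectra_path` / `patients_path`.
#' @param spectra_path,patients_path input files when `simulate = FALSE`.
#' @param model,input classifier settings, see [raman_ad()].
#' @param write_plots emit ROC/barcode plots as PNG files.
#' @return Named configuration list.
#' @export
run_config <- function(out_dir = "ramanad-run", seed = 1L, simulate = TRUE,
                       spectra_path = NULL, patients_path = NULL,
                       model = "bagged_tree", input = "barcode",
                       write_plots = TRUE) {
  list(out_dir = out_dir, seed = seed, simulate = simulate,
       spectra_path = spectra_path, patients_path = patients_path,
       model = model, input = input, write_plots = write_plots)
}

#' Run the full analysis pipeline and write its artefacts
#'
#' Simulates (or reads) a cohort, fits the classifier via [raman_ad()],
#' runs the feature-importance and partial-correlation analyses, and
#' writes every artefact (barcode, feature table, evaluation metrics, ROC
#' points, importance and correlation tables, plus the resolved
#' configuration) as delimited text under `config$out_dir`. Rerunning with
#' the same configuration reproduces the artefacts.
#'
#' @param config a [run_config()] list (or a path to a YAML file of one).
#' @return Invisibly, the fitted `raman_ad` object with an
#'   `artefact_dir` attribute.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L

  if (isTRUE(config$simulate)) {
    cohort <- simulate_cohort(synth_config(seed = seed))
    spectra <- cohort$spectra
    patients <- cohort$patients
  } else {
    spectra <- read_spectra(config$spectra_path)
    patients <- read_patients(config$patients_path)
  }

  fit <- raman_ad(spectra, patients, model = config$model %||% "bagged_tree",
                  input = config$input %||% "barcode", seed = seed)

  out <- function(f) file.path(config$out_dir, f)
  if (!is.null(fit$barcode))
    utils::write.csv(fit$barcode$regions, out("barcode.csv"),
                     row.names = FALSE)
  if (!is.null(fit$features))
    utils::write.csv(fit$features, out("feature_table.csv"),
                     row.names = FALSE)
  utils::write.csv(fit$eval$test$patient_roc$points, out("roc_test.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$eval$train$patient_roc$points, out("roc_train.csv"),
                   row.names = FALSE)
  mt <- fit$eval$test$metrics
  metrics <- data.frame(metric = c("accuracy", "sensitivity", "specificity",
                                   "ppv", "npv", "f1", "auroc",
                                   "sem_cv_auc"),
                        value = c(mt$accuracy, mt$sensitivity,
                                  mt$specificity, mt$ppv, mt$npv, mt$f1,
                                  mt$auroc, fit$eval$sem_cv_auc))
  utils::write.csv(metrics, out("metrics_test.csv"), row.names = FALSE)

  scores <- data.frame(patient_id = names(fit$eval$test$patient_scores),
                       score = unname(fit$eval$test$patient_scores),
                       diagnosis = fit$eval$test$patient_labels)
  utils::write.csv(scores, out("patient_scores_test.csv"), row.names = FALSE)

  if (!is.null(fit$features)) {
    imp <- global_surrogate_importance(fit, feature_matrix(fit$features),
                                       n_perturb = 300L, max_points = 60L,
                                       seed = seed)
    utils::write.csv(imp$importance, out("importance.csv"), row.names = FALSE)

    all_features <- build_feature_table(fit$spectra, fit$barcode)
    cm <- correlation_matrix(all_features, patients)
    utils::write.csv(cm, out("correlations_biomarkers.csv"),
                     row.names = FALSE)
    agg <- aggregate_features(all_features)
    vals <- as.list(agg[grep("^feature_", names(agg))])
    vals <- lapply(vals, function(v) stats::setNames(v, agg$patient_id))
    pc <- plm_correlations(vals, patients)
    utils::write.csv(pc, out("correlations_plm.csv"), row.names = FALSE)
  }

  if (isTRUE(config$write_plots)) {
    grDevices::png(out("roc.png"), width = 700, height = 600)
    plot(fit, type = "roc")
    grDevices::dev.off()
    if (!is.null(fit$barcode)) {
      grDevices::png(out("barcode.png"), width = 900, height = 500)
      plot(fit, type = "barcode")
      grDevices::dev.off()
    }
  }
  write_run_config(config, out("config.yaml"))
  attr(fit, "artefact_dir") <- config$out_dir
  invisible(fit)
}
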