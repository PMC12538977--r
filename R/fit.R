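#' Fit the full CSF Raman classification model
#'
#' The central fitting function of the package. Starting from (raw or
#' preprocessed) replicate spectra and the patient metadata it:
#'
#' 1. preprocesses the spectra (spike removal, Haar-wavelet denoising,
#'    polynomial baseline, rubberband anchoring, vector normalisation, PCA
#'    outlier screening at spectrum and patient level);
#' 2. draws a class-balanced 80:20 patient-level train/test split;
#' 3. extracts the spectral barcode (per-wavenumber Mann-Whitney tests)
#'    from the training spectra only, reduces each region to its area, and
#'    re-ranks regions by feature-level significance -- or, for
#'    `input = "fingerprint"`, projects the full spectra onto the PCs
#'    retaining 95 percent of the training variance;
#' 4. tunes and trains the classifier (bagged decision trees on barcode
#'    features, or a linear SVM) with patient-grouped cross-validation,
#'    then retrains it with reshuffled folds; and
#' 5. aggregates per-spectrum calls into per-patient classification scores
#'    and evaluates spectrum- and patient-level ROC curves with model
#'    operating points.
#'
#' @param spectra a [spectrum_set()] of replicate spectra.
#' @param patients data.frame with at least `patient_id` and `diagnosis`
#'   ("AD" / "non-AD"); age, sex and ATN biomarkers are carried through for
#'   downstream correlation analysis.
#' @param model "bagged_tree" or "linear_svm".
#' @param input "barcode" (region-area features) or "fingerprint"
#'   (95%-variance PCs of the full spectrum).
#' @param preprocess run the preprocessing pipeline first (set FALSE if
#'   `spectra` are already preprocessed).
#' @param split_ratio training fraction of patients per class.
#' @param alpha,max_gap,min_width barcode extraction settings, see
#'   [extract_regions()].
#' @param pca_variance variance retained for the fingerprint input.
#' @param spec a [model_spec()]; its `kind` is overridden by `model`.
#' @param pre_params a [preprocess_params()] list.
#' @param backgrounds optional background spectra.
#' @param seed master seed; all stage seeds derive from it.
#' @return An object of class `raman_ad` with components `split`,
#'   `barcode`, `features` (training feature table), `fit`, `ensemble`,
#'   `eval` (per-spectrum and per-patient ROC, MOP metrics, SEM), plus the
#'   retained spectra and patient table.
#' @seealso [predict.raman_ad()], [summary.raman_ad()], [plot.raman_ad()]
#' @export
raman_ad <- function(spectra, patients,
                     model = c("bagged_tree", "linear_svm"),
                     input = c("barcode", "fingerprint"),
                     preprocess = TRUE, split_ratio = 0.8,
                     alpha = 0.01, max_gap = 2L, min_width = 3L,
                     pca_variance = 0.95,
                     spec = model_spec(),
                     pre_params = preprocess_params(),
                     backgrounds = NULL, seed = 1L) {
  model <- match.arg(model)
  input <- match.arg(input)
  spec$kind <- model
  stopifnot(inherits(spectra, "spectrum_set"), is.data.frame(patients))

  reports <- NULL
  if (preprocess) {
    pp <- preprocess_pipeline(spectra, backgrounds = backgrounds,
                              params = pre_params)
    spectra <- pp$set
    reports <- pp[c("spectrum_report", "patient_report")]
  }
  patients <- patients[patients$patient_id %in% unique(spectra$patient_id), ,
                       drop = FALSE]

  split <- stratified_split(patients, ratio = split_ratio, seed = seed)
  train_set <- subset_spectra(spectra, patients = split$train_patient_ids)
  test_set <- subset_spectra(spectra, patients = split$test_patient_ids)
  lab_of <- stats::setNames(patients$diagnosis, patients$patient_id)
  y_train <- unname(lab_of[train_set$patient_id])
  y_test <- unname(lab_of[test_set$patient_id])

  barcode <- NULL; features <- NULL; projector <- NULL
  if (input == "barcode") {
    barcode <- build_barcode(train_set, labels = y_train, alpha = alpha,
                             max_gap = max_gap, min_width = min_width)
    if (nrow(barcode$regions) == 0)
      stop_invalid("no significant barcode regions at alpha = ", alpha,
                   "; cannot build features")
    features <- build_feature_table(train_set, barcode)
    barcode <- rank_features(barcode, features, y_train)
    features <- build_feature_table(train_set, barcode)
    X_train <- feature_matrix(features)
    X_test <- feature_matrix(build_feature_table(test_set, barcode))
  } else {
    red <- pca_reduce_fingerprint(train_set, variance = pca_variance)
    projector <- red$projector
    X_train <- red$scores
    X_test <- project_spectra(projector, test_set)
  }

  fit <- train_model(spec, X_train, y_train, train_set$patient_id,
                     seed = seed + 1L)
  ens <- retrain_ensemble(fit, X_train, y_train, train_set$patient_id,
                          seed = seed + 2L)

  eval_rep <- evaluate_ensemble(ens, X_train, y_train, train_set$patient_id,
                                X_test, y_test, test_set$patient_id)

  structure(list(split = split, barcode = barcode, projector = projector,
                 features = features, fit = fit, ensemble = ens,
                 eval = eval_rep, input = input, model = model,
                 spectra = spectra, patients = patients,
                 outlier_reports = reports, seed = seed),
            class = "raman_ad")
}

# average the retrained models' scores/calls and assemble the EvalReport
evaluate_ensemble <- function(ens, X_train, y_train, pid_train,
                              X_test, y_test, pid_test) {
  avg_scores <- function(X) {
    rowMeans(vapply(ens$models, function(m) score_spectra(ens$kind, m, X),
                    numeric(nrow(X))))
  }
  call_frac <- function(X) {
    rowMeans(vapply(ens$models,
                    function(m) call_spectra(ens$kind, m, X) == "AD",
                    logical(nrow(X))))
  }
  one_level <- function(X, y, pid) {
    sc <- avg_scores(X)
    calls <- call_frac(X) >= 0.5  # majority call across retrains
    pscore <- patient_scores(calls, pid)
    plab <- vapply(names(pscore), function(p) y[match(p, pid)], "")
    sp_roc <- roc_with_mop(sc, y)
    pt_roc <- roc_with_mop(pscore, plab)
    metrics <- metrics_table(pscore, plab, pt_roc$mop$threshold)
    list(spectrum_scores = sc, spectrum_calls = calls,
         patient_scores = pscore, patient_labels = plab,
         spectrum_roc = sp_roc, patient_roc = pt_roc, metrics = metrics)
  }
  list(train = one_level(X_train, y_train, pid_train),
       test = one_level(X_test, y_test, pid_test),
       sem_cv_auc = ens$sem, cv_aucs = ens$cv_aucs)
}

#' @export
print.raman_ad <- function(x, ...) {
  cat("CSF Raman AD classifier (", x$model, " on ", x$input,
      " input)\n", sep = "")
  cat("  patients: ", length(x$split$train_patient_ids), " train / ",
      length(x$split$test_patient_ids), " test\n", sep = "")
  if (!is.null(x$barcode))
    cat("  barcode: ", nrow(x$barcode$regions), " regions at alpha = ",
        x$barcode$alpha, "\n", sep = "")
  if (!is.null(x$projector))
    cat("  fingerprint PCs retained: ", ncol(x$projector$rotation), "\n",
        sep = "")
  cat(sprintf("  patient-level AUC: train %.3f / test %.3f\n",
              x$eval$train$patient_roc$auc, x$eval$test$patient_roc$auc))
  invisible(x)
}

#' Summarise a fitted CSF Raman classifier
#'
#' @param object a `raman_ad` fit.
#' @param ... unused.
#' @return Invisibly, a list with the metric tables; printed as a
#'   Table-3-style summary.
#' @export
summary.raman_ad <- function(object, ...) {
  fmt <- function(v) ifelse(is.na(v), "undef", sprintf("%.1f%%", 100 * v))
  lines <- function(lv, name) {
    m <- lv$metrics
    cat(sprintf("  %-6s AUC (spectrum) %.3f | AUC (patient) %.3f\n",
                name, lv$spectrum_roc$auc, lv$patient_roc$auc))
    cat("         accuracy ", fmt(m$accuracy), ", sensitivity ",
        fmt(m$sensitivity), ", specificity ", fmt(m$specificity),
        ",\n         PPV ", fmt(m$ppv), ", NPV ", fmt(m$npv), ", F1 ",
        fmt(m$f1), "\n", sep = "")
  }
  cat("CSF Raman AD classification --", object$model, "on", object$input,
      "input\n")
  lines(object$eval$train, "train")
  lines(object$eval$test, "test")
  cat(sprintf("  CV AUC across %d retrains: %.3f +/- %.3f (SEM)\n",
              length(object$eval$cv_aucs), mean(object$eval$cv_aucs),
              object$eval$sem_cv_auc))
  invisible(list(train = object$eval$train$metrics,
                 test = object$eval$test$metrics,
                 sem_cv_auc = object$eval$sem_cv_auc))
}

#' Predict patient classification scores for new spectra
#'
#' Applies the fitted barcode (or fingerprint projector) and the retrained
#' classifier ensemble to new spectra and returns per-spectrum calls or
#' per-patient classification scores (% of spectra called AD).
#'
#' @param object a `raman_ad` fit.
#' @param newdata a preprocessed [spectrum_set()] on the training axis.
#' @param type "patient" (default) for per-patient scores, "spectrum" for
#'   per-spectrum averaged continuous scores.
#' @param ... unused.
#' @return Named numeric vector.
#' @export
predict.raman_ad <- function(object, newdata, type = c("patient", "spectrum"),
                             ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "spectrum_set"))
  X <- if (object$input == "barcode") {
    feature_matrix(build_feature_table(newdata, object$barcode))
  } else {
    project_spectra(object$projector, newdata)
  }
  ens <- object$ensemble
  if (type == "spectrum") {
    sc <- rowMeans(vapply(ens$models,
                          function(m) score_spectra(ens$kind, m, X),
                          numeric(nrow(X))))
    return(stats::setNames(sc, paste(newdata$patient_id, newdata$replicate)))
  }
  calls <- rowMeans(vapply(ens$models,
                           function(m) call_spectra(ens$kind, m, X) == "AD",
                           logical(nrow(X)))) >= 0.5
  patient_scores(calls, newdata$patient_id)
}

#' Plot ROC curves or the barcode of a fitted classifier
#'
#' @param x a `raman_ad` fit.
#' @param type "roc" (train and test patient-level ROC curves with their
#'   operating points) or "barcode".
#' @param ... passed on to the underlying plot.
#' @export
plot.raman_ad <- function(x, type = c("roc", "barcode"), ...) {
  type <- match.arg(type)
  if (type == "barcode") {
    if (is.null(x$barcode)) stop_invalid("fingerprint fit has no barcode")
    return(plot(x$barcode, ...))
  }
  tr <- x$eval$train$patient_roc; te <- x$eval$test$patient_roc
  graphics::plot(tr$points$fpr, tr$points$sensitivity, type = "s",
                 col = "darkorange", xlab = "1 - specificity",
                 ylab = "sensitivity", xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::lines(te$points$fpr, te$points$sensitivity, type = "s",
                  col = "steelblue")
  graphics::abline(0, 1, lty = 3, col = "grey")
  graphics::points(1 - tr$mop$specificity, tr$mop$sensitivity, pch = 19,
                   col = "darkorange")
  graphics::points(1 - te$mop$specificity, te$mop$sensitivity, pch = 19,
                   col = "steelblue")
  graphics::legend("bottomright", bty = "n",
                   legend = c(sprintf("train AUC %.2f", tr$auc),
                              sprintf("test AUC %.2f", te$auc)),
                   col = c("darkorange", "steelblue"), lwd = 2)
  invisible(x)
}
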