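#' Class-balanced patient-level train/test split
#'
#' Samples, within each diagnosis class, the nearest integer to
#' `ratio x class size` patients into the training set; the remainder form
#' the test set. With 66 AD and 75 non-AD patients at ratio 0.8 this gives
#' 113 training and 28 test patients.
#'
#' @param patients data.frame with `patient_id` and `diagnosis`.
#' @param ratio training fraction (default 0.8).
#' @param seed RNG seed; the same seed reproduces the split.
#' @return A `split_spec`: list with `train_patient_ids`,
#'   `test_patient_ids`, `ratio`, `seed`.
#' @export
stratified_split <- function(patients, ratio = 0.8, seed = 1L) {
  stopifnot(is.data.frame(patients))
  classes <- unique(patients$diagnosis)
  if (length(classes) < 2) stop_invalid("both classes must be present")
  with_seed(seed, {
    train <- character(0)
    for (cls in classes) {
      ids <- patients$patient_id[patients$diagnosis == cls]
      n_train <- round(ratio * length(ids))
      if (n_train < 1 || n_train >= length(ids) + 1)
        stop_invalid("class ", cls, " too small to split at ratio ", ratio)
      train <- c(train, sample(ids, n_train))
    }
    structure(list(train_patient_ids = sort(train),
                   test_patient_ids = sort(setdiff(patients$patient_id, train)),
                   ratio = ratio, seed = seed), class = "split_spec")
  })
}

#' PCA reduction of the full spectral fingerprint
#'
#' Fits PCA on the training spectra and retains the smallest number of
#' components whose cumulative explained variance reaches `variance`
#' (default 95%). The fitted projector is reused verbatim on test spectra.
#'
#' @param train a preprocessed training [spectrum_set()].
#' @param variance fraction of variance to retain, in (0, 1].
#' @return list with `projector` (center + rotation), `k`, `scores` (the
#'   transformed training spectra), `explained`.
#' @export
pca_reduce_fingerprint <- function(train, variance = 0.95) {
  stopifnot(inherits(train, "spectrum_set"))
  if (!is.numeric(variance) || variance <= 0 || variance > 1)
    stop_invalid("`variance` must lie in (0, 1]")
  pc <- stats::prcomp(train$intensities, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  k <- which(cum >= variance - 1e-12)[1]
  projector <- list(center = pc$center,
                    rotation = pc$rotation[, seq_len(k), drop = FALSE])
  list(projector = projector, k = k,
       scores = pc$x[, seq_len(k), drop = FALSE],
       explained = cum[k])
}

#' Apply a fitted fingerprint projector to new spectra
#'
#' @param projector the `projector` element from
#'   [pca_reduce_fingerprint()].
#' @param set a [spectrum_set()] on the same axis.
#' @return Score matrix (one row per spectrum).
#' @export
project_spectra <- function(projector, set) {
  sweep(set$intensities, 2, projector$center) %*% projector$rotation
}

#' Model specification for spectrum-level classifiers
#'
#' @param kind "bagged_tree" (random forest with mtry = all features, i.e.
#'   bootstrap-aggregated trees) or "linear_svm".
#' @param cv_folds cross-validation folds (default 5), grouped by patient.
#' @param tuning_budget number of random-search hyperparameter candidates
#'   (default 20).
#' @param n_retrains refits with reshuffled CV groups for variability
#'   assessment (default 10).
#' @param grouped_cv keep all of a patient's spectra in one fold (default
#'   TRUE; set FALSE to allow replicate leakage between folds).
#' @param class_weights optional named misclassification weights
#'   `c(AD = , "non-AD" = )`; default equal.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(kind = c("bagged_tree", "linear_svm"), cv_folds = 5L,
                       tuning_budget = 20L, n_retrains = 10L,
                       grouped_cv = TRUE, class_weights = NULL) {
  kind <- match.arg(kind)
  if (cv_folds < 2) stop_invalid("need >= 2 CV folds")
  structure(list(kind = kind, cv_folds = as.integer(cv_folds),
                 tuning_budget = as.integer(tuning_budget),
                 n_retrains = as.integer(n_retrains),
                 grouped_cv = isTRUE(grouped_cv),
                 class_weights = class_weights), class = "model_spec")
}

# fold id per row; grouped by patient when requested
make_folds <- function(patient_id, y, k, grouped) {
  n <- length(patient_id)
  if (grouped) {
    ids <- unique(patient_id)
    fold_of_id <- stats::setNames(sample(rep_len(seq_len(k), length(ids))),
                                  sample(ids))
    unname(fold_of_id[patient_id])
  } else {
    sample(rep_len(seq_len(k), n))
  }
}

random_grid <- function(kind, budget) {
  if (kind == "bagged_tree") {
    data.frame(ntree = sample(c(100L, 200L, 300L), budget, replace = TRUE),
               maxnodes = sample(c(8L, 16L, 32L, 64L, 128L), budget,
                                 replace = TRUE),
               nodesize = sample(c(1L, 5L, 10L), budget, replace = TRUE))
  } else {
    data.frame(cost = 10^stats::runif(budget, -3, 2))
  }
}

fit_one <- function(kind, X, y, par, class_weights = NULL) {
  if (kind == "bagged_tree") {
    cw <- if (is.null(class_weights)) NULL else class_weights[levels(y)]
    randomForest::randomForest(
      x = X, y = y, mtry = ncol(X), ntree = par$ntree,
      maxnodes = min(par$maxnodes, nrow(X)), nodesize = par$nodesize,
      classwt = cw)
  } else {
    cw <- if (is.null(class_weights)) NULL else class_weights[levels(y)]
    e1071::svm(x = X, y = y, kernel = "linear", cost = par$cost,
               class.weights = cw, scale = TRUE)
  }
}

# continuous AD score per spectrum (probability for trees, decision value
# for the SVM, oriented so larger = more AD-like)
score_spectra <- function(kind, model, X) {
  if (kind == "bagged_tree") {
    as.numeric(stats::predict(model, X, type = "prob")[, "AD"])
  } else {
    d <- attr(stats::predict(model, X, decision.values = TRUE),
              "decision.values")
    s <- as.numeric(d)
    if (!grepl("^AD", colnames(d)[1])) s <- -s
    s
  }
}

# hard AD/non-AD call per spectrum at the model's default threshold
call_spectra <- function(kind, model, X) {
  as.character(stats::predict(model, X))
}

cv_auc <- function(kind, X, y, patient_id, par, spec) {
  folds <- make_folds(patient_id, y, spec$cv_folds, spec$grouped_cv)
  scores <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) return(NA_real_)
    m <- fit_one(kind, X[tr, , drop = FALSE], y[tr], par, spec$class_weights)
    scores[folds == f] <- score_spectra(kind, m, X[folds == f, , drop = FALSE])
  }
  roc_with_mop(scores, y == "AD")$auc
}

#' Train a spectrum-level classifier with grouped cross-validation
#'
#' Runs a seeded random search of `tuning_budget` hyperparameter candidates,
#' scoring each by patient-grouped `cv_folds`-fold cross-validated AUC, then
#' refits the best candidate on the full training data.
#'
#' @param spec a [model_spec()].
#' @param X numeric feature matrix (one row per spectrum).
#' @param y class labels per spectrum ("AD" / "non-AD").
#' @param patient_id patient identity per spectrum (for grouped folds).
#' @param seed RNG seed.
#' @return A `spectral_classifier`: list with the fitted `model`,
#'   `best_params`, `cv_auc`, and the spec.
#' @export
train_model <- function(spec, X, y, patient_id, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  y <- factor(as.character(y), levels = c("non-AD", "AD"))
  if (any(table(y) < spec$cv_folds))
    stop_invalid("need >= cv_folds spectra per class")
  with_seed(seed, {
    grid <- random_grid(spec$kind, spec$tuning_budget)
    aucs <- vapply(seq_len(nrow(grid)), function(i) {
      cv_auc(spec$kind, X, y, patient_id, grid[i, , drop = FALSE], spec)
    }, 0)
    best <- which.max(aucs)
    model <- fit_one(spec$kind, X, y, grid[best, , drop = FALSE],
                     spec$class_weights)
    structure(list(kind = spec$kind, model = model,
                   best_params = grid[best, , drop = FALSE],
                   cv_auc = aucs[best], search = cbind(grid, cv_auc = aucs),
                   spec = spec),
              class = "spectral_classifier")
  })
}

#' Retrain a tuned classifier with reshuffled CV groups
#'
#' Refits the best hyperparameters `n_retrains` times, each time with a
#' fresh shuffle of the cross-validation groups, recording the CV AUC of
#' each retrain; variability is summarised as the standard error of the
#' mean (SEM = SD / sqrt(n_retrains)). The retrained models are kept so
#' evaluation can average their test scores.
#'
#' @param fit a `spectral_classifier` from [train_model()].
#' @param X,y,patient_id the training data, as in [train_model()].
#' @param seed RNG seed.
#' @return list with `models`, `cv_aucs`, `sem`, `kind`, `best_params`.
#' @export
retrain_ensemble <- function(fit, X, y, patient_id, seed = 1L) {
  stopifnot(inherits(fit, "spectral_classifier"))
  X <- as.matrix(X)
  y <- factor(as.character(y), levels = c("non-AD", "AD"))
  spec <- fit$spec
  with_seed(seed, {
    models <- vector("list", spec$n_retrains)
    aucs <- numeric(spec$n_retrains)
    for (i in seq_len(spec$n_retrains)) {
      aucs[i] <- cv_auc(fit$kind, X, y, patient_id, fit$best_params, spec)
      models[[i]] <- fit_one(fit$kind, X, y, fit$best_params,
                             spec$class_weights)
    }
    list(models = models, cv_aucs = aucs,
         sem = stats::sd(aucs) / sqrt(spec$n_retrains),
         kind = fit$kind, best_params = fit$best_params)
  })
}

#' Per-patient classification score from spectrum-level calls
#'
#' The classification score of a patient is the percentage of that
#' patient's replicate spectra called AD.
#'
#' @param calls character (or logical) vector of per-spectrum calls; "AD" /
#'   TRUE counts as an AD call.
#' @param patient_id patient identity per spectrum.
#' @return Named numeric vector of scores in [0, 100], one per patient (in
#'   order of first appearance).
#' @export
patient_scores <- function(calls, patient_id) {
  if (length(calls) != length(patient_id))
    stop_invalid("one call per spectrum required")
  if (anyNA(patient_id)) stop_invalid("unmapped spectrum (NA patient id)")
  is_ad <- if (is.logical(calls)) calls else calls == "AD"
  ids <- unique(patient_id)
  out <- vapply(ids, function(p) 100 * mean(is_ad[patient_id == p]), 0)
  stats::setNames(out, ids)
}

#' Empirical ROC curve with AUC and model operating point
#'
#' Computes the empirical ROC over all distinct score thresholds, the area
#' under it by the trapezoid rule, and the model operating point (MOP): the
#' threshold maximising Youden's J = sensitivity + specificity - 1, with
#' ties resolved toward higher specificity.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels logical (TRUE = positive) or "AD"/"non-AD" labels.
#' @return list with `points` (threshold, sensitivity, specificity, fpr),
#'   `auc`, and `mop`.
#' @export
roc_with_mop <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) == "AD"
  y <- as.logical(labels)
  if (anyNA(scores) || anyNA(y)) stop_invalid("scores/labels contain NA")
  if (all(y) || !any(y)) stop_invalid("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[y] >= t), 0)
  spec <- vapply(thr, function(t) mean(scores[!y] < t), 0)
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  j <- sens + spec - 1
  best <- which(j > max(j) - 1e-12)
  best <- best[which.max(spec[best])]
  list(points = data.frame(threshold = thr, sensitivity = sens,
                           specificity = spec, fpr = fpr),
       auc = auc,
       mop = list(threshold = thr[best], sensitivity = sens[best],
                  specificity = spec[best]))
}

#' Confusion-matrix metrics at a threshold
#'
#' Computes accuracy, sensitivity, specificity, PPV, NPV, F1 and AUROC for
#' scores dichotomised at `threshold` (score >= threshold called positive).
#' Cells with zero denominators yield `NA` with an explanatory attribute
#' rather than propagating NaN.
#'
#' @param scores numeric scores.
#' @param labels logical or "AD"/"non-AD" labels.
#' @param threshold decision threshold (e.g. the MOP threshold).
#' @return Named list of metrics (fractions in [0, 1]).
#' @export
metrics_table <- function(scores, labels, threshold) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) == "AD"
  y <- as.logical(labels)
  pred <- scores >= threshold
  tp <- sum(pred & y); fp <- sum(pred & !y)
  tn <- sum(!pred & !y); fn <- sum(!pred & y)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  ppv <- safe_div(tp, tp + fp)
  npv <- safe_div(tn, tn + fn)
  f1 <- if (is.na(ppv) || is.na(sens) || (ppv + sens) == 0) NA_real_
        else 2 * ppv * sens / (ppv + sens)
  out <- list(accuracy = (tp + tn) / length(y), sensitivity = sens,
              specificity = spec, ppv = ppv, npv = npv, f1 = f1,
              auroc = if (all(y) || !any(y)) NA_real_
                      else roc_with_mop(scores, y)$auc,
              confusion = c(tp = tp, fp = fp, tn = tn, fn = fn))
  undef <- names(out)[vapply(out[1:7], function(v) is.na(v[1]), TRUE)]
  if (length(undef)) attr(out, "undefined") <- undef
  out
}
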