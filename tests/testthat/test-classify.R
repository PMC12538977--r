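make_patients <- function(n_ad, n_non) {
  data.frame(patient_id = sprintf("P%03d", seq_len(n_ad + n_non)),
             diagnosis = c(rep("AD", n_ad), rep("non-AD", n_non)),
             stringsAsFactors = FALSE)
}

test_that("stratified split follows nearest-integer class arithmetic", {
  p <- make_patients(66, 75)
  s <- stratified_split(p, 0.8, seed = 3)
  expect_length(s$train_patient_ids, 113)
  expect_length(s$test_patient_ids, 28)
  tr_diag <- p$diagnosis[match(s$train_patient_ids, p$patient_id)]
  expect_equal(sum(tr_diag == "AD"), 53)
  expect_equal(sum(tr_diag == "non-AD"), 60)
  expect_length(intersect(s$train_patient_ids, s$test_patient_ids), 0)
  expect_setequal(c(s$train_patient_ids, s$test_patient_ids), p$patient_id)

  s2 <- stratified_split(make_patients(10, 10), 0.8, seed = 1)
  expect_length(s2$train_patient_ids, 16)
  expect_length(s2$test_patient_ids, 4)

  expect_identical(stratified_split(p, 0.8, seed = 9),
                   stratified_split(p, 0.8, seed = 9))
  expect_error(stratified_split(make_patients(3, 0), 0.8, 1), "classes")
})

test_that("fingerprint PCA retains the requested variance", {
  set.seed(6)
  # rank-3 data: 3 latent factors
  L <- matrix(rnorm(3 * 50), 3, 50)
  W <- matrix(rnorm(40 * 3), 40, 3)
  s <- spectrum_set(W %*% L, 1:50, paste0("P", 1:40), rep(1L, 40))
  red <- pca_reduce_fingerprint(s, 0.95)
  expect_equal(red$k, 3)
  expect_gt(red$explained, 0.95 - 1e-12)

  red_all <- pca_reduce_fingerprint(s, 1.0)
  expect_lte(red_all$k, min(39, 50))
  expect_error(pca_reduce_fingerprint(s, 1.2), "variance")

  # projector applies identically to the training data
  expect_equal(project_spectra(red$projector, s), red$scores,
               tolerance = 1e-10)
})

test_that("patient scores are the percentage of AD calls", {
  calls <- c(rep("AD", 24), rep("non-AD", 6))
  expect_equal(unname(patient_scores(calls, rep("P1", 30))), 80)
  expect_equal(unname(patient_scores(rep("non-AD", 10), rep("P1", 10))), 0)
  expect_equal(unname(patient_scores(rep("AD", 10), rep("P1", 10))), 100)
  sc <- patient_scores(c("AD", "non-AD", "AD", "AD"),
                       c("P1", "P1", "P2", "P2"))
  expect_equal(sc, c(P1 = 50, P2 = 100))
  expect_error(patient_scores("AD", c("P1", NA)), "one call")
})

test_that("ROC, AUC and MOP match known values and oracles", {
  r1 <- roc_with_mop(c(.9, .8, .7, .1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r1$auc, 1.0)
  r2 <- roc_with_mop(c(.9, .8, .7, .1), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(r2$auc, 0.75)
  expect_error(roc_with_mop(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  # concordance-counting oracle on random small inputs
  set.seed(33)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(y) || !any(y)) next
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    expect_equal(roc_with_mop(sc, y)$auc, auc_concordance_oracle(sc, y),
                 tolerance = 1e-12)
  }

  # cross-check against pROC
  skip_if_not_installed("pROC")
  set.seed(34)
  y <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  sc <- rnorm(40) + y
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(y, sc))))
  expect_equal(roc_with_mop(sc, y)$auc, ref, tolerance = 1e-10)

  # MOP maximises Youden J
  r <- roc_with_mop(sc, y)
  j <- r$points$sensitivity + r$points$specificity - 1
  expect_equal(r$mop$sensitivity + r$mop$specificity - 1, max(j))
})

test_that("random-label AUC concentrates around one half", {
  set.seed(35)
  aucs <- replicate(100, {
    sc <- rnorm(60)
    y <- sample(rep(c(TRUE, FALSE), 30))
    roc_with_mop(sc, y)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("metrics table reproduces confusion-matrix arithmetic", {
  # TP=12 FP=1 TN=13 FN=2 at threshold 0.5
  scores <- c(rep(.9, 12), rep(.1, 2), rep(.9, 1), rep(.1, 13))
  labels <- c(rep(TRUE, 14), rep(FALSE, 14))
  m <- metrics_table(scores, labels, 0.5)
  expect_equal(m$sensitivity, 12 / 14)
  expect_equal(m$specificity, 13 / 14)
  expect_equal(m$ppv, 12 / 13)
  expect_equal(m$npv, 13 / 15)
  expect_equal(m$accuracy, 25 / 28)

  mp <- metrics_table(c(1, 1), c(TRUE, TRUE), 0.5)
  expect_equal(mp$accuracy, 1)

  # all called positive: NPV undefined, flagged rather than NaN
  ma <- metrics_table(c(.9, .9, .9, .8), c(TRUE, TRUE, FALSE, TRUE), 0.5)
  expect_true(is.na(ma$npv))
  expect_true("npv" %in% attr(ma, "undefined"))
})

test_that("grouped CV never lets a patient span folds, and training is seeded", {
  set.seed(40)
  n_pat <- 20
  pid <- rep(sprintf("P%02d", 1:n_pat), each = 5)
  y <- rep(rep(c("AD", "non-AD"), each = 10), each = 5)
  X <- matrix(rnorm(length(pid) * 3), ncol = 3)
  X[y == "AD", 1] <- X[y == "AD", 1] + 2
  colnames(X) <- paste0("feature_", 1:3)

  folds <- with_seed <- NULL
  # direct check of the fold maker through many draws
  for (i in 1:10) {
    set.seed(i)
    f <- ramanAD:::make_folds(pid, y, 5, grouped = TRUE)
    expect_true(all(tapply(f, pid, function(v) length(unique(v))) == 1))
  }

  spec <- model_spec("bagged_tree", tuning_budget = 3L, n_retrains = 3L)
  f1 <- train_model(spec, X, y, pid, seed = 5)
  f2 <- train_model(spec, X, y, pid, seed = 5)
  expect_equal(f1$best_params, f2$best_params)
  expect_equal(f1$cv_auc, f2$cv_auc)
  expect_gt(f1$cv_auc, 0.8)
})

test_that("bagged trees are invariant to feature rescaling", {
  set.seed(41)
  pid <- rep(sprintf("P%02d", 1:16), each = 4)
  y <- rep(rep(c("AD", "non-AD"), each = 8), each = 4)
  X <- matrix(rnorm(64 * 4), 64, 4)
  X[y == "AD", 2] <- X[y == "AD", 2] + 1.5
  colnames(X) <- paste0("feature_", 1:4)
  spec <- model_spec("bagged_tree", tuning_budget = 2L)
  f <- train_model(spec, X, y, pid, seed = 2)
  p1 <- ramanAD:::score_spectra("bagged_tree", f$model, X)
  p2 <- ramanAD:::score_spectra("bagged_tree", f$model,
                                sweep(X, 2, c(2, 2, 2, 2), `*`) / 2)
  expect_equal(p1, p2)
})

test_that("retrain ensemble reports SEM and bounded patient scores", {
  set.seed(42)
  pid <- rep(sprintf("P%02d", 1:20), each = 4)
  y <- rep(rep(c("AD", "non-AD"), each = 10), each = 4)
  X <- matrix(rnorm(80 * 3), 80, 3)
  X[y == "AD", 1] <- X[y == "AD", 1] + 10   # perfectly separable
  colnames(X) <- paste0("feature_", 1:3)
  spec <- model_spec("bagged_tree", tuning_budget = 2L, n_retrains = 4L)
  fit <- train_model(spec, X, y, pid, seed = 1)
  ens <- retrain_ensemble(fit, X, y, pid, seed = 2)
  expect_length(ens$cv_aucs, 4)
  expect_equal(ens$sem, sd(ens$cv_aucs) / 2)
  expect_equal(ens$cv_aucs, rep(1, 4))      # perfect separation: SEM = 0
  expect_equal(ens$sem, 0)

  calls <- ramanAD:::call_spectra("bagged_tree", ens$models[[1]], X)
  ps <- patient_scores(calls, pid)
  expect_true(all(ps >= 0 & ps <= 100))
})

test_that("the linear SVM path trains and scores coherently", {
  set.seed(43)
  pid <- rep(sprintf("P%02d", 1:20), each = 4)
  y <- rep(rep(c("AD", "non-AD"), each = 10), each = 4)
  X <- matrix(rnorm(80 * 5), 80, 5)
  X[y == "AD", 3] <- X[y == "AD", 3] + 2
  colnames(X) <- paste0("feature_", 1:5)
  spec <- model_spec("linear_svm", tuning_budget = 4L, n_retrains = 2L)
  fit <- train_model(spec, X, y, pid, seed = 3)
  sc <- ramanAD:::score_spectra("linear_svm", fit$model, X)
  # scores oriented so AD spectra sit higher
  expect_gt(mean(sc[y == "AD"]), mean(sc[y != "AD"]))
  expect_gt(roc_with_mop(sc, y == "AD")$auc, 0.85)
})
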