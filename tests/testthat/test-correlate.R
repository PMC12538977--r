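test_that("PLM scoring applies the three biomarker cutoffs", {
  p <- data.frame(abeta42 = c(500, 900, 500, 500),
                  ptau = c(60, 40, 40, 60),
                  total_tau = c(400, 300, 300, NA))
  s <- plm_score(p)
  expect_equal(s$plm, c(3, 0, 1, NA))
  expect_equal(s$A, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(s$T, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(s$N[1:3], c(TRUE, FALSE, FALSE))
  # boundary values are not positive (strict inequalities)
  sb <- plm_score(data.frame(abeta42 = 680, ptau = 56, total_tau = 355))
  expect_equal(sb$plm, 0)
})

test_that("partial correlation matches the worked fixture and the precision-matrix oracle", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5)
  # ages must not be collinear with x or the partial r is undefined
  covs <- data.frame(age = c(50, 53, 51, 55, 52, 54),
                     sex = c(0, 1, 0, 1, 0, 1))
  got <- partial_correlation(x, y, covs)
  # residual-regression oracle via the formula interface
  rx <- residuals(lm(x ~ age + sex, data = covs))
  ry <- residuals(lm(y ~ age + sex, data = covs))
  expect_equal(got$r, cor(rx, ry), tolerance = 1e-10)
  # in this fixture y = x + 1 - 2 sex, so the adjusted correlation is exact
  expect_equal(got$r, 1, tolerance = 1e-10)

  set.seed(60)
  for (i in 1:30) {
    n <- sample(10:40, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.5 * x
    covs <- data.frame(age = rnorm(n, 60, 8), sex = rbinom(n, 1, 0.5))
    if (length(unique(covs$sex)) < 2) next
    got <- partial_correlation(x, y, covs)
    expect_equal(got$r, pcor_precision_oracle(x, y, covs), tolerance = 1e-10)
    expect_equal(got$df, n - 4)
  }
})

test_that("partial correlation edge cases behave as specified", {
  set.seed(61)
  x <- rnorm(30); y <- 0.7 * x + rnorm(30, 0, 0.3)
  # no covariates: exactly Pearson, including p-value
  got <- partial_correlation(x, y)
  ref <- cor.test(x, y)
  expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)

  # orthogonal covariates leave r unchanged
  covs <- data.frame(c1 = rep(c(-1, 1), 15))
  xo <- x - mean(x); yo <- y - mean(y)
  xo <- xo - covs$c1 * sum(xo * covs$c1) / sum(covs$c1^2)
  yo <- yo - covs$c1 * sum(yo * covs$c1) / sum(covs$c1^2)
  expect_equal(partial_correlation(xo, yo, covs)$r, cor(xo, yo),
               tolerance = 1e-12)

  # y = x gives r = 1
  expect_equal(partial_correlation(x, x, data.frame(a = rnorm(30)))$r, 1,
               tolerance = 1e-10)
  # collinear covariates fail loudly
  expect_error(partial_correlation(x, y,
                                   data.frame(a = 1:30, b = 2 * (1:30))),
               "collinear")
  # zero residual variance: undefined r
  expect_true(is.na(partial_correlation(rep(1, 30), y)$r))
})

test_that("log base does not change correlations and sex coding is immaterial", {
  set.seed(62)
  conc <- exp(rnorm(40, 5, 0.5))
  x <- rnorm(40) + 0.3 * log(conc)
  covs1 <- data.frame(age = rnorm(40, 65), sex = rbinom(40, 1, 0.5))
  covs2 <- covs1; covs2$sex <- 1 - covs2$sex
  r_ln <- partial_correlation(x, log(conc), covs1)$r
  r_l10 <- partial_correlation(x, log10(conc), covs1)$r
  expect_equal(r_ln, r_l10, tolerance = 1e-12)
  expect_equal(partial_correlation(x, log(conc), covs2)$r, r_ln,
               tolerance = 1e-12)
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(63)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    # monotone in raw ranks
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
})

test_that("correlation matrix has the right family structure and exclusions", {
  co <- simulate_cohort(synth_config(n_per_class = c(40L, 40L),
                                     spectra_per_patient = 2L, seed = 64))
  regions <- default_effect_regions()
  tab <- build_feature_table(co$spectra, regions)
  cm <- correlation_matrix(tab, co$patients)
  expect_equal(nrow(cm), 30)      # 10 features x 3 biomarkers, one family
  expect_equal(length(unique(cm$feature)), 10)
  expect_true(all(cm$p_adj >= cm$p_raw - 1e-12))
  # missing total tau shrinks n in that column only
  n_tt <- unique(cm$n[cm$biomarker == "total_tau"])
  n_pt <- unique(cm$n[cm$biomarker == "ptau"])
  expect_equal(n_pt, 80)
  expect_equal(n_tt, 80 - sum(is.na(co$patients$total_tau)))
})

test_that("coupled features are detected and shuffled biomarkers are not", {
  set.seed(65)
  hits_coupled <- fp_shuffled <- numeric(20)
  for (i in 1:20) {
    co <- simulate_cohort(synth_config(n_per_class = c(50L, 50L),
                                       spectra_per_patient = 3L,
                                       seed = 100 + i))
    pp <- preprocess_pipeline(co$spectra,
                              params = preprocess_params(
                                spectrum_level = FALSE,
                                patient_level = FALSE))
    tab <- build_feature_table(pp$set, default_effect_regions())
    cm <- correlation_matrix(tab, co$patients)
    # feature areas are severity-coupled through the injected effects, and
    # biomarkers are severity-coupled too: expect detections
    hits_coupled[i] <- sum(cm$significant)
    shuffled <- co$patients
    shuffled[c("abeta42", "ptau", "total_tau")] <-
      shuffled[sample(nrow(shuffled)), c("abeta42", "ptau", "total_tau")]
    cm0 <- correlation_matrix(tab, shuffled)
    fp_shuffled[i] <- sum(cm0$significant)
  }
  expect_gt(mean(hits_coupled > 0), 0.8)
  expect_lt(mean(fp_shuffled), 1)
})

test_that("classifier-score PLM correlations form their own FDR family", {
  co <- simulate_cohort(synth_config(n_per_class = c(30L, 30L),
                                     spectra_per_patient = 2L, seed = 66,
                                     missing_ttau_fraction = 0))
  tab <- build_feature_table(co$spectra, default_effect_regions())
  agg <- ramanAD:::aggregate_features(tab)
  vals <- lapply(agg[grep("^feature_", names(agg))],
                 function(v) setNames(v, agg$patient_id))
  pc <- plm_correlations(vals, co$patients)
  expect_equal(nrow(pc), 10)
  expect_true(all(pc$r >= -1 & pc$r <= 1))
  expect_true(all(pc$p_adj >= pc$p_raw - 1e-12))
})
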