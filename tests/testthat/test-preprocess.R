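test_that("background subtraction removes the pointwise mean of backgrounds", {
  s <- tiny_set(c(4, 4))
  bg <- rbind(c(2, 2), c(4, 4), c(6, 6))
  expect_equal(subtract_background(s, bg)$intensities[1, ], c(0, 0))
  expect_equal(subtract_background(s, rbind(c(0, 0)))$intensities[1, ],
               c(4, 4))
  expect_equal(subtract_background(s, rbind(c(4, 4)))$intensities[1, ],
               c(0, 0))
  expect_error(subtract_background(s, rbind(c(1, 2, 3))), "axis")
})

test_that("spike filter replaces isolated spikes and passes smooth input", {
  x <- seq(0, 1, length.out = 101)
  smooth <- sin(2 * pi * x) + 2
  s <- tiny_set(smooth, axis = seq_len(101))
  expect_equal(remove_spikes(s)$intensities[1, ], smooth)
  expect_equal(remove_spikes(tiny_set(rep(3, 50)))$intensities[1, ],
               rep(3, 50))

  spiked <- smooth
  spiked[40] <- 100 * spiked[40]
  out <- remove_spikes(tiny_set(spiked, axis = seq_len(101)))$intensities[1, ]
  med <- stats::runmed(spiked, 7, endrule = "median")
  expect_equal(out[40], med[40])              # replaced by the local median
  expect_equal(out[-40], spiked[-40])         # neighbours untouched
  expect_error(remove_spikes(s, window = 4), "odd")
})

test_that("wavelet denoising is identity on constants and shrinks white noise", {
  s <- tiny_set(rep(2.5, 128))
  expect_equal(denoise_wavelet(s, 6)$intensities[1, ], rep(2.5, 128),
               tolerance = 1e-12)
  expect_error(denoise_wavelet(tiny_set(rep(1, 16)), 6), "short")

  set.seed(11)
  sds <- replicate(100, {
    y <- rnorm(256, 0, 1)
    sd(denoise_wavelet(tiny_set(y), 6)$intensities[1, ])
  })
  expect_true(all(sds < 1))
  expect_lt(mean(sds), 0.5)
})

test_that("denoising improves RMSE to a known clean signal", {
  ax <- make_axis(512, 659, 1761)
  clean <- lorentzian_sig <- exp(-0.5 * ((ax - 1100) / 30)^2) +
    0.6 * exp(-0.5 * ((ax - 1400) / 20)^2)
  set.seed(22)
  rmse_before <- rmse_after <- numeric(20)
  for (i in 1:20) {
    noisy <- clean + rnorm(512, 0, 0.1)
    den <- denoise_wavelet(tiny_set(noisy, axis = ax), 6)$intensities[1, ]
    rmse_before[i] <- sqrt(mean((noisy - clean)^2))
    rmse_after[i] <- sqrt(mean((den - clean)^2))
  }
  expect_lt(mean(rmse_after), mean(rmse_before))
})

test_that("polynomial baseline removal annihilates low-order polynomials", {
  ax <- make_axis(200, 659, 1761)
  x <- (ax - mean(ax)) / sd(ax)
  for (ord in 0:5) {
    y <- rowSums(outer(x, 0:ord, `^`))
    out <- subtract_poly_baseline(tiny_set(y, axis = ax), 5)$intensities[1, ]
    expect_lt(max(abs(out)), 1e-8 * max(abs(y), 1))
  }
  expect_equal(subtract_poly_baseline(tiny_set(rep(7, 50)))$intensities[1, ],
               rep(0, 50), tolerance = 1e-12)
})

test_that("baseline fit preserves a narrow peak on a polynomial background", {
  ax <- make_axis(400, 659, 1761)
  xs <- 2 * (ax - ax[1]) / (ax[length(ax)] - ax[1]) - 1
  baseline <- 2 + 0.5 * xs - 0.3 * xs^3 + 0.1 * xs^5
  peak <- exp(-0.5 * ((ax - 1003) / 3)^2)
  out <- subtract_poly_baseline(tiny_set(baseline + peak, axis = ax),
                                5)$intensities[1, ]
  # direct least-squares oracle on the same basis
  X <- cbind(1, stats::poly(ax, 5))
  oracle <- (baseline + peak) - X %*% qr.solve(X, baseline + peak)
  expect_equal(out, as.numeric(oracle), tolerance = 1e-9)
  # the peak height survives within the fit's leverage
  expect_gt(max(out[abs(ax - 1003) < 5]), 0.8 * max(peak))
})

test_that("rubberband anchoring zeroes the end channels", {
  expect_equal(rubberband_anchor(tiny_set(c(1, 5, 3),
                                          axis = c(0, 1, 2)))$intensities[1, ],
               c(0, 3, 0))
  lin <- tiny_set(2 + 3 * (1:50), axis = 1:50)
  expect_equal(rubberband_anchor(lin)$intensities[1, ], rep(0, 50),
               tolerance = 1e-12)
  set.seed(1)
  rnd <- tiny_set(rnorm(64), axis = 1:64)
  out <- rubberband_anchor(rnd)$intensities[1, ]
  expect_equal(out[c(1, 64)], c(0, 0))
  # convex hull mode: baseline lies at or below the spectrum, ends at zero
  outh <- rubberband_anchor(rnd, convex_hull = TRUE)$intensities[1, ]
  expect_true(all(outh >= -1e-12))
  expect_equal(outh[c(1, 64)], c(0, 0), tolerance = 1e-12)
})

test_that("vector normalisation yields unit norm and is idempotent", {
  expect_equal(vector_normalize(tiny_set(c(3, 4)))$intensities[1, ],
               c(0.6, 0.8))
  set.seed(2)
  s <- tiny_set(matrix(rnorm(5 * 30), 5))
  v1 <- vector_normalize(s)
  expect_equal(unname(sqrt(rowSums(v1$intensities^2))), rep(1, 5),
               tolerance = 1e-12)
  v2 <- vector_normalize(v1)
  expect_equal(v2$intensities, v1$intensities, tolerance = 1e-12)
  expect_error(vector_normalize(tiny_set(rep(0, 10))), "zero")
})

test_that("spectrum-level outlier screen flags a single deviant replicate", {
  base <- sin(seq(0, 6, length.out = 100)) + 2
  Y <- matrix(rep(base, 30), 30, byrow = TRUE)
  set.seed(5)
  Y <- Y + matrix(rnorm(3000, 0, 0.01), 30)
  Y[17, ] <- Y[17, ] + 0.5 * exp(-0.5 * ((1:100 - 50) / 10)^2)
  s <- spectrum_set(Y, 1:100, rep("P1", 30), 1:30)
  rep_ <- pca_outliers_spectra(s, 3, 3)
  expect_true("P1 17" %in% rep_$removed_keys)
  expect_lte(length(rep_$removed_keys), 2)

  # 29 identical replicates + 1 deviant: exactly that one flagged
  Yd <- matrix(rep(base, 30), 30, byrow = TRUE)
  Yd[7, ] <- Yd[7, ] + 0.5 * exp(-0.5 * ((1:100 - 30) / 8)^2)
  sd_ <- spectrum_set(Yd, 1:100, rep("P1", 30), 1:30)
  expect_equal(pca_outliers_spectra(sd_, 3, 3)$removed_keys, "P1 7")

  # identical replicates: nothing flagged
  Yc <- matrix(rep(base, 10), 10, byrow = TRUE)
  sc <- spectrum_set(Yc, 1:100, rep("P1", 10), 1:10)
  expect_length(pca_outliers_spectra(sc, 3, 3)$removed_keys, 0)
  # infinite threshold: empty report
  expect_length(pca_outliers_spectra(s, 3, Inf)$removed_keys, 0)
})

test_that("patient-level screen flags contaminated patients, invariant to order", {
  co <- simulate_cohort(small_cfg(n_per_class = c(15L, 15L), seed = 8))
  cont <- inject_contamination(co$spectra, c("P004", "P022"), 0.5)
  pp <- vector_normalize(rubberband_anchor(subtract_poly_baseline(
    remove_spikes(cont))))
  rep1 <- pca_outliers_patients(pp, 3, 3)
  expect_setequal(rep1$removed_patient_ids, c("P004", "P022"))

  # permutation invariance
  set.seed(99)
  perm <- sample(n_spectra(pp))
  pp2 <- subset_spectra(pp, idx = perm)
  rep2 <- pca_outliers_patients(pp2, 3, 3)
  expect_setequal(rep2$removed_patient_ids, rep1$removed_patient_ids)

  expect_error(pca_outliers_patients(subset_spectra(pp, patients = "P004"),
                                     3, 3), "3 patients")
})

test_that("full pipeline output has unit norm and anchored ends", {
  co <- simulate_cohort(small_cfg(seed = 13))
  pp <- preprocess_pipeline(co$spectra)
  Y <- pp$set$intensities
  expect_equal(unname(sqrt(rowSums(Y^2))), rep(1, nrow(Y)), tolerance = 1e-9)
  expect_equal(unname(Y[, 1]), rep(0, nrow(Y)), tolerance = 1e-9)
  expect_equal(unname(Y[, ncol(Y)]), rep(0, nrow(Y)), tolerance = 1e-9)
  expect_true(length(pp$set$steps) >= 5)
})

test_that("replaying the provenance log reproduces the processed set exactly", {
  co <- simulate_cohort(small_cfg(seed = 21, n_per_class = 4L))
  pp <- preprocess_pipeline(co$spectra)
  replayed <- replay_steps(co$spectra, pp$set$steps)
  expect_identical(replayed$intensities, pp$set$intensities)
  expect_identical(replayed$patient_id, pp$set$patient_id)
})

test_that("noise-free flat-baseline input reduces to the normalised template", {
  cfg <- clean_cfg()
  co <- simulate_cohort(cfg)
  pp <- preprocess_pipeline(co$spectra,
                            params = preprocess_params(spectrum_level = FALSE,
                                                       patient_level = FALSE))
  tmpl <- class_templates(cfg)$base
  # template after the same deterministic corrections, normalised
  ts <- tiny_set(tmpl, axis = tmpl_axis <- class_templates(cfg)$axis)
  ref <- vector_normalize(rubberband_anchor(subtract_poly_baseline(
    denoise_wavelet(remove_spikes(ts)))))$intensities[1, ]
  expect_equal(unname(pp$set$intensities[1, ]), unname(ref), tolerance = 1e-8)
})
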