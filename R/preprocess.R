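#' Subtract averaged background spectra
#'
#' Subtracts the pointwise mean of three (or more) substrate background
#' spectra from every spectrum in the set, as done against the aluminium
#' slide background in droplet-deposition measurements.
#'
#' @param set a [spectrum_set()].
#' @param backgrounds a `spectrum_set` or numeric matrix of background
#'   spectra on the same axis (one per row).
#' @return The background-subtracted `spectrum_set`.
#' @export
subtract_background <- function(set, backgrounds) {
  stopifnot(inherits(set, "spectrum_set"))
  B <- if (inherits(backgrounds, "spectrum_set")) {
    if (max(abs(backgrounds$axis - set$axis)) > 1e-9)
      stop_invalid("background axis does not match spectra axis")
    backgrounds$intensities
  } else as.matrix(backgrounds)
  if (ncol(B) != length(set$axis))
    stop_invalid("background length does not match axis")
  bmean <- colMeans(B)
  out <- set_intensities(set, sweep(set$intensities, 2, bmean))
  log_step(out, "subtract_background", list(backgrounds = B))
}

#' Remove cosmic-ray spikes by rolling-median filtering
#'
#' Channels whose modified z-score against a rolling median exceeds
#' `z_thresh` are replaced by the local median; everything else passes
#' through bit-identically. An automated replacement for interactive
#' "zapping" of cosmic rays. The defaults (window 7, threshold 8) never
#' trigger on Lorentzian bands of typical width.
#'
#' @param set a [spectrum_set()].
#' @param window odd rolling-median window in channels (>= 3).
#' @param z_thresh modified z-score threshold.
#' @return The despiked `spectrum_set`.
#' @export
remove_spikes <- function(set, window = 7L, z_thresh = 8) {
  stopifnot(inherits(set, "spectrum_set"))
  if (window < 3 || window %% 2 == 0)
    stop_invalid("`window` must be odd and >= 3")
  Y <- set$intensities
  for (i in seq_len(nrow(Y))) {
    y <- Y[i, ]
    med <- stats::runmed(y, window, endrule = "median")
    resid <- y - med
    s <- stats::median(abs(resid))
    # smooth monotone spectra give mostly zero residuals; fall back to the
    # first-difference scale so genuine spikes are still detected
    if (s == 0) s <- stats::median(abs(diff(y))) / sqrt(2)
    if (s == 0) next
    z <- 0.6745 * abs(resid) / s
    hit <- z > z_thresh
    if (any(hit)) Y[i, hit] <- med[hit]
  }
  out <- set_intensities(set, Y)
  log_step(out, "remove_spikes", list(window = window, z_thresh = z_thresh))
}

#' Haar-wavelet denoising
#'
#' Decomposes each spectrum with a Haar wavelet to `levels` levels
#' (symmetric padding to the next dyadic length), soft-thresholds the
#' detail coefficients at the universal threshold \eqn{\sigma\sqrt{2\ln n}}
#' with \eqn{\sigma} estimated from the finest-level median absolute
#' deviation, and reconstructs.
#'
#' @param set a [spectrum_set()].
#' @param levels decomposition depth (default 6).
#' @return The denoised `spectrum_set` (same length spectra).
#' @export
denoise_wavelet <- function(set, levels = 6L) {
  stopifnot(inherits(set, "spectrum_set"))
  if (length(set$axis) < 2L^levels)
    stop_invalid("spectra shorter than 2^levels channels")
  out <- set_intensities(set, haar_denoise_rows(set$intensities, levels))
  log_step(out, "denoise_wavelet", list(levels = levels))
}

#' Polynomial fluorescence-baseline subtraction
#'
#' Fits an order-`order` polynomial to each spectrum over the wavenumber
#' axis by least squares and subtracts it; the default fifth order targets
#' the smooth fluorescence background of biofluid Raman spectra.
#'
#' @param set a [spectrum_set()].
#' @param order polynomial order (default 5).
#' @return The baseline-corrected `spectrum_set`.
#' @export
subtract_poly_baseline <- function(set, order = 5L) {
  stopifnot(inherits(set, "spectrum_set"))
  n <- length(set$axis)
  if (n <= order + 1) stop_invalid("need more channels than order + 1")
  P <- cbind(rep(1 / sqrt(n), n), stats::poly(set$axis, degree = order))
  Y <- set$intensities
  fitted <- (Y %*% P) %*% t(P)
  out <- set_intensities(set, Y - fitted)
  log_step(out, "subtract_poly_baseline", list(order = order))
}

#' Rubberband-style end-point anchoring
#'
#' Subtracts from each spectrum the straight line through its first and
#' last intensity values, so both end channels sit exactly on zero. With
#' `convex_hull = TRUE` the full lower convex hull is subtracted instead.
#'
#' @param set a [spectrum_set()].
#' @param convex_hull use the lower convex hull rather than the end-point
#'   chord.
#' @return The anchored `spectrum_set`.
#' @export
rubberband_anchor <- function(set, convex_hull = FALSE) {
  stopifnot(inherits(set, "spectrum_set"))
  x <- set$axis
  n <- length(x)
  Y <- set$intensities
  if (!convex_hull) {
    frac <- (x - x[1]) / (x[n] - x[1])
    base <- Y[, 1] %o% (1 - frac) + Y[, n] %o% frac
    Y <- Y - base
  } else {
    for (i in seq_len(nrow(Y))) {
      Y[i, ] <- Y[i, ] - lower_hull_baseline(x, Y[i, ])
    }
  }
  out <- set_intensities(set, Y)
  log_step(out, "rubberband_anchor", list(convex_hull = convex_hull))
}

# lower convex hull baseline (Andrew's monotone chain on sorted x)
lower_hull_baseline <- function(x, y) {
  n <- length(x)
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      if ((x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]) <= 0)
        hull <- hull[-length(hull)]
      else break
    }
    hull <- c(hull, i)
  }
  stats::approx(x[hull], y[hull], xout = x)$y
}

#' Vector (unit Euclidean norm) normalisation
#'
#' @param set a [spectrum_set()].
#' @return The normalised `spectrum_set`; every row has Euclidean norm 1.
#' @export
vector_normalize <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  nrm <- sqrt(rowSums(set$intensities^2))
  if (any(nrm == 0)) stop_invalid("cannot normalise an all-zero spectrum")
  out <- set_intensities(set, set$intensities / nrm)
  log_step(out, "vector_normalize", list())
}

# PCA robust score distance: RMS over the first n_pcs PCs of the
# (x - median)/MAD z-scores of the PC scores
pca_score_distance <- function(M, n_pcs) {
  k <- min(n_pcs, nrow(M) - 1L, ncol(M))
  if (k < 1) return(rep(0, nrow(M)))
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE, rank. = k)
  S <- pc$x[, seq_len(k), drop = FALSE]
  # use only components with nonzero spread (degenerate PCs carry no signal)
  live <- apply(S, 2, function(x) stats::mad(x) > 0 || stats::sd(x) > 0)
  if (!any(live)) return(rep(0, nrow(M)))
  Z <- apply(S[, live, drop = FALSE], 2, robust_z)
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = nrow(M))
  sqrt(rowMeans(Z^2))
}

#' Spectrum-level PCA outlier screening (within patient)
#'
#' For each patient, the replicate spectra are decomposed by PCA and each
#' spectrum's score distance (root-mean-square robust z-score over the
#' first `n_pcs` component scores) is compared to `dist_thresh`.
#'
#' @param set a [spectrum_set()].
#' @param n_pcs number of leading PCs in the score distance.
#' @param dist_thresh flagging threshold in robust SD units.
#' @return An `outlier_report`: data.frame of scores plus the flagged keys.
#' @export
pca_outliers_spectra <- function(set, n_pcs = 3L, dist_thresh = 3) {
  stopifnot(inherits(set, "spectrum_set"))
  ids <- unique(set$patient_id)
  score <- rep(0, n_spectra(set))
  for (pid in ids) {
    rows <- which(set$patient_id == pid)
    if (length(rows) < n_pcs + 2) {
      warning("patient ", pid, " has too few spectra for outlier screening;",
              " none flagged", call. = FALSE)
      next
    }
    score[rows] <- pca_score_distance(
      set$intensities[rows, , drop = FALSE], n_pcs)
  }
  flagged <- score > dist_thresh
  structure(list(
    level = "spectrum",
    scores = data.frame(patient_id = set$patient_id,
                        replicate = set$replicate,
                        score = score, flagged = flagged),
    removed_keys = paste(set$patient_id, set$replicate)[flagged],
    removed_patient_ids = character(0),
    threshold = dist_thresh, n_pcs = n_pcs), class = "outlier_report")
}

#' Patient-level PCA outlier screening
#'
#' PCA on the patient-mean spectra; patients whose score distance exceeds
#' `dist_thresh` are flagged and all their spectra marked for removal.
#' This is the screen that catches e.g. blood-contaminated CSF samples.
#'
#' @inheritParams pca_outliers_spectra
#' @return An `outlier_report` listing flagged patient ids.
#' @export
pca_outliers_patients <- function(set, n_pcs = 3L, dist_thresh = 3) {
  stopifnot(inherits(set, "spectrum_set"))
  M <- patient_means(set)
  if (nrow(M) < 3) stop_invalid("patient-level screening needs >= 3 patients")
  score <- pca_score_distance(M, n_pcs)
  flagged <- score > dist_thresh
  structure(list(
    level = "patient",
    scores = data.frame(patient_id = rownames(M), score = score,
                        flagged = flagged),
    removed_keys = character(0),
    removed_patient_ids = rownames(M)[flagged],
    threshold = dist_thresh, n_pcs = n_pcs), class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  n_flag <- if (x$level == "patient") length(x$removed_patient_ids)
            else length(x$removed_keys)
  cat("<outlier_report> level =", x$level, "| flagged", n_flag, "of",
      nrow(x$scores), "| threshold", x$threshold, "robust SD on",
      x$n_pcs, "PCs\n")
  invisible(x)
}

#' Default preprocessing parameters
#'
#' @param window,z_thresh spike filter settings, see [remove_spikes()].
#' @param wavelet_levels see [denoise_wavelet()].
#' @param poly_order see [subtract_poly_baseline()].
#' @param convex_hull see [rubberband_anchor()].
#' @param n_pcs,dist_thresh outlier-screen settings, see
#'   [pca_outliers_spectra()].
#' @param spectrum_level,patient_level enable the two outlier screens.
#' @return Named list of parameters for [preprocess_pipeline()].
#' @export
preprocess_params <- function(window = 7L, z_thresh = 8, wavelet_levels = 6L,
                              poly_order = 5L, convex_hull = FALSE,
                              n_pcs = 3L, dist_thresh = 3,
                              spectrum_level = TRUE, patient_level = TRUE) {
  list(window = window, z_thresh = z_thresh, wavelet_levels = wavelet_levels,
       poly_order = poly_order, convex_hull = convex_hull, n_pcs = n_pcs,
       dist_thresh = dist_thresh, spectrum_level = spectrum_level,
       patient_level = patient_level)
}

#' Full spectral preprocessing pipeline
#'
#' Applies, in order: background subtraction (optional), spike removal,
#' Haar-wavelet denoising, fifth-order polynomial baseline subtraction,
#' rubberband end-point anchoring, vector normalisation, then
#' spectrum-level and patient-level PCA outlier removal. Every step is
#' recorded in the provenance log; [replay_steps()] on the raw input
#' reproduces the output exactly.
#'
#' @param raw a raw [spectrum_set()].
#' @param backgrounds optional background spectra for
#'   [subtract_background()].
#' @param params a [preprocess_params()] list.
#' @return list with `set` (the processed `spectrum_set`), `spectrum_report`
#'   and `patient_report` (outlier reports, or NULL if disabled).
#' @export
preprocess_pipeline <- function(raw, backgrounds = NULL,
                                params = preprocess_params()) {
  set <- raw
  if (!is.null(backgrounds)) set <- subtract_background(set, backgrounds)
  set <- remove_spikes(set, window = params$window, z_thresh = params$z_thresh)
  set <- denoise_wavelet(set, levels = params$wavelet_levels)
  set <- subtract_poly_baseline(set, order = params$poly_order)
  set <- rubberband_anchor(set, convex_hull = params$convex_hull)
  set <- vector_normalize(set)

  spectrum_report <- NULL
  if (isTRUE(params$spectrum_level)) {
    spectrum_report <- pca_outliers_spectra(set, params$n_pcs,
                                            params$dist_thresh)
    if (length(spectrum_report$removed_keys) > 0) {
      keep <- !(paste(set$patient_id, set$replicate) %in%
                  spectrum_report$removed_keys)
      set <- subset_spectra(set, idx = keep)
      set <- log_step(set, "drop_spectra",
                      list(keys = spectrum_report$removed_keys))
    }
  }
  patient_report <- NULL
  if (isTRUE(params$patient_level)) {
    patient_report <- pca_outliers_patients(set, params$n_pcs,
                                            params$dist_thresh)
    if (length(patient_report$removed_patient_ids) > 0) {
      set <- subset_spectra(set,
        idx = !(set$patient_id %in% patient_report$removed_patient_ids))
      set <- log_step(set, "drop_patients",
        list(patient_ids = patient_report$removed_patient_ids))
    }
  }
  list(set = set, spectrum_report = spectrum_report,
       patient_report = patient_report)
}
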