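#' Per-wavenumber Mann-Whitney U tests between two classes
#'
#' At every channel of the shared axis, ranks the pooled intensities of the
#' two spectrum sets and computes the two-sided Mann-Whitney U p-value plus
#' the sign of (mean of class A - mean of class B). Exact p-values (via the
#' null U distribution) are used when both groups have fewer than 20
#' spectra and the channel is tie-free; otherwise the normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param class_a,class_b two [spectrum_set()] objects on the same axis
#'   (conventionally AD and non-AD).
#' @return A `shift_pvalue_track`: list with `axis`, `p`, `u_stat` (U of
#'   class A), and `direction` (+1 where class A's mean exceeds class B's).
#' @export
mannwhitney_per_shift <- function(class_a, class_b) {
  stopifnot(inherits(class_a, "spectrum_set"), inherits(class_b, "spectrum_set"))
  if (max(abs(class_a$axis - class_b$axis)) > 1e-9)
    stop_invalid("the two classes must share one axis")
  na <- n_spectra(class_a); nb <- n_spectra(class_b)
  if (na < 2 || nb < 2) stop_invalid("need >= 2 spectra per class")
  X <- rbind(class_a$intensities, class_b$intensities)
  res <- mw_columns(X, na, nb)
  dirn <- sign(colMeans(class_a$intensities) - colMeans(class_b$intensities))
  structure(list(axis = class_a$axis, p = res$p, u_stat = res$u,
                 direction = dirn),
            class = "shift_pvalue_track")
}

# vectorised Mann-Whitney over the columns of X (first na rows = group A)
mw_columns <- function(X, na, nb) {
  n <- na + nb
  p <- numeric(ncol(X)); u <- numeric(ncol(X))
  exact_ok <- max(na, nb) < 20
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    r <- rank(x)
    ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    u[j] <- ua
    has_ties <- anyDuplicated(x) > 0
    if (exact_ok && !has_ties) {
      p[j] <- if (ua > na * nb / 2) {
        min(1, 2 * stats::pwilcox(ua - 1, na, nb, lower.tail = FALSE))
      } else {
        min(1, 2 * stats::pwilcox(ua, na, nb))
      }
    } else {
      mu <- na * nb / 2
      tie_len <- if (has_ties) rle(sort(x))$lengths else 1L
      tie_term <- sum(tie_len^3 - tie_len) / (n * (n - 1))
      sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
      if (sigma2 <= 0) { p[j] <- 1; next }
      z <- ua - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
      p[j] <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(p = p, u = u)
}

# scalar two-sample Mann-Whitney on feature vectors (same conventions)
mw_test <- function(x, y) {
  res <- mw_columns(matrix(c(x, y), ncol = 1), length(x), length(y))
  list(p = res$p, u = res$u)
}

#' Extract contiguous significant regions ("spectral barcode") from a
#' p-value track
#'
#' Finds maximal runs of channels with `p < alpha`, merges runs separated
#' by at most `max_gap` non-significant channels, discards runs narrower
#' than `min_width` channels, assigns each region the majority channel
#' direction, and ranks regions by their smallest channel p-value
#' (ties broken toward the lower wavenumber bound).
#'
#' @param track a `shift_pvalue_track` from [mannwhitney_per_shift()].
#' @param alpha significance level per channel (default 0.01).
#' @param max_gap maximal run separation (channels) still merged.
#' @param min_width minimal region width (channels) retained.
#' @return data.frame of regions: `rank`, `lo`, `hi` (cm^-1 channel
#'   centres), `lo_idx`, `hi_idx`, `direction`, `min_p`. May have 0 rows.
#' @export
extract_regions <- function(track, alpha = 0.01, max_gap = 2L,
                            min_width = 3L) {
  stopifnot(inherits(track, "shift_pvalue_track"))
  sig <- track$p < alpha
  if (!any(sig)) return(empty_regions())
  runs <- significant_runs(sig, max_gap)
  runs <- runs[(runs$hi_idx - runs$lo_idx + 1L) >= min_width, , drop = FALSE]
  if (nrow(runs) == 0) return(empty_regions())
  runs$lo <- track$axis[runs$lo_idx]
  runs$hi <- track$axis[runs$hi_idx]
  runs$min_p <- vapply(seq_len(nrow(runs)), function(i) {
    min(track$p[runs$lo_idx[i]:runs$hi_idx[i]])
  }, 0)
  runs$direction <- vapply(seq_len(nrow(runs)), function(i) {
    d <- track$direction[runs$lo_idx[i]:runs$hi_idx[i]]
    if (sum(d) >= 0) 1 else -1
  }, 0)
  ord <- order(runs$min_p, runs$lo)
  runs <- runs[ord, , drop = FALSE]
  runs$rank <- seq_len(nrow(runs))
  rownames(runs) <- NULL
  runs[, c("rank", "lo", "hi", "lo_idx", "hi_idx", "direction", "min_p")]
}

empty_regions <- function() {
  data.frame(rank = integer(0), lo = numeric(0), hi = numeric(0),
             lo_idx = integer(0), hi_idx = integer(0),
             direction = numeric(0), min_p = numeric(0))
}

# maximal TRUE runs, then merge runs separated by <= max_gap FALSEs
significant_runs <- function(sig, max_gap) {
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lo <- starts[r$values]; hi <- ends[r$values]
  merged_lo <- lo[1]; merged_hi <- hi[1]
  if (length(lo) > 1) {
    for (i in 2:length(lo)) {
      if (lo[i] - merged_hi[length(merged_hi)] - 1L <= max_gap) {
        merged_hi[length(merged_hi)] <- hi[i]
      } else {
        merged_lo <- c(merged_lo, lo[i]); merged_hi <- c(merged_hi, hi[i])
      }
    }
  }
  data.frame(lo_idx = merged_lo, hi_idx = merged_hi)
}

#' Build a spectral barcode from training data
#'
#' Runs [mannwhitney_per_shift()] between the AD and non-AD spectra of a
#' training set and extracts the significant regions, returning the
#' rank-ordered barcode together with the training mean spectrum.
#'
#' @param set a preprocessed training [spectrum_set()].
#' @param labels class label per spectrum ("AD" / "non-AD"), or per patient
#'   via `patients`.
#' @param patients optional data.frame with `patient_id` and `diagnosis`
#'   used to derive `labels`.
#' @param alpha,max_gap,min_width see [extract_regions()].
#' @return An object of class `raman_barcode`: list with `regions`,
#'   `reference_mean`, `alpha`, `axis`, `track`.
#' @export
build_barcode <- function(set, labels = NULL, patients = NULL, alpha = 0.01,
                          max_gap = 2L, min_width = 3L) {
  labels <- resolve_labels(set, labels, patients)
  a <- subset_spectra(set, idx = labels == "AD")
  b <- subset_spectra(set, idx = labels != "AD")
  track <- mannwhitney_per_shift(a, b)
  regions <- extract_regions(track, alpha = alpha, max_gap = max_gap,
                             min_width = min_width)
  structure(list(regions = regions, reference_mean = colMeans(set$intensities),
                 alpha = alpha, axis = set$axis, track = track),
            class = "raman_barcode")
}

resolve_labels <- function(set, labels, patients) {
  if (is.null(labels)) {
    if (is.null(patients)) stop_invalid("give `labels` or `patients`")
    labels <- patients$diagnosis[match(set$patient_id, patients$patient_id)]
    if (anyNA(labels)) stop_invalid("some spectra have no patient record")
  }
  if (length(labels) != n_spectra(set))
    stop_invalid("one label per spectrum required")
  as.character(labels)
}

#' @export
print.raman_barcode <- function(x, ...) {
  cat("<raman_barcode>", nrow(x$regions), "regions at alpha =", x$alpha, "\n")
  if (nrow(x$regions) > 0)
    print(transform(x$regions, min_p = signif(min_p, 3)), row.names = FALSE)
  invisible(x)
}

#' Plot a spectral barcode over the reference mean spectrum
#'
#' @param x a `raman_barcode`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.raman_barcode <- function(x, ...) {
  graphics::plot(x$axis, x$reference_mean, type = "l", col = "grey40",
                 xlab = expression(paste("Raman shift (", cm^-1, ")")),
                 ylab = "intensity (a.u.)", ...)
  if (nrow(x$regions) > 0) {
    ylim <- graphics::par("usr")[3:4]
    for (i in seq_len(nrow(x$regions))) {
      col <- if (x$regions$direction[i] > 0) grDevices::rgb(1, 0, 0, 0.25)
             else grDevices::rgb(0, 0, 1, 0.25)
      graphics::rect(x$regions$lo[i], ylim[1], x$regions$hi[i], ylim[2],
                     col = col, border = NA)
    }
  }
  invisible(x)
}

#' Trapezoidal area of spectra over a barcode region
#'
#' Integrates each spectrum's intensity over the channels falling in
#' `[lo, hi]` using the trapezoid rule, with no local baseline subtraction.
#' A region collapsed to a single channel has zero area by the trapezoid
#' convention.
#'
#' @param set a [spectrum_set()] (or a single-row set).
#' @param lo,hi region bounds in cm^-1; must lie within the axis.
#' @return Numeric vector of areas (a.u. cm^-1), one per spectrum.
#' @export
region_area <- function(set, lo, hi) {
  stopifnot(inherits(set, "spectrum_set"))
  axis <- set$axis
  if (lo > hi || lo < axis[1] - 1e-9 || hi > axis[length(axis)] + 1e-9)
    stop_invalid("region [", lo, ", ", hi, "] outside the axis range")
  ch <- which(axis >= lo - 1e-9 & axis <= hi + 1e-9)
  if (length(ch) < 2) return(rep(0, n_spectra(set)))
  spacing <- axis_spacing(axis)
  w <- trapezoid_weights(length(ch), spacing)
  as.numeric(set$intensities[, ch, drop = FALSE] %*% w)
}

#' Per-spectrum feature table of barcode region areas
#'
#' One row per spectrum, one column per barcode region (in rank order).
#'
#' @param set a preprocessed [spectrum_set()] on the barcode's axis.
#' @param barcode a `raman_barcode` (or a region data.frame).
#' @return data.frame with `patient_id`, `replicate`, and `feature_1` ...
#'   `feature_K` area columns.
#' @export
build_feature_table <- function(set, barcode) {
  regions <- if (inherits(barcode, "raman_barcode")) barcode$regions
             else as.data.frame(barcode)
  if (inherits(barcode, "raman_barcode") &&
      max(abs(barcode$axis - set$axis)) > 1e-9)
    stop_invalid("spectrum set and barcode are on different axes")
  out <- data.frame(patient_id = set$patient_id, replicate = set$replicate,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(regions))) {
    out[[paste0("feature_", i)]] <-
      region_area(set, regions$lo[i], regions$hi[i])
  }
  out
}

feature_matrix <- function(table) {
  as.matrix(table[, grep("^feature_", names(table)), drop = FALSE])
}

#' Re-rank barcode regions by feature-level significance
#'
#' Runs a Mann-Whitney test per feature column (region area) between the
#' two classes and re-orders the regions by ascending p-value, ties broken
#' toward the lower wavenumber bound. Idempotent.
#'
#' @param barcode a `raman_barcode`.
#' @param table a feature table from [build_feature_table()].
#' @param labels class label per table row ("AD" vs anything else).
#' @return The re-ranked `raman_barcode` with a `feature_p` column added.
#' @export
rank_features <- function(barcode, table, labels) {
  stopifnot(inherits(barcode, "raman_barcode"))
  labels <- as.character(labels)
  if (length(labels) != nrow(table)) stop_invalid("one label per row required")
  if (length(unique(labels)) != 2) stop_invalid("need exactly 2 classes")
  M <- feature_matrix(table)
  if (ncol(M) != nrow(barcode$regions))
    stop_invalid("feature table does not match barcode regions")
  is_a <- labels == "AD"
  pvals <- vapply(seq_len(ncol(M)), function(j) {
    mw_test(M[is_a, j], M[!is_a, j])$p
  }, 0)
  regions <- barcode$regions
  regions$feature_p <- pvals
  ord <- order(pvals, regions$lo)
  regions <- regions[ord, , drop = FALSE]
  regions$rank <- seq_len(nrow(regions))
  rownames(regions) <- NULL
  barcode$regions <- regions
  barcode
}
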