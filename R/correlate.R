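#' PLM (Paris-North Lille Montpellier) biomarker score
#'
#' Counts positive CSF ATN biomarkers per patient: amyloid positive if
#' Aβ42 < 680 pg/ml, tau positive if p-tau > 56 pg/ml, neurodegeneration
#' positive if total tau > 355 pg/ml. Three positives indicate a very high
#' likelihood of AD; zero a very low likelihood. Patients missing any of
#' the three biomarkers get an undefined (NA) score.
#'
#' @param patients data.frame with `abeta42`, `ptau`, `total_tau` columns
#'   (pg/ml), or a single-patient list.
#' @param cutoffs named cutoffs, defaults
#'   `c(abeta42 = 680, ptau = 56, total_tau = 355)`.
#' @return data.frame with logical `A`, `T`, `N` components and integer
#'   `plm` (0-3, NA when any component is missing).
#' @export
plm_score <- function(patients,
                      cutoffs = c(abeta42 = 680, ptau = 56, total_tau = 355)) {
  p <- as.data.frame(patients)
  A <- p$abeta42 < cutoffs[["abeta42"]]
  T_ <- p$ptau > cutoffs[["ptau"]]
  N <- p$total_tau > cutoffs[["total_tau"]]
  plm <- as.integer(A) + as.integer(T_) + as.integer(N)
  out <- data.frame(A = A, T = T_, N = N, plm = plm)
  if ("patient_id" %in% names(p)) out <- cbind(patient_id = p$patient_id, out)
  out
}

#' Age/sex-adjusted partial correlation
#'
#' Residualises `x` and `y` on the covariates (plus intercept) by least
#' squares and returns the Pearson correlation of the residuals, with the
#' two-sided p-value from \eqn{t = r\sqrt{(n-2-k)/(1-r^2)}} on
#' \eqn{n-2-k} degrees of freedom for k covariates. With no covariates
#' this is exactly the Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame/matrix of covariates (e.g. age and 0/1
#'   sex), or NULL.
#' @return list with `r`, `p`, `n`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  keep <- stats::complete.cases(x, y,
                                if (is.null(covariates)) rep(0, length(x))
                                else covariates)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  k <- 0L
  if (!is.null(covariates)) {
    C <- as.matrix(as.data.frame(covariates)[keep, , drop = FALSE])
    storage.mode(C) <- "double"
    k <- ncol(C)
    Z <- cbind(1, C)
    if (qr(Z)$rank < ncol(Z))
      stop("collinear covariates: partial correlation is not identified",
           call. = FALSE)
    x <- stats::lm.fit(Z, x)$residuals
    y <- stats::lm.fit(Z, y)$residuals
  }
  if (n <= k + 2) stop_invalid("need n > number of covariates + 2")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, df = n - 2L - k))
  r <- stats::cor(x, y)
  df <- n - 2L - k
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(r = r, p = p, n = n, df = df)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment across one family of tests
#' (monotone, capped at 1).
#'
#' @param p numeric p-values in [0, 1].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop_invalid("p-values must be numbers in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Partial-correlation matrix of spectral features against ATN biomarkers
#'
#' Aggregates the feature table to one mean area per patient and feature,
#' log-transforms the biomarker concentrations, and computes the age/sex-
#' adjusted partial correlation of every (feature, biomarker) pair. All
#' pairs are Benjamini-Hochberg adjusted as a single family (10 features x
#' 3 biomarkers = 30 comparisons with the default barcode). Patients with
#' missing total tau are excluded from the total-tau column only.
#'
#' @param features feature table ([build_feature_table()]) with
#'   `patient_id` and `feature_*` columns.
#' @param patients data.frame with `patient_id`, `age`, `sex` and biomarker
#'   columns.
#' @param biomarkers biomarker columns to correlate against.
#' @param fdr_alpha significance level on the adjusted p-values.
#' @return data.frame with one row per (feature, biomarker) pair: `r`,
#'   `p_raw`, `p_adj`, `n`, `significant`.
#' @export
correlation_matrix <- function(features, patients,
                               biomarkers = c("abeta42", "ptau", "total_tau"),
                               fdr_alpha = 0.05) {
  agg <- aggregate_features(features)
  idx <- match(agg$patient_id, patients$patient_id)
  if (anyNA(idx)) stop_invalid("feature table patients missing from metadata")
  meta <- patients[idx, , drop = FALSE]
  cov <- data.frame(age = meta$age, sex = as.integer(meta$sex == "M"))
  fcols <- grep("^feature_", names(agg), value = TRUE)
  out <- list()
  for (b in biomarkers) {
    if (!b %in% names(meta) || all(is.na(meta[[b]]))) {
      warning("biomarker ", b, " missing; skipped", call. = FALSE)
      next
    }
    logb <- log(meta[[b]])
    for (f in fcols) {
      pc <- partial_correlation(agg[[f]], logb, cov)
      out[[length(out) + 1L]] <- data.frame(
        feature = f, biomarker = b, r = pc$r, p_raw = pc$p, n = pc$n)
    }
  }
  res <- do.call(rbind, out)
  res$p_adj <- bh_adjust(res$p_raw)
  res$significant <- res$p_adj < fdr_alpha
  res
}

#' Partial correlations of classifier scores with PLM status
#'
#' Correlates per-patient classification scores (or per-patient mean
#' feature areas) with the ordinal PLM score (0-3), adjusted for age and
#' sex; the family (e.g. the 10 feature-PLM tests) is BH-adjusted
#' separately from the feature-biomarker matrix.
#'
#' @param values named list or data.frame of per-patient quantities to
#'   correlate (names become rows), or a single named numeric vector of
#'   patient scores.
#' @param patients data.frame with `patient_id`, `age`, `sex` and the
#'   three ATN biomarkers (for the PLM score).
#' @param fdr_alpha significance level on the adjusted p-values.
#' @return data.frame with `variable`, `r`, `p_raw`, `p_adj`, `n`,
#'   `significant`.
#' @export
plm_correlations <- function(values, patients, fdr_alpha = 0.05) {
  plm <- plm_score(patients)$plm
  if (is.numeric(values) && !is.null(names(values)))
    values <- list(score = values)
  out <- list()
  for (nm in names(values)) {
    v <- values[[nm]]
    idx <- match(names(v) %||% patients$patient_id, patients$patient_id)
    cov <- data.frame(age = patients$age[idx],
                      sex = as.integer(patients$sex[idx] == "M"))
    pc <- partial_correlation(as.numeric(v), plm[idx], cov)
    out[[length(out) + 1L]] <- data.frame(variable = nm, r = pc$r,
                                          p_raw = pc$p, n = pc$n)
  }
  res <- do.call(rbind, out)
  res$p_adj <- bh_adjust(res$p_raw)
  res$significant <- res$p_adj < fdr_alpha
  res
}

# patient-level mean of each feature column
aggregate_features <- function(features) {
  fcols <- grep("^feature_", names(features), value = TRUE)
  agg <- stats::aggregate(features[fcols],
                          by = list(patient_id = features$patient_id), mean)
  agg
}
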