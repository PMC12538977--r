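#' PCA projection of a feature table
#'
#' Column-centred (optionally z-scored) principal component analysis of the
#' barcode feature areas, used for exploratory clustering of samples.
#'
#' @param table a feature table from [build_feature_table()], or a numeric
#'   matrix.
#' @param n_components components to retain (default: all).
#' @param scale. z-score the features first (default TRUE; region areas
#'   have heterogeneous scales).
#' @return A `projection_result`: list with `scores`, `loadings`, and
#'   `explained_variance` per retained component.
#' @export
pca_project <- function(table, n_components = NULL, scale. = TRUE) {
  M <- if (is.matrix(table)) table else feature_matrix(table)
  if (ncol(M) < 1) stop_invalid("no feature columns")
  sds <- apply(M, 2, stats::sd)
  if (all(sds == 0)) stop_invalid("feature matrix is constant")
  if (scale. && any(sds == 0)) {
    warning("constant feature columns left unscaled", call. = FALSE)
    M[, sds == 0] <- 0
    scale_vec <- ifelse(sds == 0, 1, sds)
    M <- scale(M, center = TRUE, scale = scale_vec)
    pc <- stats::prcomp(M, center = FALSE, scale. = FALSE)
  } else {
    pc <- stats::prcomp(M, center = TRUE, scale. = scale.)
  }
  k <- min(n_components %||% ncol(pc$rotation), ncol(pc$rotation))
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 explained_variance = pc$sdev[seq_len(k)]^2,
                 total_variance = sum(pc$sdev^2),
                 method = "pca"),
            class = "projection_result")
}

#' Fisher linear discriminant projection of a feature table
#'
#' Computes the single discriminant axis maximising the between- to
#' within-class variance ratio of the (optionally z-scored) features, i.e.
#' the Fisher direction \eqn{S_w^{-1}(\mu_1 - \mu_0)}. If the pooled
#' within-class covariance is singular a small ridge is added and a
#' message logged.
#'
#' @param table feature table or numeric matrix.
#' @param labels two-class label per row ("AD" treated as the positive
#'   class when present).
#' @param scale. z-score features first (default TRUE).
#' @param ridge optional ridge added to the pooled covariance; `NULL` means
#'   only on singularity.
#' @return A `projection_result` with one score column `LD1` and the
#'   discriminant loadings.
#' @export
lda_project <- function(table, labels, scale. = TRUE, ridge = NULL) {
  M <- if (is.matrix(table)) table else feature_matrix(table)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop_invalid("need exactly 2 classes")
  pos <- if ("AD" %in% classes) "AD" else classes[2]
  if (scale.) M <- scale(M)
  mu1 <- colMeans(M[labels == pos, , drop = FALSE])
  mu0 <- colMeans(M[labels != pos, , drop = FALSE])
  n1 <- sum(labels == pos); n0 <- sum(labels != pos)
  S1 <- stats::cov(M[labels == pos, , drop = FALSE])
  S0 <- stats::cov(M[labels != pos, , drop = FALSE])
  Sw <- ((n1 - 1) * S1 + (n0 - 1) * S0) / (n1 + n0 - 2)
  if (!is.null(ridge)) Sw <- Sw + diag(ridge, ncol(M))
  w <- tryCatch(solve(Sw, mu1 - mu0), error = function(e) NULL)
  if (is.null(w)) {
    message("within-class covariance singular; ridge regularisation applied")
    lam <- 1e-6 * mean(diag(Sw))
    if (lam <= 0) lam <- 1e-6
    w <- solve(Sw + diag(lam, ncol(M)), mu1 - mu0)
  }
  w <- w / sqrt(sum(w^2))
  scores <- M %*% w
  colnames(scores) <- "LD1"
  structure(list(scores = scores, loadings = matrix(w, ncol = 1,
                   dimnames = list(colnames(M), "LD1")),
                 explained_variance = NULL, positive_class = pos,
                 method = "lda"),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat("<projection_result> method =", x$method, "|", nrow(x$scores),
      "samples x", ncol(x$scores), "components\n")
  if (!is.null(x$explained_variance)) {
    pct <- 100 * x$explained_variance / x$total_variance
    cat("  explained variance (%):", paste(round(pct, 1), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Best linear-cutoff classification accuracy of a 1-D projection
#'
#' Scans all thresholds between adjacent distinct score values (and both
#' orientations) and returns the cutoff maximising balanced accuracy, with
#' ties broken toward the lower threshold. Reports overall and per-class
#' fractions correct.
#'
#' @param scores numeric 1-D projection (e.g. LD1 or PC1 scores).
#' @param labels two-class label per score.
#' @return list with `threshold`, `positive_high` (whether the positive
#'   class sits above the threshold), `overall`, and `per_class` named
#'   fractions.
#' @export
linear_cutoff_accuracy <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop_invalid("need exactly 2 classes")
  pos <- if ("AD" %in% classes) "AD" else classes[2]
  y <- labels == pos
  su <- sort(unique(scores))
  cand <- c(su[1] - 1, (su[-1] + su[-length(su)]) / 2, su[length(su)] + 1)
  best <- NULL
  for (dir_high in c(TRUE, FALSE)) {
    for (thr in cand) {
      called_pos <- if (dir_high) scores > thr else scores < thr
      sens <- mean(called_pos[y]); spec <- mean(!called_pos[!y])
      bal <- (sens + spec) / 2
      if (is.null(best) || bal > best$bal + 1e-12) {
        best <- list(bal = bal, threshold = thr, positive_high = dir_high,
                     sens = sens, spec = spec)
      }
    }
  }
  per_class <- c(best$sens, best$spec)
  names(per_class) <- c(pos, setdiff(classes, pos))
  list(threshold = best$threshold, positive_high = best$positive_high,
       overall = mean((if (best$positive_high) scores > best$threshold
                       else scores < best$threshold) == y),
       per_class = per_class, balanced = best$bal)
}
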