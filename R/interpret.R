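#' Global surrogate (LIME-style) feature importance
#'
#' For a sample of training points, perturbs the (z-scored) features around
#' each point, weights the perturbations by a Gaussian kernel of width
#' `kernel_width` in standardised space, fits a depth-limited decision tree
#' surrogate to the black-box model's scores, and records the surrogate's
#' per-feature importance as the local weights. The global importance of a
#' feature is the mean of its absolute local weights over all queried
#' points.
#'
#' @param score_fun function(matrix) -> numeric score per row (the fitted
#'   model's continuous AD score); for a `raman_ad` fit use
#'   \code{function(X) rowMeans(sapply(fit$ensemble$models, ...))} or pass
#'   the fit itself.
#' @param X training feature matrix (rows = spectra, cols = features).
#' @param kernel_width Gaussian kernel width in z-scored feature space
#'   (default 0.5).
#' @param n_perturb perturbations per queried point (default 1000).
#' @param max_points cap on queried training points (sampled without
#'   replacement) to keep runtime bounded.
#' @param maxdepth surrogate tree depth.
#' @param seed RNG seed.
#' @return An `importance_report`: data.frame with per-feature global
#'   importance and rank, plus the matrix of local weights.
#' @export
global_surrogate_importance <- function(score_fun, X, kernel_width = 0.5,
                                        n_perturb = 1000L, max_points = 200L,
                                        maxdepth = 3L, seed = 1L) {
  score_fun <- as_score_fun(score_fun)
  X <- as.matrix(X)
  p <- ncol(X)
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  Z <- scale(X, center = mu, scale = sds)
  with_seed(seed, {
    pts <- if (nrow(X) > max_points) sample.int(nrow(X), max_points)
           else seq_len(nrow(X))
    local_w <- matrix(0, length(pts), p,
                      dimnames = list(NULL, colnames(X) %||%
                                        paste0("feature_", seq_len(p))))
    for (i in seq_along(pts)) {
      z0 <- Z[pts[i], ]
      # perturb in standardised space around the query point
      Zp <- matrix(stats::rnorm(n_perturb * p, 0, 1), n_perturb, p)
      Zp <- sweep(Zp, 2, z0, `+`)
      colnames(Zp) <- colnames(local_w)
      d2 <- rowSums(sweep(Zp, 2, z0)^2)
      wts <- exp(-d2 / (2 * kernel_width^2))
      Xp <- sweep(sweep(Zp, 2, sds, `*`), 2, mu, `+`)
      colnames(Xp) <- colnames(X)
      ys <- score_fun(Xp)
      df <- data.frame(y = ys, Zp)
      names(df)[-1] <- colnames(local_w)
      tr <- rpart::rpart(y ~ ., data = df, weights = wts,
                         control = rpart::rpart.control(maxdepth = maxdepth,
                                                        cp = 0.001,
                                                        minsplit = 10))
      vi <- tr$variable.importance
      if (!is.null(vi)) {
        vi <- vi / sum(vi)
        local_w[i, names(vi)] <- vi
      }
    }
    gi <- colMeans(abs(local_w))
    report <- data.frame(feature = colnames(local_w), importance = gi,
                         rank = rank(-gi, ties.method = "first"),
                         row.names = NULL)
    report <- report[order(report$rank), ]
    structure(list(importance = report, local_weights = local_w,
                   kernel_width = kernel_width), class = "importance_report")
  })
}

as_score_fun <- function(f) {
  if (inherits(f, "raman_ad")) {
    fit <- f
    return(function(X) {
      rowMeans(vapply(fit$ensemble$models,
                      function(m) score_spectra(fit$ensemble$kind, m, X),
                      numeric(nrow(X))))
    })
  }
  if (inherits(f, "spectral_classifier")) {
    fit <- f
    return(function(X) score_spectra(fit$kind, fit$model, X))
  }
  stopifnot(is.function(f))
  f
}

#' @export
print.importance_report <- function(x, ...) {
  cat("<importance_report> kernel width", x$kernel_width, "\n")
  print(transform(x$importance, importance = signif(importance, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Partial dependence of a model on one feature
#'
#' PD(v) is the mean model score over the training rows with feature
#' `feature_index` forced to the value v, evaluated on a uniform grid over
#' the observed feature range. The curve and its maximum are returned.
#'
#' @inheritParams global_surrogate_importance
#' @param feature_index column of `X` to vary.
#' @param grid_size grid points over the feature's observed range.
#' @return list with `grid`, `pd` (curve values), `maximum` (highest PD
#'   score), and `at` (grid value attaining it).
#' @export
partial_dependence <- function(score_fun, X, feature_index, grid_size = 20L) {
  score_fun <- as_score_fun(score_fun)
  X <- as.matrix(X)
  v <- X[, feature_index]
  if (max(v) == min(v)) {
    warning("constant feature: flat partial dependence", call. = FALSE)
    grid <- rep(v[1], 2)
  } else {
    grid <- seq(min(v), max(v), length.out = grid_size)
  }
  pd <- vapply(grid, function(g) {
    Xg <- X
    Xg[, feature_index] <- g
    mean(score_fun(Xg))
  }, 0)
  list(grid = grid, pd = pd, maximum = max(pd), at = grid[which.max(pd)])
}
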