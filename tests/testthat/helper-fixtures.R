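# shared fixtures and independent oracles, all built in code

# a small spectrum_set from a plain matrix (default trivial axis)
tiny_set <- function(Y, axis = NULL, pid = NULL, rep_ = NULL) {
  Y <- rbind(Y)
  if (is.null(axis)) axis <- seq_len(ncol(Y))
  if (is.null(pid)) pid <- paste0("P", seq_len(nrow(Y)))
  if (is.null(rep_)) rep_ <- rep(1L, nrow(Y))
  spectrum_set(Y, axis, pid, rep_)
}

# fast small-cohort generator settings for unit tests
small_cfg <- function(...) {
  defaults <- list(n_per_class = c(10L, 12L), spectra_per_patient = 6L,
                   seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_config, args)
}

# noise-free degenerate generator settings
clean_cfg <- function(...) {
  small_cfg(noise_sd = 0, patient_effect_sd = 0, severity_sd = 0,
            cosmic_ray_rate = 0,
            baseline_coeffs_range = cbind(lo = rep(0, 6), hi = rep(0, 6)),
            effect_regions = data.frame(lo = numeric(0), hi = numeric(0),
                                        effect = numeric(0)),
            missing_ttau_fraction = 0, ...)
}

# --- independent oracles -------------------------------------------------

# exact two-sided Mann-Whitney p by enumerating all group-A subsets
mw_enum_oracle <- function(x, y) {
  na <- length(x); n <- na + length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  subsets <- utils::combn(n, na)
  us <- apply(subsets, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(u = u_obs, p = min(1, p))
}

# AUC by pairwise concordance counting
auc_concordance_oracle <- function(scores, y) {
  pos <- scores[y]; neg <- scores[!y]
  gr <- outer(pos, neg, `>`); eq <- outer(pos, neg, `==`)
  (sum(gr) + 0.5 * sum(eq)) / (length(pos) * length(neg))
}

# BH step-up formula applied literally
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# partial correlation from the precision matrix of (x, y, covariates)
pcor_precision_oracle <- function(x, y, covs) {
  M <- cbind(x = x, y = y, as.matrix(covs))
  P <- solve(stats::cov(M))
  -P["x", "y"] / sqrt(P["x", "x"] * P["y", "y"])
}

# brute-force run merger for extract_regions
runs_oracle <- function(sig, max_gap, min_width) {
  idx <- which(sig)
  if (length(idx) == 0) return(list())
  groups <- cumsum(c(1, diff(idx) > max_gap + 1))
  out <- lapply(split(idx, groups), range)
  Filter(function(r) diff(r) + 1 >= min_width, out)
}

# jaccard overlap of two closed intervals
interval_jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  union <- max(a[2], b[2]) - min(a[1], b[1])
  if (union <= 0) return(0)
  inter / union
}
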