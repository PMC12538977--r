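# Haar discrete wavelet transform on the rows of a matrix, with symmetric
# padding to the next dyadic length. Used by denoise_wavelet().

next_pow2 <- function(n) 2L^ceiling(log2(n))

# returns list(approx = matrix, details = list of matrices finest..coarsest)
haar_decompose <- function(Y, levels) {
  details <- vector("list", levels)
  A <- Y
  for (l in seq_len(levels)) {
    m <- ncol(A)
    odd <- seq(1, m, by = 2); even <- seq(2, m, by = 2)
    details[[l]] <- (A[, odd, drop = FALSE] - A[, even, drop = FALSE]) / sqrt(2)
    A <- (A[, odd, drop = FALSE] + A[, even, drop = FALSE]) / sqrt(2)
  }
  list(approx = A, details = details)
}

haar_reconstruct <- function(dec) {
  A <- dec$approx
  for (l in rev(seq_along(dec$details))) {
    D <- dec$details[[l]]
    m <- 2L * ncol(A)
    X <- matrix(0, nrow(A), m)
    X[, seq(1, m, by = 2)] <- (A + D) / sqrt(2)
    X[, seq(2, m, by = 2)] <- (A - D) / sqrt(2)
    A <- X
  }
  A
}

# symmetric (reflective) pad of rows to length `target`
pad_symmetric <- function(Y, target) {
  n <- ncol(Y)
  if (n == target) return(Y)
  extra <- target - n
  if (extra > n) stop_invalid("spectrum too short for requested padding")
  cbind(Y, Y[, n:(n - extra + 1), drop = FALSE])
}

# soft-threshold Haar denoising of matrix rows: universal threshold
# sigma * sqrt(2 log n) with sigma from the finest-level detail MAD per row
haar_denoise_rows <- function(Y, levels) {
  n <- ncol(Y)
  target <- next_pow2(n)
  if (target %% 2L^levels != 0L || target < 2L^levels)
    stop_invalid("spectrum too short for ", levels, " decomposition levels")
  Yp <- pad_symmetric(Y, target)
  dec <- haar_decompose(Yp, levels)
  sigma <- apply(dec$details[[1]], 1, function(d) stats::median(abs(d))) / 0.6745
  lambda <- sigma * sqrt(2 * log(target))
  for (l in seq_along(dec$details)) {
    D <- dec$details[[l]]
    D <- sign(D) * pmax(abs(D) - lambda, 0)  # lambda recycles by row
    dec$details[[l]] <- D
  }
  haar_reconstruct(dec)[, seq_len(n), drop = FALSE]
}
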