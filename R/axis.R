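#' Construct a uniform wavenumber axis
#'
#' Builds the Raman-shift axis on which all spectra in a set live. The
#' default instrument geometry covers 659--1761 cm\eqn{^{-1}} in 1015
#' channels, i.e. a channel spacing of about 1.09 cm\eqn{^{-1}}.
#'
#' @param n_points number of channels (>= 2).
#' @param start first Raman shift (cm^-1).
#' @param end last Raman shift (cm^-1); must exceed `start`.
#' @return Numeric vector of strictly increasing, uniformly spaced Raman
#'   shifts with first value `start` and last value `end`.
#' @examples
#' ax <- make_axis(1015, 659, 1761)
#' round(axis_spacing(ax), 2)  # 1.09
#' @export
make_axis <- function(n_points = 1015L, start = 659, end = 1761) {
  if (length(n_points) != 1L || !is.finite(n_points) || n_points < 2)
    stop_invalid("`n_points` must be a single integer >= 2")
  if (!is.finite(start) || !is.finite(end) || end <= start)
    stop_invalid("axis span must be positive (`end` > `start`)")
  seq(start, end, length.out = as.integer(n_points))
}

#' Channel spacing of a uniform axis
#'
#' @param axis numeric axis as from [make_axis()].
#' @return The (uniform) spacing in cm^-1.
#' @export
axis_spacing <- function(axis) {
  validate_axis(axis)
  (axis[length(axis)] - axis[1]) / (length(axis) - 1L)
}

# strictly increasing + uniform spacing within 1e-9 relative tolerance
validate_axis <- function(axis) {
  if (!is.numeric(axis) || length(axis) < 2L || anyNA(axis))
    stop_invalid("axis must be a numeric vector of length >= 2 without NA")
  d <- diff(axis)
  if (any(d <= 0)) stop_invalid("axis must be strictly increasing")
  if (max(abs(d - d[1])) > 1e-9 * max(abs(axis)))
    stop_invalid("axis spacing is not uniform")
  invisible(axis)
}
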