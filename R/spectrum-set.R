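#' Create a set of spectra on a shared wavenumber axis
#'
#' The `spectrum_set` is the carrier object of the pipeline: an
#' `n_spectra x n_channels` intensity matrix, the shared axis, the patient
#' and replicate identity of every row, and a provenance log of the
#' processing steps applied so far.
#'
#' @param intensities numeric matrix, one spectrum per row.
#' @param axis wavenumber axis; length must equal `ncol(intensities)`.
#' @param patient_id character vector, one entry per row.
#' @param replicate integer replicate index per row; `(patient_id,
#'   replicate)` pairs must be unique.
#' @param steps provenance log (list of steps already applied), normally
#'   left empty.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(intensities, axis, patient_id, replicate,
                         steps = list()) {
  intensities <- as.matrix(intensities)
  validate_axis(axis)
  if (ncol(intensities) != length(axis))
    stop_invalid("intensity columns (", ncol(intensities),
                 ") do not match axis length (", length(axis), ")")
  if (!all(is.finite(intensities)))
    stop_invalid("intensities must be finite")
  n <- nrow(intensities)
  patient_id <- as.character(patient_id)
  replicate <- as.integer(replicate)
  if (length(patient_id) != n || length(replicate) != n)
    stop_invalid("patient_id and replicate must have one entry per spectrum")
  key <- paste(patient_id, replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop_invalid("duplicate (patient_id, replicate) key: ",
                 gsub("\r", ", ", dup))
  }
  dimnames(intensities) <- NULL
  structure(list(intensities = intensities, axis = as.numeric(axis),
                 patient_id = patient_id, replicate = replicate,
                 steps = steps),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("<spectrum_set> ", nrow(x$intensities), " spectra, ",
      length(x$axis), " channels (",
      format(x$axis[1]), "-", format(x$axis[length(x$axis)]), " cm^-1), ",
      length(unique(x$patient_id)), " patients\n", sep = "")
  if (length(x$steps))
    cat("  steps:", paste(vapply(x$steps, `[[`, "", "step"),
                          collapse = " -> "), "\n")
  invisible(x)
}

#' Number of spectra in a set
#' @param set a `spectrum_set`.
#' @return Integer count of spectra (rows).
#' @export
n_spectra <- function(set) nrow(set$intensities)

#' Subset a spectrum set by row index or patient id
#'
#' @param set a `spectrum_set`.
#' @param idx integer/logical row index, or
#' @param patients character vector of patient ids to keep (used when `idx`
#'   is missing).
#' @return A `spectrum_set` with the selected spectra; provenance retained.
#' @export
subset_spectra <- function(set, idx = NULL, patients = NULL) {
  stopifnot(inherits(set, "spectrum_set"))
  if (is.null(idx)) {
    if (is.null(patients)) stop_invalid("give `idx` or `patients`")
    idx <- set$patient_id %in% patients
  }
  spectrum_set(set$intensities[idx, , drop = FALSE], set$axis,
               set$patient_id[idx], set$replicate[idx], steps = set$steps)
}

#' Per-patient mean spectra
#'
#' @param set a `spectrum_set`.
#' @return Matrix of patient-mean spectra, rownames = patient ids, in order
#'   of first appearance.
#' @export
patient_means <- function(set) {
  ids <- unique(set$patient_id)
  out <- matrix(0, length(ids), length(set$axis))
  for (i in seq_along(ids)) {
    rows <- set$patient_id == ids[i]
    out[i, ] <- colMeans(set$intensities[rows, , drop = FALSE])
  }
  rownames(out) <- ids
  out
}

# append one provenance entry (step name + parameter list)
log_step <- function(set, step, params = list()) {
  set$steps <- c(set$steps, list(list(step = step, params = params)))
  set
}

# replace the intensity matrix, keeping identity columns
set_intensities <- function(set, mat) {
  stopifnot(nrow(mat) == nrow(set$intensities),
            ncol(mat) == ncol(set$intensities))
  set$intensities <- mat
  set
}

#' Replay a provenance log on a raw spectrum set
#'
#' Re-applies, in order, the preprocessing steps recorded in another set's
#' provenance log. Replaying the log of a processed set on the raw input
#' reproduces the processed intensities exactly.
#'
#' @param raw the unprocessed `spectrum_set`.
#' @param steps a provenance log (the `$steps` field of a processed set).
#' @return The reprocessed `spectrum_set`.
#' @export
replay_steps <- function(raw, steps) {
  out <- raw
  for (s in steps) {
    out <- switch(s$step,
      subtract_background = subtract_background(out, s$params$backgrounds),
      remove_spikes = remove_spikes(out, window = s$params$window,
                                    z_thresh = s$params$z_thresh),
      denoise_wavelet = denoise_wavelet(out, levels = s$params$levels),
      subtract_poly_baseline = subtract_poly_baseline(out,
                                                      order = s$params$order),
      rubberband_anchor = rubberband_anchor(out,
                                            convex_hull = s$params$convex_hull),
      vector_normalize = vector_normalize(out),
      drop_spectra = subset_spectra(out, idx = !(paste(out$patient_id,
        out$replicate) %in% s$params$keys)),
      drop_patients = subset_spectra(out,
        idx = !(out$patient_id %in% s$params$patient_ids)),
      stop_invalid("unknown provenance step: ", s$step))
  }
  out
}
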