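#' Configuration for the synthetic CSF Raman cohort generator
#'
#' Returns the default generator settings, which emulate the structure of a
#' two-class clinical CSF Raman study: 143 patients (67 AD, 76 non-AD), 30
#' replicate spectra per patient on a 1015-channel axis over 659--1761
#' cm\eqn{^{-1}}, a protein-dominated peak template (phenylalanine ~1003
#' cm\eqn{^{-1}}, amide III 1200--1350, amide I 1600--1700), class effects
#' localised to ten feature regions, an order-5 polynomial fluorescence
#' baseline, additive Gaussian noise, Poisson cosmic-ray spikes, additive
#' per-patient offsets, a latent per-patient severity that scales the class
#' effect, and class-conditional log-normal ATN biomarkers coupled to that
#' severity.
#'
#' @param n_per_class patients per class; one count (both classes) or
#'   `c(AD, nonAD)`.
#' @param spectra_per_patient replicate spectra per patient (>= 1).
#' @param n_points,start,end wavenumber axis geometry.
#' @param peak_table data.frame with columns `center`, `fwhm`, `amplitude`
#'   (Lorentzian profiles).
#' @param effect_regions data.frame with columns `lo`, `hi`, `effect`; the
#'   signed effect is expressed in units of the baseline within-class
#'   standard deviation of the region's raw area.
#' @param baseline_coeffs_range (order+1) x 2 matrix of uniform ranges for
#'   the polynomial baseline coefficients (Chebyshev-scaled x in [-1, 1]).
#' @param noise_sd additive channel noise SD (a.u.).
#' @param patient_effect_sd SD of the additive per-patient intensity offset.
#' @param severity_sd SD of the latent per-patient severity (AD centred at
#'   1, non-AD at 0) that multiplies the injected class effect.
#' @param cosmic_ray_rate expected cosmic-ray spikes per spectrum (Poisson).
#' @param spike_amplitude spike height (a.u.), large relative to the peaks.
#' @param contaminated_patient_ids patients to contaminate at generation
#'   time (via [inject_contamination()]).
#' @param contamination_amplitude amplitude of the injected broadband
#'   contaminant; default 10x `noise_sd`.
#' @param biomarker_model class-conditional log-normal `(meanlog, sdlog)`
#'   per biomarker plus the severity coupling correlations.
#' @param missing_ttau_fraction fraction of patients with total tau missing.
#' @param seed RNG seed; identical configs give bit-identical cohorts.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_per_class = c(67L, 76L),
                         spectra_per_patient = 30L,
                         n_points = 1015L, start = 659, end = 1761,
                         peak_table = default_peak_table(),
                         effect_regions = default_effect_regions(),
                         baseline_coeffs_range = default_baseline_range(),
                         noise_sd = 0.02,
                         patient_effect_sd = 0.01,
                         severity_sd = 0.3,
                         cosmic_ray_rate = 0.05,
                         spike_amplitude = 20,
                         contaminated_patient_ids = character(0),
                         contamination_amplitude = 10 * noise_sd,
                         biomarker_model = default_biomarker_model(),
                         missing_ttau_fraction = 7 / 143,
                         seed = 1L) {
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, 2L)
  n_per_class <- as.integer(n_per_class)
  if (any(n_per_class < 1)) stop_invalid("need >= 1 patient per class")
  if (spectra_per_patient < 1) stop_invalid("spectra_per_patient must be >= 1")
  if (noise_sd < 0 || patient_effect_sd < 0 || severity_sd < 0)
    stop_invalid("all SDs must be >= 0")
  axis <- make_axis(n_points, start, end)
  er <- as.data.frame(effect_regions)
  if (nrow(er) > 0) {
    if (!all(c("lo", "hi", "effect") %in% names(er)))
      stop_invalid("effect_regions needs columns lo, hi, effect")
    if (any(er$lo < axis[1]) || any(er$hi > axis[length(axis)]) ||
        any(er$lo > er$hi))
      stop_invalid("effect region bounds must lie inside the axis range")
  }
  structure(list(
    n_per_class = n_per_class, spectra_per_patient = as.integer(spectra_per_patient),
    n_points = as.integer(n_points), start = start, end = end,
    peak_table = as.data.frame(peak_table), effect_regions = er,
    baseline_coeffs_range = baseline_coeffs_range,
    noise_sd = noise_sd, patient_effect_sd = patient_effect_sd,
    severity_sd = severity_sd, cosmic_ray_rate = cosmic_ray_rate,
    spike_amplitude = spike_amplitude,
    contaminated_patient_ids = as.character(contaminated_patient_ids),
    contamination_amplitude = contamination_amplitude,
    biomarker_model = biomarker_model,
    missing_ttau_fraction = missing_ttau_fraction,
    seed = as.integer(seed)), class = "synth_config")
}

#' Default Lorentzian peak table for a CSF protein fingerprint
#'
#' Band positions follow standard protein Raman assignments (tryptophan 758,
#' tyrosine 852, phenylalanine ring-breathing 1003, amide III 1230--1320,
#' CH2 deformation 1450, amide I 1655 cm^-1, ...).
#'
#' @return data.frame with columns `center`, `fwhm`, `amplitude`.
#' @export
default_peak_table <- function() {
  data.frame(
    center = c(758, 852, 880, 936, 998, 1003, 1007, 1031, 1080, 1126,
               1196, 1240, 1265, 1320, 1333, 1370, 1450, 1488, 1555,
               1616, 1655, 1749),
    fwhm = c(12, 10, 10, 12, 5, 5, 6, 7, 12, 10,
             10, 18, 16, 14, 8, 7, 14, 10, 12, 10, 30, 6),
    amplitude = c(0.50, 0.40, 0.30, 0.30, 0.45, 1.00, 0.40, 0.50, 0.35,
                  0.30, 0.25, 0.50, 0.45, 0.40, 0.35, 0.25, 0.70, 0.25,
                  0.20, 0.35, 0.90, 0.15))
}

#' Default class-effect regions
#'
#' Eight intervals reported as AD spectral-biomarker regions
#' (996--1001, 1003--1010, 740--771, 1328--1338, 1480--1496, 1189--1203,
#' 1366--1374, 1747--1751 cm^-1) plus two configurable placeholder regions
#' (1076--1086 and 1650--1660 cm^-1) standing in for the two features whose
#' bounds are not recoverable. Signs alternate between increased and
#' decreased area in the AD class; magnitudes default to one within-class
#' SD of the region area.
#'
#' @param effect_size magnitude applied to every region (SD units).
#' @return data.frame with columns `lo`, `hi`, `effect`.
#' @export
default_effect_regions <- function(effect_size = 1) {
  lo <- c(1003, 996, 740, 1328, 1076, 1480, 1189, 1650, 1366, 1747)
  hi <- c(1010, 1001, 771, 1338, 1086, 1496, 1203, 1660, 1374, 1751)
  sgn <- c(1, -1, 1, -1, 1, -1, 1, -1, 1, -1)
  data.frame(lo = lo, hi = hi, effect = sgn * effect_size)
}

#' @rdname synth_config
#' @export
default_baseline_range <- function() {
  cbind(lo = c(0.2, rep(-0.25, 5)), hi = c(1.0, rep(0.25, 5)))
}

#' @rdname synth_config
#' @export
default_biomarker_model <- function() {
  list(
    AD = list(abeta42 = c(meanlog = log(420), sdlog = 0.30),
              ptau = c(meanlog = log(80), sdlog = 0.35),
              total_tau = c(meanlog = log(500), sdlog = 0.35)),
    `non-AD` = list(abeta42 = c(meanlog = log(950), sdlog = 0.30),
                    ptau = c(meanlog = log(35), sdlog = 0.35),
                    total_tau = c(meanlog = log(240), sdlog = 0.40)),
    coupling = c(abeta42 = -0.5, ptau = 0.5, total_tau = 0.5))
}

# sum of Lorentzian profiles over the axis
lorentzian_template <- function(axis, peak_table) {
  y <- numeric(length(axis))
  for (i in seq_len(nrow(peak_table))) {
    g <- peak_table$fwhm[i] / 2
    y <- y + peak_table$amplitude[i] * g^2 /
      ((axis - peak_table$center[i])^2 + g^2)
  }
  y
}

# trapezoid weights for integrating over channel subset of a uniform axis
trapezoid_weights <- function(m, spacing) {
  if (m < 2) return(rep(0, m))
  w <- rep(spacing, m)
  w[c(1, m)] <- spacing / 2
  w
}

# per-region multiplicative scaling factor per unit severity, calibrated so
# a unit-severity patient shifts the raw region area by `effect` baseline
# within-class SDs (channel noise + additive patient offset)
region_scaling <- function(axis, template, regions, noise_sd,
                           patient_effect_sd) {
  spacing <- (axis[length(axis)] - axis[1]) / (length(axis) - 1)
  kappa <- numeric(nrow(regions))
  idx <- vector("list", nrow(regions))
  for (r in seq_len(nrow(regions))) {
    ch <- which(axis >= regions$lo[r] - 1e-9 & axis <= regions$hi[r] + 1e-9)
    if (length(ch) < 2)
      stop_invalid("effect region [", regions$lo[r], ", ", regions$hi[r],
                   "] covers fewer than 2 channels")
    w <- trapezoid_weights(length(ch), spacing)
    area_t <- sum(w * template[ch])
    sd0 <- sqrt(noise_sd^2 * sum(w^2) + (patient_effect_sd * sum(w))^2)
    if (area_t <= 0) stop_invalid("template area is zero inside a region")
    kappa[r] <- regions$effect[r] * sd0 / area_t
    idx[[r]] <- ch
  }
  list(kappa = kappa, idx = idx)
}

#' Closed-form class template means of a generator configuration
#'
#' Returns the noise-free expected spectrum of each class (severity at its
#' class mean: 1 for AD, 0 for non-AD), before baseline, offsets and
#' normalisation. Used to reason about where the injected class contrast
#' lives.
#'
#' @param config a [synth_config()].
#' @return list with `axis`, `base`, `AD`, `non_AD` numeric vectors.
#' @export
class_templates <- function(config) {
  axis <- make_axis(config$n_points, config$start, config$end)
  base <- lorentzian_template(axis, config$peak_table)
  ad <- base
  if (nrow(config$effect_regions) > 0) {
    sc <- region_scaling(axis, base, config$effect_regions,
                         config$noise_sd, config$patient_effect_sd)
    for (r in seq_along(sc$kappa))
      ad[sc$idx[[r]]] <- ad[sc$idx[[r]]] * (1 + sc$kappa[r])
  }
  list(axis = axis, base = base, AD = ad, non_AD = base)
}

#' Simulate a synthetic two-class CSF Raman cohort
#'
#' Draws a full cohort under the generator model of [synth_config()]:
#' patient-level severity and offsets, replicate spectra with polynomial
#' baselines, channel noise and cosmic-ray spikes, and severity-coupled
#' ATN biomarker concentrations. The same config (including seed) always
#' reproduces the identical cohort.
#'
#' @param config a [synth_config()].
#' @return list with `spectra` (a [spectrum_set()]) and `patients` (a
#'   data.frame with patient_id, diagnosis, age, sex, abeta42, ptau,
#'   total_tau, severity).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    axis <- make_axis(config$n_points, config$start, config$end)
    base <- lorentzian_template(axis, config$peak_table)
    n_ad <- config$n_per_class[1]; n_non <- config$n_per_class[2]
    n_pat <- n_ad + n_non
    ids <- sprintf("P%03d", seq_len(n_pat))
    diagnosis <- c(rep("AD", n_ad), rep("non-AD", n_non))

    sc <- NULL
    if (nrow(config$effect_regions) > 0)
      sc <- region_scaling(axis, base, config$effect_regions,
                           config$noise_sd, config$patient_effect_sd)

    sev_mean <- ifelse(diagnosis == "AD", 1, 0)
    severity <- stats::rnorm(n_pat, sev_mean, config$severity_sd)
    offset <- stats::rnorm(n_pat, 0, config$patient_effect_sd)

    nrep <- config$spectra_per_patient
    n_chan <- length(axis)
    Y <- matrix(0, n_pat * nrep, n_chan)
    x01 <- 2 * (axis - axis[1]) / (axis[n_chan] - axis[1]) - 1
    xpow <- outer(x01, 0:(nrow(config$baseline_coeffs_range) - 1), `^`)

    for (i in seq_len(n_pat)) {
      tmpl <- base
      if (!is.null(sc)) {
        for (r in seq_along(sc$kappa)) {
          f <- 1 + sc$kappa[r] * severity[i]
          tmpl[sc$idx[[r]]] <- tmpl[sc$idx[[r]]] * max(f, 0)
        }
      }
      rows <- (i - 1) * nrep + seq_len(nrep)
      rng <- config$baseline_coeffs_range
      coefs <- matrix(stats::runif(nrep * nrow(rng), rng[, 1], rng[, 2]),
                      nrow(rng), nrep)
      baselines <- t(xpow %*% coefs)
      noise <- if (config$noise_sd > 0) {
        matrix(stats::rnorm(nrep * n_chan, 0, config$noise_sd), nrep, n_chan)
      } else 0
      block <- rep(1, nrep) %o% tmpl + baselines + noise + offset[i]
      if (config$cosmic_ray_rate > 0) {
        nspk <- stats::rpois(nrep, config$cosmic_ray_rate)
        for (j in which(nspk > 0)) {
          ch <- sample.int(n_chan, nspk[j])
          block[j, ch] <- block[j, ch] +
            config$spike_amplitude * stats::runif(nspk[j], 0.5, 1.5)
        }
      }
      Y[rows, ] <- block
    }

    patients <- data.frame(
      patient_id = ids, diagnosis = diagnosis,
      age = round(stats::rnorm(n_pat, ifelse(diagnosis == "AD", 64, 68),
                               ifelse(diagnosis == "AD", 9, 11))),
      sex = ifelse(stats::runif(n_pat) <
                     ifelse(diagnosis == "AD", 0.43, 0.71), "M", "F"),
      stringsAsFactors = FALSE)

    bm <- config$biomarker_model
    zsev <- (severity - sev_mean) / max(config$severity_sd, 1e-12)
    for (marker in c("abeta42", "ptau", "total_tau")) {
      rho <- bm$coupling[[marker]]
      zin <- stats::rnorm(n_pat)
      z <- rho * zsev + sqrt(1 - rho^2) * zin
      val <- numeric(n_pat)
      for (cls in c("AD", "non-AD")) {
        par <- bm[[cls]][[marker]]
        sel <- diagnosis == cls
        val[sel] <- exp(par[["meanlog"]] + par[["sdlog"]] * z[sel])
      }
      patients[[marker]] <- val
    }
    n_miss <- round(config$missing_ttau_fraction * n_pat)
    if (n_miss > 0)
      patients$total_tau[sample.int(n_pat, n_miss)] <- NA_real_
    patients$severity <- severity

    set <- spectrum_set(Y, axis,
                        patient_id = rep(ids, each = nrep),
                        replicate = rep(seq_len(nrep), n_pat))
    if (length(config$contaminated_patient_ids) > 0)
      set <- inject_contamination(set, config$contaminated_patient_ids,
                                  config$contamination_amplitude)
    list(spectra = set, patients = patients)
  })
}

#' Inject broadband contamination into selected patients' spectra
#'
#' Adds a smooth broad Gaussian band (distinct from any fingerprint peak)
#' to every spectrum of the listed patients, emulating e.g. blood
#' contamination of a CSF sample. Other spectra are untouched.
#'
#' @param set a [spectrum_set()].
#' @param patient_ids patients to contaminate; must exist in `set`.
#' @param amplitude peak height of the contaminant band (a.u.).
#' @param center,width Gaussian band centre and SD in cm^-1.
#' @return The modified `spectrum_set`.
#' @export
inject_contamination <- function(set, patient_ids, amplitude,
                                 center = 1250, width = 200) {
  stopifnot(inherits(set, "spectrum_set"))
  patient_ids <- as.character(patient_ids)
  missing_ids <- setdiff(patient_ids, set$patient_id)
  if (length(missing_ids) > 0)
    stop_invalid("unknown patient id(s): ", paste(missing_ids, collapse = ", "))
  if (length(patient_ids) == 0) return(set)
  shape <- amplitude * exp(-0.5 * ((set$axis - center) / width)^2)
  rows <- set$patient_id %in% patient_ids
  set$intensities[rows, ] <- set$intensities[rows, , drop = FALSE] +
    rep(1, sum(rows)) %o% shape
  set
}
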