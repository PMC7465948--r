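#' Define a ground-truth analyte for simulation
#'
#' @param spectrum a [library_spectrum()] giving the component's EI mass
#'   spectrum.
#' @param retention_time apex retention time, minutes.
#' @param peak_width_sigma Gaussian peak sigma, minutes.
#' @param amount total peak area in arbitrary units.
#' @param saturation optional flat-top clipping level (counts) emulating an
#'   overloaded detector; `Inf` disables clipping.
#' @param tail_tau optional exponential tail time constant (minutes) for an
#'   exponentially-modified-Gaussian shape; 0 gives a pure Gaussian.
#' @return object of class `ground_truth_component`.
#' @export
ground_truth_component <- function(spectrum, retention_time,
                                   peak_width_sigma, amount,
                                   saturation = Inf, tail_tau = 0) {
  stopifnot(inherits(spectrum, "library_spectrum"))
  if (peak_width_sigma <= 0) stop("peak_width_sigma must be > 0")
  if (amount < 0) stop("amount must be >= 0")
  structure(
    list(spectrum = spectrum, retention_time = retention_time,
         peak_width_sigma = peak_width_sigma, amount = amount,
         saturation = saturation, tail_tau = tail_tau),
    class = "ground_truth_component"
  )
}

#' Define a chromatogram simulation
#'
#' Defaults mirror a quadrupole EI full-scan acquisition: 3.6 scans/s and
#' an m/z 50--450 scan range.
#'
#' @param run_length run duration in minutes.
#' @param run_start time of the first scan, minutes (default 0).
#' @param scan_rate scans per second (default 3.6).
#' @param mz_range length-2 integer vector, inclusive m/z range
#'   (default c(50, 450)).
#' @param components list of [ground_truth_component()] analytes.
#' @param baseline_level constant background level, counts.
#' @param noise_sd additive Gaussian noise sd, counts (clamped at 0).
#' @param matrix_components optional broad/overloaded interferents, same
#'   type as `components`.
#' @param rng_seed integer seed; simulation is deterministic given it.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(run_length, run_start = 0, scan_rate = 3.6,
                            mz_range = c(50L, 450L), components = list(),
                            baseline_level = 0, noise_sd = 0,
                            matrix_components = list(), rng_seed = 1L) {
  if (scan_rate <= 0) stop("scan_rate must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (run_length <= 0) stop("run_length must be > 0")
  structure(
    list(run_length = run_length, run_start = run_start,
         scan_rate = scan_rate, mz_range = as.integer(mz_range),
         components = components, baseline_level = baseline_level,
         noise_sd = noise_sd, matrix_components = matrix_components,
         rng_seed = as.integer(rng_seed)),
    class = "simulation_spec"
  )
}

# peak shape evaluated at scan times; EMG when tau > 0, else Gaussian,
# scaled so the continuous-time area equals `amount`
peak_profile <- function(times, rt, sigma, amount, tau, dt) {
  if (tau > 0) {
    # EMG density via the standard erfc form
    z <- (sigma / tau - (times - rt) / sigma) / sqrt(2)
    dens <- exp(sigma^2 / (2 * tau^2) - (times - rt) / tau) *
      pracma::erfc(z) / (2 * tau)
  } else {
    dens <- stats::dnorm(times, rt, sigma)
  }
  amount * dens * dt
}

#' Simulate a GC/MS scan chromatogram with known ground truth
#'
#' Each component contributes `amount x Gaussian(t; rt, sigma)` (area-
#' normalized, so per-scan values are density x scan spacing) outer-
#' multiplied with its unit-normalized spectrum. A constant baseline and
#' i.i.d. Gaussian noise (clamped at zero) are added. Matrix interferents
#' are handled identically, with optional flat-top clipping at their
#' saturation level applied to the summed signal.
#'
#' @param spec a [simulation_spec()].
#' @return list with elements `chromatogram` (a [chromatogram()]) and
#'   `truth` (manifest: per-component name, rt, amount, scan span, and the
#'   per-scan elution profile matrix).
#' @export
simulate_chromatogram <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  dt <- 1 / (spec$scan_rate * 60)           # scan spacing, minutes
  times <- seq(spec$run_start, spec$run_start + spec$run_length, by = dt)
  mz_axis <- seq.int(spec$mz_range[1], spec$mz_range[2])
  I <- length(times); J <- length(mz_axis)
  all_comp <- c(spec$components, spec$matrix_components)
  mat <- matrix(0, I, J)
  profiles <- matrix(0, I, length(all_comp))
  for (ci in seq_along(all_comp)) {
    comp <- all_comp[[ci]]
    if (comp$retention_time < min(times) || comp$retention_time > max(times)) {
      stop(sprintf("component '%s' retention time %.3f min outside run span",
                   comp$spectrum$name, comp$retention_time))
    }
    prof <- peak_profile(times, comp$retention_time, comp$peak_width_sigma,
                         comp$amount, comp$tail_tau, dt)
    svec <- numeric(J)
    keep <- comp$spectrum$mz >= mz_axis[1] & comp$spectrum$mz <= mz_axis[J]
    svec[comp$spectrum$mz[keep] - mz_axis[1] + 1L] <- comp$spectrum$intensity[keep]
    if (sum(svec) > 0) svec <- svec / sum(svec)
    contrib <- outer(prof, svec)
    if (is.finite(comp$saturation)) {
      contrib <- pmin(contrib, comp$saturation)
    }
    mat <- mat + contrib
    profiles[, ci] <- prof
  }
  mat <- mat + spec$baseline_level
  if (spec$noise_sd > 0) {
    set.seed(spec$rng_seed)
    mat <- mat + matrix(stats::rnorm(I * J, 0, spec$noise_sd), I, J)
    mat[mat < 0] <- 0
  }
  truth <- list(
    components = lapply(seq_along(all_comp), function(ci) {
      comp <- all_comp[[ci]]
      span <- range(which(profiles[, ci] > 1e-12 * max(profiles[, ci])))
      list(name = comp$spectrum$name, retention_time = comp$retention_time,
           amount = comp$amount, scan_span = span)
    }),
    profiles = profiles,
    scan_times = times, mz_axis = mz_axis, rng_seed = spec$rng_seed
  )
  meta <- list(simulated = "true", scan_rate = format(spec$scan_rate),
               rng_seed = format(spec$rng_seed))
  list(chromatogram = chromatogram(times, mz_axis, mat, meta), truth = truth)
}

#' Cosine similarity between two centroided spectra
#'
#' Computed on the union m/z grid of the two spectra (unweighted).
#'
#' @param a,b [library_spectrum()] objects, or numeric vectors named by m/z.
#' @return cosine similarity in [0, 1].
#' @export
spectrum_cosine <- function(a, b) {
  va <- spectrum_as_vector(a); vb <- spectrum_as_vector(b)
  grid <- sort(unique(c(as.integer(names(va)), as.integer(names(vb)))))
  da <- db <- numeric(length(grid))
  da[match(as.integer(names(va)), grid)] <- va
  db[match(as.integer(names(vb)), grid)] <- vb
  na <- sqrt(sum(da^2)); nb <- sqrt(sum(db^2))
  if (na == 0 || nb == 0) stop("cosine undefined for an all-zero spectrum")
  sum(da * db) / (na * nb)
}

# coerce a library_spectrum or named vector to an m/z-named numeric vector
spectrum_as_vector <- function(x) {
  if (inherits(x, "library_spectrum")) {
    stats::setNames(as.numeric(x$intensity), x$mz)
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else {
    stop("expected a library_spectrum or an m/z-named numeric vector")
  }
}
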