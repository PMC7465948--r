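#' Replicate-generation parameters
#'
#' One pseudo-replicate is described by a signed retention-time offset and
#' a positive intensity multiplier. Multipliers are normally drawn in
#' [0.5, 1.5] and offsets in [-0.003, 0.003] min (sub-scan at 3.6 scans/s,
#' where one scan is about 0.0046 min); values outside the multiplier band
#' are accepted with a warning.
#'
#' @param rt_offset signed retention-time offset, minutes.
#' @param multiplier positive intensity scale factor.
#' @return object of class `replicate_spec`.
#' @export
replicate_spec <- function(rt_offset, multiplier) {
  if (multiplier <= 0) stop("multiplier must be > 0")
  if (multiplier < 0.5 || multiplier > 1.5) {
    warning(sprintf("multiplier %.5f outside the usual [0.5, 1.5] band",
                    multiplier))
  }
  structure(list(rt_offset = as.numeric(rt_offset),
                 multiplier = as.numeric(multiplier)),
            class = "replicate_spec")
}

#' Scale all intensities by a constant factor
#'
#' @param x a [chromatogram()].
#' @param factor positive multiplier.
#' @return a `chromatogram` with every intensity scaled; scan times
#'   unchanged.
#' @export
multiply_chrom <- function(x, factor) {
  stopifnot(inherits(x, "chromatogram"))
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
    stop("factor must be a single positive number")
  }
  x$intensities <- x$intensities * factor
  x
}

#' Shift a chromatogram in retention time by a sub-scan offset
#'
#' The signal is translated by `offset` minutes and resampled back onto
#' the ORIGINAL scan-time grid by per-channel linear interpolation, so the
#' result stays co-registered with the input (same scan count and times).
#' Out-of-range regions hold the edge scan's value.
#'
#' @param x a [chromatogram()].
#' @param offset signed shift in minutes; positive moves peaks to later
#'   times. Magnitude must be smaller than the run span.
#' @return shifted `chromatogram`.
#' @export
shift_rt <- function(x, offset) {
  stopifnot(inherits(x, "chromatogram"))
  span <- diff(range(x$scan_times))
  if (abs(offset) >= span) stop("offset magnitude must be below the run span")
  if (offset == 0) return(x)
  # value at original time t comes from the unshifted signal at t - offset
  tq <- x$scan_times - offset
  I <- length(x$scan_times)
  lo <- findInterval(tq, x$scan_times, rightmost.closed = FALSE)
  lo <- pmin(pmax(lo, 1L), I - 1L)
  hi <- lo + 1L
  w <- (tq - x$scan_times[lo]) / (x$scan_times[hi] - x$scan_times[lo])
  w <- pmin(pmax(w, 0), 1)  # edge hold
  x$intensities <- x$intensities[lo, , drop = FALSE] * (1 - w) +
    x$intensities[hi, , drop = FALSE] * w
  x
}

#' Savitzky-Golay denoising of every m/z channel
#'
#' Per-channel smoothing with the given window and polynomial order
#' (defaults 5 scans, order 2), clamped at zero. Polynomials of degree at
#' most the filter order pass through unchanged.
#'
#' @param x a [chromatogram()].
#' @param window odd filter length in scans (default 5).
#' @param order polynomial order (default 2).
#' @return denoised `chromatogram`; metadata notes the filter.
#' @export
denoise_chrom <- function(x, window = 5L, order = 2L) {
  stopifnot(inherits(x, "chromatogram"))
  if (nrow(x$intensities) < window) {
    stop(sprintf("need at least %d scans for the denoising window", window))
  }
  sm <- apply(x$intensities, 2, function(col) {
    signal::sgolayfilt(col, p = order, n = window)
  })
  sm[sm < 0] <- 0
  x$intensities <- sm
  x$metadata$denoised <- sprintf("savitzky-golay(%d,%d)", window, order)
  x
}

#' Build a five-member pseudo-replicate set from one chromatogram
#'
#' Member 0 is the original; member k+1 is
#' `shift_rt(multiply_chrom(x, m_k), d_k)`, optionally denoised. PARAFAC2
#' needs at least five samples with independent variation, so at least
#' four replicate specs are required (or a seed from which they are drawn:
#' multiplier ~ Uniform[0.5, 1.5], offset ~ Uniform[-0.003, 0.003] min).
#'
#' @param x a [chromatogram()].
#' @param specs list of [replicate_spec()] (>= 4), or `NULL` to draw
#'   `n_replicates` specs using `rng_seed`.
#' @param n_replicates number of derived members when drawing specs
#'   (default 4).
#' @param denoise logical; apply [denoise_chrom()] to every member.
#' @param rng_seed integer seed for drawn specs.
#' @return object of class `replicate_set`: list with `members` (list of
#'   K chromatograms, member 1 = original) and `specs`.
#' @export
make_replicate_set <- function(x, specs = NULL, n_replicates = 4L,
                               denoise = FALSE, rng_seed = NULL) {
  stopifnot(inherits(x, "chromatogram"))
  if (is.null(specs)) {
    if (is.null(rng_seed)) {
      stop(paste("supply >= 4 replicate specs or an rng_seed:",
                 "PARAFAC2 requires at least five chromatograms"))
    }
    if (n_replicates < 4L) {
      stop("at least 4 derived members are required for a five-member set")
    }
    set.seed(rng_seed)
    specs <- replicate(n_replicates, replicate_spec(
      rt_offset = stats::runif(1, -0.003, 0.003),
      multiplier = stats::runif(1, 0.5, 1.5)), simplify = FALSE)
  }
  if (length(specs) < 4L) {
    stop(paste("got", length(specs), "replicate specs; at least 4 are",
               "needed so the set reaches the five-chromatogram minimum"))
  }
  stopifnot(all(vapply(specs, inherits, logical(1), "replicate_spec")))
  members <- vector("list", length(specs) + 1L)
  members[[1L]] <- x
  for (k in seq_along(specs)) {
    members[[k + 1L]] <- shift_rt(multiply_chrom(x, specs[[k]]$multiplier),
                                  specs[[k]]$rt_offset)
  }
  if (denoise) members <- lapply(members, denoise_chrom)
  structure(list(members = members, specs = specs),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("replicate_set: %d members (1 original + %d derived)\n",
              length(x$members), length(x$specs)))
  for (k in seq_along(x$specs)) {
    cat(sprintf("  member %d: offset %+.5f min, multiplier %.5f\n",
                k + 1L, x$specs[[k]]$rt_offset, x$specs[[k]]$multiplier))
  }
  invisible(x)
}

#' Applied multipliers of a replicate set
#'
#' @param set a `replicate_set`.
#' @return numeric vector of length K: 1 for the original followed by the
#'   recorded multipliers.
#' @export
set_multipliers <- function(set) {
  stopifnot(inherits(set, "replicate_set"))
  c(1, vapply(set$specs, `[[`, numeric(1), "multiplier"))
}
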