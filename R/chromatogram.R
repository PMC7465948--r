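#' Construct a GC/MS chromatogram
#'
#' A chromatogram is a dense scan-time-by-m/z intensity matrix on a
#' unit-spaced integer m/z grid, plus free-form acquisition metadata.
#' Negative intensities (which occur in some vendor exports after baseline
#' subtraction) are clamped to zero with a warning, since the downstream
#' PARAFAC2 model assumes non-negative data.
#'
#' @param scan_times numeric vector of scan acquisition times in minutes,
#'   strictly increasing, length I >= 2.
#' @param mz_axis strictly increasing integer m/z bins, length J >= 2
#'   (quadrupole unit resolution; default grid is 50--450).
#' @param intensities numeric I x J matrix of ion counts.
#' @param metadata named list of free-form strings (instrument, sample id,
#'   scan rate, ...).
#' @return An object of class `chromatogram` with elements `scan_times`,
#'   `mz_axis`, `intensities`, `metadata`.
#' @examples
#' ch <- chromatogram(c(1, 1.01, 1.02), 50:52, matrix(1, 3, 3))
#' tic(ch)
#' @export
chromatogram <- function(scan_times, mz_axis, intensities,
                         metadata = list()) {
  scan_times <- as.numeric(scan_times)
  mz_axis <- as.integer(round(mz_axis))
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (length(scan_times) < 2L) stop("chromatogram needs at least 2 scans")
  if (length(mz_axis) < 2L) stop("chromatogram needs at least 2 m/z bins")
  if (any(diff(scan_times) <= 0)) stop("scan_times must be strictly increasing")
  if (any(diff(mz_axis) <= 0)) stop("mz_axis must be strictly increasing")
  if (nrow(intensities) != length(scan_times) ||
      ncol(intensities) != length(mz_axis)) {
    stop("intensities must be length(scan_times) x length(mz_axis)")
  }
  n_neg <- sum(intensities < 0)
  if (n_neg > 0) {
    warning(sprintf("clamped %d negative intensity value(s) to 0", n_neg))
    intensities[intensities < 0] <- 0
  }
  dimnames(intensities) <- NULL
  structure(
    list(scan_times = scan_times, mz_axis = mz_axis,
         intensities = intensities, metadata = metadata),
    class = "chromatogram"
  )
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf(
    "GC/MS chromatogram: %d scans (%.3f-%.3f min), m/z %d-%d (%d bins)\n",
    length(x$scan_times), min(x$scan_times), max(x$scan_times),
    min(x$mz_axis), max(x$mz_axis), length(x$mz_axis)))
  if (length(x$metadata)) {
    cat("metadata:", paste(names(x$metadata), unlist(x$metadata),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Total ion chromatogram
#'
#' @param x a `chromatogram`.
#' @return numeric vector, per-scan sum over all m/z bins.
#' @export
tic <- function(x) {
  stopifnot(inherits(x, "chromatogram"))
  rowSums(x$intensities)
}

#' Write a chromatogram as dense CSV
#'
#' Internal human-inspectable dialect: header row `time` followed by the
#' integer m/z bins; one row per scan, first column the scan time in
#' minutes.
#'
#' @param x a `chromatogram`.
#' @param path output file path.
#' @export
write_chrom_csv <- function(x, path) {
  stopifnot(inherits(x, "chromatogram"))
  df <- data.frame(time = x$scan_times, x$intensities, check.names = FALSE)
  names(df) <- c("time", x$mz_axis)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(NULL)
}

#' Read a dense-CSV chromatogram
#'
#' @param path file written by [write_chrom_csv()].
#' @return a `chromatogram`.
#' @export
read_chrom_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time") stop("dense CSV must start with a 'time' column")
  chromatogram(df[[1]], as.integer(names(df)[-1]),
               as.matrix(df[, -1, drop = FALSE]))
}
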