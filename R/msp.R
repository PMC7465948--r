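#' Construct a library (reference) mass spectrum
#'
#' Centroided reference spectrum on integer m/z, normalized so the base
#' peak has intensity 999 (the NIST convention). Normalization is
#' idempotent.
#'
#' @param name compound label.
#' @param mz integer m/z values (unique).
#' @param intensity non-negative intensities; rescaled to base peak 999.
#' @param retention_time optional retention time in minutes.
#' @return object of class `library_spectrum` with fields `name`, `mz`,
#'   `intensity`, `retention_time`.
#' @export
library_spectrum <- function(name, mz, intensity, retention_time = NA_real_) {
  mz <- as.integer(round(mz))
  intensity <- as.numeric(intensity)
  if (length(mz) < 1L) stop("spectrum needs at least one peak")
  if (length(mz) != length(intensity)) stop("mz/intensity length mismatch")
  if (anyDuplicated(mz)) stop("m/z values must be unique")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (max(intensity) <= 0) stop("spectrum must have a nonzero base peak")
  o <- order(mz)
  structure(
    list(name = as.character(name), mz = mz[o],
         intensity = round(intensity[o] / max(intensity) * 999),
         retention_time = as.numeric(retention_time)),
    class = "library_spectrum"
  )
}

#' @export
print.library_spectrum <- function(x, ...) {
  cat(sprintf("library_spectrum '%s': %d peaks, base m/z %d%s\n",
              x$name, length(x$mz), x$mz[which.max(x$intensity)],
              if (is.finite(x$retention_time))
                sprintf(", RT %.2f min", x$retention_time) else ""))
  invisible(x)
}

#' Parse a NIST MSP spectral library
#'
#' Reads the MSP text dialect: entries start with `Name:`, carry a
#' `Num Peaks:` count, and list `m/z intensity` pairs separated by
#' semicolons or whitespace. Each spectrum is renormalized to base peak
#' 999; entry order is preserved.
#'
#' @param path MSP file path.
#' @return list of [library_spectrum()] objects (possibly empty).
#' @export
read_msp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  name <- NULL; rt <- NA_real_; npk <- NA_integer_; pair_txt <- character(0)
  flush_entry <- function() {
    if (is.null(name)) return(invisible(NULL))
    toks <- unlist(strsplit(paste(pair_txt, collapse = " "), "[;,[:space:]]+"))
    toks <- toks[nzchar(toks)]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals) || length(vals) %% 2 != 0) {
      stop(sprintf("malformed peak list in MSP entry '%s'", name))
    }
    mz <- vals[c(TRUE, FALSE)]; inten <- vals[c(FALSE, TRUE)]
    if (!is.na(npk) && length(mz) != npk) {
      stop(sprintf("MSP entry '%s': Num Peaks %d but %d pairs listed",
                   name, npk, length(mz)))
    }
    out[[length(out) + 1L]] <<- library_spectrum(name, mz, inten, rt)
    invisible(NULL)
  }
  in_peaks <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (grepl("^Name:", ln, ignore.case = TRUE)) {
      flush_entry()
      name <- trimws(sub("^Name:", "", ln, ignore.case = TRUE))
      rt <- NA_real_; npk <- NA_integer_; pair_txt <- character(0)
      in_peaks <- FALSE
    } else if (grepl("^Num Peaks:", ln, ignore.case = TRUE)) {
      npk <- as.integer(trimws(sub("^Num Peaks:", "", ln, ignore.case = TRUE)))
      in_peaks <- TRUE
    } else if (grepl("^(Retention_?time|RT):", ln, ignore.case = TRUE)) {
      rt <- as.numeric(trimws(sub("^[^:]+:", "", ln)))
    } else if (in_peaks && nzchar(ln)) {
      pair_txt <- c(pair_txt, ln)
    } else if (!nzchar(ln)) {
      next
    }
    # other header fields (Formula:, MW:, Comment:, ...) are ignored
  }
  flush_entry()
  out
}

#' Write spectra to an MSP file
#'
#' @param spectra list of [library_spectrum()] objects.
#' @param path output file path.
#' @export
write_msp <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(sprintf("Name: %s", sp$name), con)
    if (is.finite(sp$retention_time)) {
      writeLines(sprintf("Retention_time: %g", sp$retention_time), con)
    }
    writeLines(sprintf("Num Peaks: %d", length(sp$mz)), con)
    writeLines(paste(sprintf("%d %g;", sp$mz, sp$intensity), collapse = " "), con)
    writeLines("", con)
  }
  invisible(NULL)
}
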