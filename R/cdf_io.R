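#' Read an ANDI/AIA netCDF (CDF) mass-spectrometry file
#'
#' Reads the ANDI-MS variable set (`scan_acquisition_time`, `scan_index`,
#' `point_count`, `mass_values`, `intensity_values`) and bins the sparse
#' per-scan peak lists onto a unit-spaced integer m/z grid spanning the
#' observed (rounded) m/z range.  m/z values are rounded to the nearest
#' integer; collisions within a scan are summed, so total ion current is
#' conserved.  Scan times are converted from seconds to minutes.
#'
#' @param path path to a CDF file.
#' @return a [chromatogram()].
#' @export
read_cdf <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  need <- c("scan_acquisition_time", "scan_index", "point_count",
            "mass_values", "intensity_values")
  have <- names(nc$var)
  missing <- setdiff(need, have)
  if (length(missing)) {
    stop(sprintf("not an ANDI-MS file: missing variable(s) %s",
                 paste(missing, collapse = ", ")))
  }
  scan_time_s <- as.numeric(ncdf4::ncvar_get(nc, "scan_acquisition_time"))
  point_count <- as.integer(ncdf4::ncvar_get(nc, "point_count"))
  n_scans <- length(scan_time_s)
  if (n_scans == 0L) stop("CDF file contains zero scans")
  total_pts <- sum(point_count)
  if (total_pts > 0L) {
    mass_values <- as.numeric(ncdf4::ncvar_get(nc, "mass_values"))
    intensity_values <- as.numeric(ncdf4::ncvar_get(nc, "intensity_values"))
    mass_values <- mass_values[seq_len(total_pts)]
    intensity_values <- intensity_values[seq_len(total_pts)]
    mz_int <- as.integer(round(mass_values))
    mz_lo <- min(mz_int); mz_hi <- max(mz_int)
  } else {
    # all-empty scans: fall back to the instrument's stated range if present
    mz_lo <- 50L; mz_hi <- 51L
    mz_int <- integer(0); intensity_values <- numeric(0)
  }
  mz_axis <- seq.int(mz_lo, max(mz_hi, mz_lo + 1L))
  J <- length(mz_axis)
  mat <- matrix(0, n_scans, J)
  if (total_pts > 0L) {
    scan_of_point <- rep.int(seq_len(n_scans), point_count)
    idx <- (mz_int - mz_lo) * n_scans + scan_of_point
    acc <- vapply(split(intensity_values, idx), sum, numeric(1))
    mat[as.integer(names(acc))] <- acc
  }
  meta <- list(source = basename(path))
  chromatogram(scan_time_s / 60, mz_axis, mat, meta)
}

#' Write a chromatogram as an ANDI/AIA netCDF (CDF) file
#'
#' Emits the ANDI-MS variable set; zero-intensity bins are omitted from
#' each scan's peak list.  Scan times are stored in seconds per the ANDI
#' convention.  The written file round-trips through [read_cdf()] with
#' intensities preserved exactly (unit m/z grid) and scan times to
#' numerical precision.
#'
#' @param x a [chromatogram()].
#' @param path output path.
#' @export
write_cdf <- function(x, path) {
  stopifnot(inherits(x, "chromatogram"))
  I <- nrow(x$intensities)
  nz <- x$intensities > 0
  point_count <- as.integer(rowSums(nz))
  total_pts <- sum(point_count)
  scan_dim <- ncdf4::ncdim_def("scan_number", "", seq_len(I),
                               create_dimvar = FALSE)
  pt_dim <- ncdf4::ncdim_def("point_number", "",
                             seq_len(max(total_pts, 1L)),
                             create_dimvar = FALSE)
  vars <- list(
    ncdf4::ncvar_def("scan_acquisition_time", "seconds", scan_dim, prec = "double"),
    ncdf4::ncvar_def("scan_index", "", scan_dim, prec = "integer"),
    ncdf4::ncvar_def("point_count", "", scan_dim, prec = "integer"),
    ncdf4::ncvar_def("mass_values", "m/z", pt_dim, prec = "double"),
    ncdf4::ncvar_def("intensity_values", "counts", pt_dim, prec = "double")
  )
  nc <- tryCatch(ncdf4::nc_create(path, vars),
                 error = function(e) stop(sprintf("cannot write CDF '%s': %s",
                                                  path, conditionMessage(e))))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, "scan_acquisition_time", x$scan_times * 60)
  ncdf4::ncvar_put(nc, "scan_index",
                   as.integer(cumsum(c(0L, point_count[-I]))))
  ncdf4::ncvar_put(nc, "point_count", point_count)
  if (total_pts > 0L) {
    tnz <- t(nz)  # column-major over scans
    mz_all <- rep(x$mz_axis, times = I)[as.vector(tnz)]
    int_all <- t(x$intensities)[tnz]
    ncdf4::ncvar_put(nc, "mass_values", mz_all, count = total_pts)
    ncdf4::ncvar_put(nc, "intensity_values", int_all, count = total_pts)
  } else {
    ncdf4::ncvar_put(nc, "mass_values", 0, count = 1)
    ncdf4::ncvar_put(nc, "intensity_values", 0, count = 1)
  }
  invisible(NULL)
}
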