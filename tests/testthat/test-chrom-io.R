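test_that("chromatogram constructor validates and clamps negatives", {
  expect_error(chromatogram(c(1, 1), 50:51, matrix(0, 2, 2)),
               "strictly increasing")
  expect_error(chromatogram(c(1, 2), c(51, 50), matrix(0, 2, 2)),
               "strictly increasing")
  expect_error(chromatogram(c(1, 2), 50:51, matrix(0, 3, 2)))
  expect_warning(
    ch <- chromatogram(c(1, 2), 50:51, matrix(c(-1, 2, 3, 4), 2, 2)),
    "clamped 1 negative")
  expect_true(all(ch$intensities >= 0))
})

test_that("dense CSV dialect round-trips", {
  ch <- sim_single()$chromatogram
  path <- withr::local_tempfile(fileext = ".csv")
  write_chrom_csv(ch, path)
  back <- read_chrom_csv(path)
  expect_equal(back$mz_axis, ch$mz_axis)
  expect_equal(back$scan_times, ch$scan_times, tolerance = 1e-12)
  expect_equal(back$intensities, ch$intensities, tolerance = 1e-12)
})

test_that("CDF round-trip is lossless on the unit grid", {
  ch <- sim_single()$chromatogram
  path <- withr::local_tempfile(fileext = ".cdf")
  write_cdf(ch, path)
  back <- read_cdf(path)
  expect_equal(length(back$scan_times), length(ch$scan_times))
  expect_equal(back$scan_times, ch$scan_times, tolerance = 1e-9)
  # the file's m/z axis spans only the observed range; compare there
  keep <- ch$mz_axis %in% back$mz_axis
  expect_equal(back$intensities, ch$intensities[, keep], tolerance = 1e-12)
  # total ion current per scan conserved exactly
  expect_equal(rowSums(back$intensities), tic(ch), tolerance = 1e-12)
})

test_that("CDF reader bins non-integer m/z onto the unit grid", {
  # write a minimal ANDI file by hand: 3 scans, one peak at m/z 100.2 in
  # scan 2, plus a far point fixing the observed range at 50.0-110.4
  path <- withr::local_tempfile(fileext = ".cdf")
  scan_dim <- ncdf4::ncdim_def("scan_number", "", 1:3, create_dimvar = FALSE)
  pt_dim <- ncdf4::ncdim_def("point_number", "", 1:3, create_dimvar = FALSE)
  vars <- list(
    ncdf4::ncvar_def("scan_acquisition_time", "seconds", scan_dim, prec = "double"),
    ncdf4::ncvar_def("scan_index", "", scan_dim, prec = "integer"),
    ncdf4::ncvar_def("point_count", "", scan_dim, prec = "integer"),
    ncdf4::ncvar_def("mass_values", "m/z", pt_dim, prec = "double"),
    ncdf4::ncvar_def("intensity_values", "counts", pt_dim, prec = "double"))
  nc <- ncdf4::nc_create(path, vars)
  ncdf4::ncvar_put(nc, "scan_acquisition_time", c(60, 61, 62))
  ncdf4::ncvar_put(nc, "scan_index", c(0L, 1L, 3L))
  ncdf4::ncvar_put(nc, "point_count", c(1L, 2L, 0L))
  ncdf4::ncvar_put(nc, "mass_values", c(50.0, 100.2, 110.4))
  ncdf4::ncvar_put(nc, "intensity_values", c(1, 5, 2))
  ncdf4::nc_close(nc)

  ch <- read_cdf(path)
  expect_equal(ch$mz_axis, 50:110)          # floor/ceil of rounded range
  expect_equal(ch$scan_times, c(1, 61 / 60, 62 / 60))
  expect_equal(ch$intensities[2, ch$mz_axis == 100], 5)
  expect_equal(ch$intensities[2, ch$mz_axis == 110], 2)
  expect_equal(sum(ch$intensities), 8)      # binning conserves TIC
})

test_that("CDF reader names missing ANDI variables", {
  path <- withr::local_tempfile(fileext = ".cdf")
  d <- ncdf4::ncdim_def("scan_number", "", 1:2, create_dimvar = FALSE)
  v <- ncdf4::ncvar_def("scan_acquisition_time", "s", d, prec = "double")
  nc <- ncdf4::nc_create(path, list(v))
  ncdf4::ncvar_put(nc, v, c(1, 2))
  ncdf4::nc_close(nc)
  expect_error(read_cdf(path), "mass_values")
})

test_that("all-zero chromatogram round-trips through CDF", {
  ch <- chromatogram(c(1, 1.01, 1.02), 50:55, matrix(0, 3, 6))
  path <- withr::local_tempfile(fileext = ".cdf")
  write_cdf(ch, path)
  back <- read_cdf(path)
  expect_equal(nrow(back$intensities), 3)
  expect_true(all(back$intensities == 0))
})

test_that("replicate set written as CDF files re-reads co-registered", {
  rs <- make_replicate_set(sim_single()$chromatogram, fixed_specs())
  dir <- withr::local_tempdir()
  paths <- file.path(dir, sprintf("member%d.cdf", seq_along(rs$members)))
  for (k in seq_along(rs$members)) write_cdf(rs$members[[k]], paths[k])
  back <- lapply(paths, read_cdf)
  expect_true(all(vapply(back, function(b)
    identical(dim(b$intensities), dim(back[[1]]$intensities)), logical(1))))
  for (k in seq_along(back)) {
    expect_equal(back[[k]]$scan_times, rs$members[[k]]$scan_times,
                 tolerance = 1e-9)
  }
})

test_that("MSP parsing normalizes, preserves order, and validates counts", {
  path <- withr::local_tempfile(fileext = ".msp")
  writeLines(c(
    "Name: first",
    "Formula: C6H6",
    "Num Peaks: 2",
    "100 50; 120 100;",
    "",
    "Name: second",
    "Num Peaks: 1",
    "77 10"), path)
  lib <- read_msp(path)
  expect_length(lib, 2)
  expect_equal(vapply(lib, `[[`, character(1), "name"), c("first", "second"))
  expect_equal(lib[[1]]$intensity, c(round(50 / 100 * 999), 999))
  expect_equal(lib[[1]]$intensity[1], 500)
  expect_equal(lib[[2]]$intensity, 999)

  # normalization is idempotent
  renorm <- library_spectrum(lib[[1]]$name, lib[[1]]$mz, lib[[1]]$intensity)
  expect_equal(renorm$intensity, lib[[1]]$intensity)

  bad <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("Name: broken", "Num Peaks: 3", "100 50; 120 100;"), bad)
  expect_error(read_msp(bad), "broken")

  empty <- withr::local_tempfile(fileext = ".msp")
  writeLines(character(0), empty)
  expect_length(read_msp(empty), 0)
})

test_that("write_msp round-trips through read_msp", {
  lib <- list(spec_a(), spec_hepta())
  path <- withr::local_tempfile(fileext = ".msp")
  write_msp(lib, path)
  back <- read_msp(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$mz, lib[[1]]$mz)
  expect_equal(back[[1]]$intensity, lib[[1]]$intensity)
  expect_equal(back[[2]]$retention_time, 8.50)
})

test_that("bundled synthetic MSP library loads", {
  lib <- read_msp(system.file("extdata", "synthetic_library.msp",
                              package = "gcdeconv"))
  expect_length(lib, 5)
  expect_true(all(vapply(lib, function(s) max(s$intensity) == 999, logical(1))))
})
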