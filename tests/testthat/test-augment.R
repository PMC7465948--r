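test_that("multiply scales every cell exactly and rejects bad factors", {
  ch <- chromatogram(c(1, 2), 50:51, matrix(c(10, 30, 20, 0), 2, 2))
  expect_identical(multiply_chrom(ch, 1.0)$intensities, ch$intensities)
  expect_equal(multiply_chrom(ch, 0.5)$intensities,
               matrix(c(5, 15, 10, 0), 2, 2))
  one_cell <- chromatogram(c(1, 2), 50:51, matrix(c(1000, 0, 0, 0), 2, 2))
  expect_equal(multiply_chrom(one_cell, 1.99866)$intensities[1, 1], 1998.66)
  expect_error(multiply_chrom(ch, 0), "positive")
  expect_error(multiply_chrom(ch, -1), "positive")
})

test_that("multiply preserves spectral shape at every scan", {
  ch <- sim_single()$chromatogram
  scaled <- multiply_chrom(ch, 1.3)
  i <- which.max(tic(ch))
  q1 <- ch$intensities[i, ]; q2 <- scaled$intensities[i, ]
  names(q1) <- names(q2) <- ch$mz_axis
  expect_equal(spectrum_cosine(q1[q1 > 0], q2[q2 > 0]), 1, tolerance = 1e-12)
})

test_that("shift_rt moves the TIC apex by the offset and is near-invertible", {
  ch <- sim_single()$chromatogram
  dt <- diff(ch$scan_times[1:2])
  expect_identical(shift_rt(ch, 0)$intensities, ch$intensities)

  sh <- shift_rt(ch, 0.003)
  apex0 <- ch$scan_times[which.max(tic(ch))]
  apex1 <- sh$scan_times[which.max(tic(sh))]
  expect_lt(abs(apex1 - (apex0 + 0.003)), dt + 1e-12)
  # scan grid is unchanged (co-registration)
  expect_identical(sh$scan_times, ch$scan_times)

  # shift(+d) then shift(-d) restores interior cells within the linear-
  # interpolation error bound (max local second difference x d^2 scale)
  back <- shift_rt(sh, -0.003)
  interior <- 3:(nrow(ch$intensities) - 2)
  d2 <- abs(diff(ch$intensities, differences = 2))
  bound <- max(d2) * (0.003 / dt)^2 + 1e-9
  expect_lt(max(abs(back$intensities[interior, ] - ch$intensities[interior, ])),
            bound)

  expect_error(shift_rt(ch, 10), "run span")
})

test_that("shift_rt conserves total signal for interior peaks within 0.1%", {
  ch <- sim_single()$chromatogram
  for (d in c(-0.003, 0.0015, 0.003)) {
    expect_equal(sum(shift_rt(ch, d)$intensities), sum(ch$intensities),
                 tolerance = 0.001)
  }
})

test_that("Savitzky-Golay denoise reproduces low-degree polynomials and cuts noise", {
  times <- seq(0, 1, length.out = 41)
  const <- chromatogram(times, 50:51, matrix(7, 41, 2))
  expect_equal(denoise_chrom(const)$intensities, const$intensities,
               tolerance = 1e-9)
  ramp <- chromatogram(times, 50:51, cbind(seq(0, 40), seq(40, 0)))
  expect_equal(denoise_chrom(ramp)$intensities, ramp$intensities,
               tolerance = 1e-9)
  set.seed(42)
  noisy <- chromatogram(times, 50:51, matrix(abs(rnorm(82, 100, 10)), 41, 2))
  sm <- denoise_chrom(noisy)
  expect_lt(var(sm$intensities[, 1]), var(noisy$intensities[, 1]))
  expect_error(denoise_chrom(chromatogram(1:3, 50:51, matrix(1, 3, 2))),
               "scans")
})

test_that("make_replicate_set builds a five-member co-registered set", {
  ch <- sim_single()$chromatogram
  rs <- make_replicate_set(ch, fixed_specs())
  expect_s3_class(rs, "replicate_set")
  expect_length(rs$members, 5)
  expect_true(all(vapply(rs$members, function(m)
    identical(m$mz_axis, ch$mz_axis) &&
      identical(m$scan_times, ch$scan_times), logical(1))))

  expect_error(make_replicate_set(ch, fixed_specs()[1:3]), "five")
  expect_error(make_replicate_set(ch), "five")

  ident <- replicate(4, replicate_spec(0, 1.0), simplify = FALSE)
  rs0 <- make_replicate_set(ch, ident)
  for (k in 2:5) expect_equal(rs0$members[[k]]$intensities, ch$intensities)
})

test_that("member TIC sums scale by the recorded multipliers", {
  ch <- sim_single()$chromatogram
  rs <- make_replicate_set(ch, fixed_specs())
  s0 <- sum(tic(ch))
  mult <- set_multipliers(rs)
  for (k in 2:5) {
    expect_equal(sum(tic(rs$members[[k]])) / s0, mult[k], tolerance = 0.001)
  }
})

test_that("seeded replicate drawing is deterministic and in-band", {
  ch <- sim_single()$chromatogram
  a <- make_replicate_set(ch, rng_seed = 9)
  b <- make_replicate_set(ch, rng_seed = 9)
  expect_equal(set_multipliers(a), set_multipliers(b))
  expect_identical(a$members[[3]]$intensities, b$members[[3]]$intensities)
  offs <- vapply(a$specs, `[[`, numeric(1), "rt_offset")
  expect_true(all(abs(offs) <= 0.003))
  expect_true(all(set_multipliers(a)[-1] >= 0.5 & set_multipliers(a)[-1] <= 1.5))
})

test_that("multipliers outside the usual band warn but are accepted", {
  expect_warning(replicate_spec(0.001, 1.99866), "outside")
  expect_silent(replicate_spec(0.001, 1.2))
  expect_error(replicate_spec(0, 0), "> 0")
})
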