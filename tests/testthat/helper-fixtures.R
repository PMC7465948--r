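# Shared fixtures: small synthetic spectra and chromatograms built in code.
# Narrow m/z ranges keep the PARAFAC2 fits fast; the ions used lie inside.

spec_a <- function() {
  library_spectrum("analyte-A", c(60, 75, 88, 101), c(999, 620, 410, 150))
}

spec_b <- function() {
  library_spectrum("analyte-B", c(55, 68, 95, 110), c(999, 730, 350, 240))
}

# heptachlor/fenchlorphos-like pair for the co-elution scenario
spec_hepta <- function() {
  library_spectrum("hepta-like", c(100, 272, 274, 237, 65, 135, 337, 339),
                   c(999, 820, 650, 400, 350, 300, 180, 120),
                   retention_time = 8.50)
}

spec_fen <- function() {
  library_spectrum("fen-like", c(285, 287, 125, 79, 109, 167, 321),
                   c(999, 780, 600, 450, 300, 220, 150),
                   retention_time = 8.51)
}

sim_single <- function(noise_sd = 0, seed = 7, mz_range = c(50, 120),
                       rt = 2.0, sigma = 0.01, amount = 5000) {
  simulate_chromatogram(simulation_spec(
    run_length = 0.4, run_start = 1.8, mz_range = mz_range,
    components = list(ground_truth_component(spec_a(), rt, sigma, amount)),
    baseline_level = 0, noise_sd = noise_sd, rng_seed = seed))
}

sim_coelute <- function(noise_sd = 0, seed = 7) {
  simulate_chromatogram(simulation_spec(
    run_length = 0.4, run_start = 8.3, mz_range = c(50, 350),
    components = list(
      ground_truth_component(spec_hepta(), 8.50, 0.01, 5000),
      ground_truth_component(spec_fen(), 8.51, 0.01, 5000)),
    baseline_level = 0, noise_sd = noise_sd, rng_seed = seed))
}

# four fixed sub-scan replicate specs in the usual bands
fixed_specs <- function() {
  list(replicate_spec(-0.00156, 1.2),
       replicate_spec(0.00221, 1.45),
       replicate_spec(0.00158, 0.64),
       replicate_spec(-0.00107, 1.01))
}

# five-member set and interval cube around the single analyte
single_cube <- function(noise_sd = 0) {
  sim <- sim_single(noise_sd = noise_sd)
  rs <- make_replicate_set(sim$chromatogram, fixed_specs())
  list(set = rs, cube = build_cube(rs, rt_interval(1.94, 2.07, "single")),
       truth = sim$truth)
}

coelute_cube <- function(noise_sd = 0, seed = 7) {
  sim <- sim_coelute(noise_sd = noise_sd, seed = seed)
  rs <- make_replicate_set(sim$chromatogram, fixed_specs())
  list(set = rs, cube = build_cube(rs, rt_interval(8.44, 8.57, "coelute")))
}

fast_settings <- function(...) {
  fit_settings(n_starts = 2L, max_iterations = 2000L, rng_seed = 3L, ...)
}
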