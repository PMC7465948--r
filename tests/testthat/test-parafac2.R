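test_that("rank-1 cube: near-perfect fit and multiplier recovery", {
  sc <- single_cube()
  m <- fit_parafac2(sc$cube, 1, fast_settings())
  expect_gte(m$fit_percent, 99.99)
  mult <- set_multipliers(sc$set)
  ratio <- m$sample_loadings[, 1] / mult
  expect_lt(max(abs(ratio / mean(ratio) - 1)), 0.01)
  expect_true(m$converged)
})

test_that("two co-eluting components are resolved with cosine >= 0.999", {
  cc <- coelute_cube()
  m <- fit_parafac2(cc$cube, 2, fast_settings())
  recs <- extract_components(m, cc$cube)
  cos_h <- vapply(recs, function(r) spectrum_cosine(r$spectrum, spec_hepta()),
                  numeric(1))
  cos_f <- vapply(recs, function(r) spectrum_cosine(r$spectrum, spec_fen()),
                  numeric(1))
  # best-match assignment: each truth spectrum is recovered by one component
  expect_gte(max(cos_h), 0.999)
  expect_gte(max(cos_f), 0.999)
  expect_false(which.max(cos_h) == which.max(cos_f))
})

test_that("model fit is non-decreasing in the component count", {
  sc <- coelute_cube()
  f1 <- fit_parafac2(sc$cube, 1, fast_settings())$fit_percent
  f2 <- fit_parafac2(sc$cube, 2, fast_settings())$fit_percent
  expect_lte(f1, f2 + 1e-6)
})

test_that("classic direct-fit ALS has monotone non-increasing SSE", {
  sc <- single_cube(noise_sd = 2)
  m <- fit_parafac2(sc$cube, 2,
                    fit_settings(n_starts = 1, max_iterations = 200,
                                 nonneg_elution = FALSE, rng_seed = 1))
  tr <- m$sse_trace
  expect_true(all(diff(tr) <= 1e-9 * pmax(tr[-length(tr)], 1e-300)))
})

test_that("the PARAFAC2 cross-product constraint holds across members", {
  cc <- coelute_cube(noise_sd = 1)
  m <- fit_parafac2(cc$cube, 2, fast_settings())
  xps <- lapply(m$elution_profiles, crossprod)
  ref <- xps[[1]]
  for (k in 2:length(xps)) {
    expect_lt(max(abs(xps[[k]] - ref)) / max(abs(ref)), 1e-6)
  }
})

test_that("scale convention: unit-norm spectral and common-factor columns", {
  sc <- single_cube()
  m <- fit_parafac2(sc$cube, 1, fast_settings())
  expect_equal(sqrt(colSums(m$spectral_loadings^2)), rep(1, 1),
               tolerance = 1e-9)
  expect_equal(sqrt(colSums(m$H^2)), rep(1, 1), tolerance = 1e-9)
  expect_true(all(m$spectral_loadings >= -1e-12))
  expect_true(all(m$sample_loadings >= -1e-12))
})

test_that("fitting is deterministic given the seed", {
  sc <- single_cube(noise_sd = 2)
  m1 <- fit_parafac2(sc$cube, 2, fast_settings())
  m2 <- fit_parafac2(sc$cube, 2, fast_settings())
  expect_identical(m1$sse, m2$sse)
  expect_identical(m1$spectral_loadings, m2$spectral_loadings)
})

test_that("parameter validation rejects impossible fits", {
  sc <- single_cube()
  expect_error(fit_parafac2(sc$cube, 0, fast_settings()), "range")
  expect_error(fit_parafac2(sc$cube, 10000, fast_settings()), "range")
  zero <- sc$cube
  zero$slabs <- lapply(zero$slabs, function(x) x * 0)
  expect_error(fit_parafac2(zero, 1, fast_settings()), "degenerate")
})

test_that("R = 1 agrees with a direct nonlinear least-squares oracle", {
  # tiny random positive cube; oracle parameterizes X_k ~ p_k c_k s' with
  # unit-norm p_k, s and optimizes all parameters numerically
  set.seed(31)
  I <- 5; J <- 4; K <- 3
  slabs <- lapply(seq_len(K), function(k) {
    outer(runif(I, 0.5, 1), runif(J, 0.5, 1)) * runif(1, 0.8, 1.2) +
      matrix(runif(I * J, 0, 0.05), I, J)
  })
  cube <- structure(list(slabs = slabs,
                         interval = rt_interval(0, 1, "tiny"),
                         scan_times = seq(0, 0.9, length.out = I),
                         mz_axis = 50:(50 + J - 1)),
                    class = "interval_cube")
  m <- fit_parafac2(cube, 1, fit_settings(n_starts = 3, rng_seed = 2,
                                          max_iterations = 5000,
                                          convergence_tol = 1e-12))
  oracle_sse <- function(par) {
    ps <- lapply(seq_len(K), function(k) par[((k - 1) * I + 1):(k * I)])
    s <- par[(K * I + 1):(K * I + J)]
    cs <- par[(K * I + J + 1):(K * I + J + K)]
    sum(vapply(seq_len(K), function(k) {
      p <- ps[[k]] / sqrt(sum(ps[[k]]^2))
      sum((slabs[[k]] - outer(p, s / sqrt(sum(s^2))) * cs[k])^2)
    }, numeric(1)))
  }
  init <- c(rep(1, K * I), rep(1, J),
            vapply(slabs, function(x) sqrt(sum(x^2)), numeric(1)))
  opt <- stats::optim(init, oracle_sse, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(abs(m$sse - opt$value) / max(opt$value, 1e-12), 0.01)
})

test_that("core consistency is exactly 100 for a single component", {
  sc <- single_cube(noise_sd = 2)
  m <- fit_parafac2(sc$cube, 1, fast_settings())
  expect_equal(m$core_consistency, 100, tolerance = 1e-6)
  expect_equal(core_consistency(m, sc$cube, method = "tucker3"), 100,
               tolerance = 1e-6)
})

test_that("correct component count keeps core consistency near 100", {
  cc <- coelute_cube()
  m <- fit_parafac2(cc$cube, 2, fast_settings())
  expect_gte(m$core_consistency, 99)
})

test_that("tucker3 core consistency matches a vectorized kronecker oracle", {
  cc <- coelute_cube(noise_sd = 1)
  m <- fit_parafac2(cc$cube, 2, fast_settings())
  R <- m$n_components; K <- length(cc$cube$slabs); J <- ncol(cc$cube$slabs[[1]])
  Y <- array(0, c(R, J, K))
  for (k in seq_len(K)) Y[, , k] <- crossprod(m$P[[k]], cc$cube$slabs[[k]])
  M <- kronecker(m$sample_loadings,
                 kronecker(m$spectral_loadings, m$H))
  g <- pracma::pinv(M) %*% as.vector(Y)
  tgt <- as.vector(array(diag(R), c(R, R, R)) * 0 +
                     vapply(seq_len(R^3), function(i) {
                       idx <- arrayInd(i, c(R, R, R))
                       as.numeric(idx[1] == idx[2] && idx[2] == idx[3])
                     }, numeric(1)))
  oracle <- 100 * (1 - sum((g - tgt)^2) / R)
  expect_equal(core_consistency(m, cc$cube, method = "tucker3"), oracle,
               tolerance = 1e-4)
})

test_that("residual bookkeeping is exact and members stay comparable", {
  cc <- coelute_cube(noise_sd = 1)
  m <- fit_parafac2(cc$cube, 2, fast_settings())
  rs <- residual_summary(m, cc$cube)
  expect_equal(sum(rs$per_member^2), m$sse, tolerance = 1e-9)
  expect_equal(rs$relative_residual, 1 - m$fit_percent / 100, tolerance = 1e-12)
  expect_lt(max(rs$per_member), 3 * stats::median(rs$per_member))

  exact <- single_cube()
  me <- fit_parafac2(exact$cube, 1, fast_settings())
  re <- residual_summary(me, exact$cube)
  cube_norm <- sqrt(sum(vapply(exact$cube$slabs, function(x) sum(x^2),
                               numeric(1))))
  expect_true(all(re$per_member < 1e-6 * cube_norm))
})

test_that("model JSON serialization captures loadings and diagnostics", {
  sc <- single_cube()
  m <- fit_parafac2(sc$cube, 1, fast_settings())
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$n_components, 1)
  expect_equal(back$diagnostics$fit_percent, m$fit_percent, tolerance = 1e-9)
  expect_equal(as.numeric(back$sample_loadings), as.numeric(m$sample_loadings),
               tolerance = 1e-12)
})
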