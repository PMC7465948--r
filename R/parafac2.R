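#' PARAFAC2 fitting settings
#'
#' @param max_iterations maximum ALS iterations per start (default 50000).
#' @param convergence_tol relative SSE change declaring convergence
#'   (default 1e-8).
#' @param n_starts number of initializations: one SVD-based start plus
#'   seeded random starts; the best SSE wins, ties to the lower start
#'   index (default 3).
#' @param nonneg_spectral,nonneg_sample impose non-negativity on the
#'   spectral / sample (concentration) mode (default both `TRUE`).
#' @param nonneg_elution impose non-negativity on the elution profiles via
#'   flexible coupling (default `TRUE`). Chromatographic peaks are
#'   non-negative, and for pseudo-replicate sets (where every component's
#'   concentration scales with the same member multiplier) this constraint
#'   is what makes the decomposition identifiable; without it the model is
#'   rotationally degenerate and resolved spectra come out mixed. Set
#'   `FALSE` for the classic direct-fit algorithm with an unconstrained
#'   orthonormal elution basis.
#' @param rng_seed integer seed controlling the random starts.
#' @return object of class `fit_settings`.
#' @export
fit_settings <- function(max_iterations = 50000L, convergence_tol = 1e-8,
                         n_starts = 3L, nonneg_spectral = TRUE,
                         nonneg_sample = TRUE, nonneg_elution = TRUE,
                         rng_seed = 1L) {
  if (max_iterations < 1L) stop("max_iterations must be >= 1")
  if (convergence_tol <= 0) stop("convergence_tol must be > 0")
  if (n_starts < 1L) stop("n_starts must be >= 1")
  structure(list(max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 n_starts = as.integer(n_starts),
                 nonneg_spectral = nonneg_spectral,
                 nonneg_sample = nonneg_sample,
                 nonneg_elution = nonneg_elution,
                 rng_seed = as.integer(rng_seed)),
            class = "fit_settings")
}

matrixStats_colAnyNeg <- function(X) .colSums(X < 0, nrow(X), ncol(X)) > 0

# vectorized projected (cyclic) coordinate descent for many simultaneous
# small NNLS problems sharing one Gram matrix: minimize, per column j,
# 0.5 x' G x - b_j' x subject to x >= 0. Strictly convex (G carries a
# ridge), so the descent converges to the unique solution; every sweep is
# monotone in the objective, and warm starts keep ALS monotone overall.
nnls_gram_cd <- function(G, Bmat, X0, sweeps = 400L, tol = 1e-12) {
  R <- nrow(G)
  dg <- pmax(diag(G), 1e-300)
  X <- pmax(X0, 0)
  scale_ref <- max(abs(X), 1e-300)
  for (s in seq_len(sweeps)) {
    delta <- 0
    for (r in seq_len(R)) {
      xr_new <- pmax(0, X[r, ] + (Bmat[r, ] - G[r, ] %*% X) / dg[r])
      delta <- max(delta, max(abs(xr_new - X[r, ])))
      X[r, ] <- xr_new
    }
    if (delta <= tol * scale_ref) break
  }
  X
}

# least squares with one shared Gram: min ||Z x - y|| over columns y of
# Ymat, optionally non-negative (violating columns refined by projected
# coordinate descent, warm-started from the previous block value when
# supplied so alternating updates never increase the objective)
nnls_columns <- function(Z, Ymat, prev = NULL) {
  G <- crossprod(Z)
  solve_gram(G, crossprod(Z, Ymat), nonneg = TRUE, prev = prev)
}

# ordinary least squares for the same system (unconstrained modes)
ols_columns <- function(Z, Ymat) {
  G <- crossprod(Z)
  ridge <- 1e-12 * max(diag(G), 1e-300)
  solve(G + diag(ridge, ncol(G)), crossprod(Z, Ymat))
}

# column-wise Khatri-Rao product
khatri_rao <- function(A, B) {
  R <- ncol(A)
  out <- matrix(0, nrow(A) * nrow(B), R)
  for (r in seq_len(R)) out[, r] <- kronecker(A[, r], B[, r])
  out
}

# solve the normal-equation systems G x = rhs_j for every column of RHS
# (G is R x R, shared), with optional non-negativity. The unconstrained
# solution is used wherever it is already feasible; violating columns are
# refined together by projected coordinate descent. When `prev` (R x n)
# holds the block's previous value, the better of the two starts is kept
# per column, so the enclosing ALS objective cannot increase.
solve_gram <- function(G, RHS, nonneg, prev = NULL) {
  Gr <- G + diag(1e-12 * max(diag(G), 1e-300), ncol(G))
  Ru <- chol(Gr)
  X <- backsolve(Ru, backsolve(Ru, RHS, transpose = TRUE))
  if (!nonneg) return(X)
  bad <- which(matrixStats_colAnyNeg(X))
  if (!length(bad)) return(X)
  Bb <- RHS[, bad, drop = FALSE]
  cand <- nnls_gram_cd(Gr, Bb, X[, bad, drop = FALSE])
  if (!is.null(prev)) {
    pv <- pmax(prev[, bad, drop = FALSE], 0)
    obj <- function(M) 0.5 * colSums(M * (Gr %*% M)) - colSums(Bb * M)
    cand2 <- nnls_gram_cd(Gr, Bb, pv, sweeps = 50L)
    worse <- obj(cand2) < obj(cand)
    if (any(worse)) cand[, worse] <- cand2[, worse, drop = FALSE]
  }
  X[, bad] <- cand
  X
}

# pure-channel ("key ion") selection: greedily pick the R m/z channels
# whose mean elution patterns carry the most norm orthogonal to the
# already-selected ones; their raw profiles make a near-pure elution init
pure_channel_keys <- function(slabs, R) {
  Xbar <- Reduce(`+`, slabs) / length(slabs)
  J <- ncol(Xbar)
  keys <- integer(0)
  Q <- Xbar
  for (r in seq_len(R)) {
    norms <- colSums(Q^2)
    norms[keys] <- -Inf
    keys <- c(keys, which.max(norms))
    U <- qr.Q(qr(Xbar[, keys, drop = FALSE]))
    Q <- Xbar - U %*% crossprod(U, Xbar)
  }
  keys
}

# flexible-coupling ALS: X_k ~ B_k diag(c_k) S' with B_k >= 0 coupled to
# the PARAFAC2 structure B_k ~ P_k H by a quadratic penalty whose weight
# mu is ramped up until the coupling is tight; the returned model is the
# projected (exactly coupled) one
parafac2_als_flex <- function(slabs, R, H, S, C, settings, B0 = NULL) {
  K <- length(slabs); I <- nrow(slabs[[1L]]); J <- ncol(slabs[[1L]])
  ss_total <- sum(vapply(slabs, function(X) sum(X^2), numeric(1)))
  StS_fun <- function(S) crossprod(S)
  B <- if (!is.null(B0)) B0 else lapply(slabs, function(X) {
    # fall back to the slab's own leading subspace, made non-negative
    r0 <- min(R, ncol(X), nrow(X))
    sv <- svd(X, nu = r0, nv = 0)
    Bk <- abs(sv$u %*% diag(sv$d[seq_len(r0)], r0))
    if (r0 < R) Bk <- cbind(Bk, matrix(mean(Bk), I, R - r0))
    Bk
  })
  P <- vector("list", K)
  fit_sse <- function() {
    s <- 0
    for (k in seq_len(K)) {
      s <- s + sum((slabs[[k]] - B[[k]] %*% (C[k, ] * t(S)))^2)
    }
    s
  }
  coup_sse <- function() {
    s <- 0
    for (k in seq_len(K)) s <- s + sum((B[[k]] - P[[k]] %*% H)^2)
    s
  }
  # initial P, H consistent with B
  for (k in seq_len(K)) {
    sv <- svd(B[[k]] %*% t(H), nu = R, nv = R)
    P[[k]] <- sv$u %*% t(sv$v)
  }
  H <- Reduce(`+`, lapply(seq_len(K), function(k) crossprod(P[[k]], B[[k]]))) / K
  mu <- NA_real_
  obj_prev <- Inf
  sse_trace <- numeric(0)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(settings$max_iterations)) {
    # coupling-structure updates (Procrustes + common factor)
    for (k in seq_len(K)) {
      sv <- svd(B[[k]] %*% t(H), nu = R, nv = R)
      P[[k]] <- sv$u %*% t(sv$v)
    }
    H <- Reduce(`+`, lapply(seq_len(K), function(k) crossprod(P[[k]], B[[k]]))) / K
    if (is.na(mu)) {
      f0 <- fit_sse(); c0 <- coup_sse()
      mu <- if (c0 > 0) 0.1 * max(f0, 1e-12 * ss_total) / c0 else 1
    }
    # S rows (spectra)
    G <- matrix(0, R, R); RHS <- matrix(0, R, J)
    for (k in seq_len(K)) {
      Dk <- C[k, ]
      BtB <- crossprod(B[[k]])
      G <- G + (Dk %o% Dk) * BtB
      RHS <- RHS + Dk * crossprod(B[[k]], slabs[[k]])
    }
    S <- t(solve_gram(G, RHS, settings$nonneg_spectral, prev = t(S)))
    # c_k (sample loadings)
    StS <- StS_fun(S)
    for (k in seq_len(K)) {
      G <- crossprod(B[[k]]) * StS
      rhs <- colSums(B[[k]] * (slabs[[k]] %*% S))
      C[k, ] <- solve_gram(G, matrix(rhs, R, 1), settings$nonneg_sample,
                           prev = matrix(C[k, ], R, 1))
    }
    # B_k rows (elution profiles)
    StS <- StS_fun(S)
    for (k in seq_len(K)) {
      Dk <- C[k, ]
      G <- (Dk %o% Dk) * StS + diag(mu, R)
      RHS <- Dk * (t(S) %*% t(slabs[[k]])) + mu * t(P[[k]] %*% H)
      B[[k]] <- t(solve_gram(G, RHS, settings$nonneg_elution,
                             prev = t(B[[k]])))
    }
    # rebalance scale into the sample mode
    for (r in seq_len(R)) {
      ns <- sqrt(sum(S[, r]^2))
      if (ns > 0) { S[, r] <- S[, r] / ns; C[, r] <- C[, r] * ns }
    }
    f <- fit_sse(); cp <- coup_sse()
    sse_trace <- c(sse_trace, f)
    iters <- it
    rel_coup <- cp / max(f, 1e-12 * ss_total)
    # converged once the fit has plateaued (change measured against the
    # cube's total sum of squares, so exact fits terminate) and the
    # coupling is tight
    if (abs(obj_prev - f) <= settings$convergence_tol * ss_total &&
        rel_coup < 1e-8) {
      converged <- TRUE
      break
    }
    obj_prev <- f
    if (rel_coup > 1e-10) mu <- mu * 1.08
  }
  # project onto the exact PARAFAC2 structure and polish S, C once
  for (k in seq_len(K)) {
    sv <- svd(B[[k]] %*% t(H), nu = R, nv = R)
    P[[k]] <- sv$u %*% t(sv$v)
  }
  H <- Reduce(`+`, lapply(seq_len(K), function(k) crossprod(P[[k]], B[[k]]))) / K
  B <- lapply(P, function(Pk) Pk %*% H)
  G <- matrix(0, R, R); RHS <- matrix(0, R, J)
  for (k in seq_len(K)) {
    Dk <- C[k, ]
    G <- G + (Dk %o% Dk) * crossprod(B[[k]])
    RHS <- RHS + Dk * crossprod(B[[k]], slabs[[k]])
  }
  S <- t(solve_gram(G, RHS, settings$nonneg_spectral, prev = t(S)))
  StS <- StS_fun(S)
  for (k in seq_len(K)) {
    G <- crossprod(B[[k]]) * StS
    rhs <- colSums(B[[k]] * (slabs[[k]] %*% S))
    C[k, ] <- solve_gram(G, matrix(rhs, R, 1), settings$nonneg_sample,
                         prev = matrix(C[k, ], R, 1))
  }
  sse <- fit_sse()
  list(P = P, H = H, S = S, C = C, sse = sse, ss_total = ss_total,
       iterations = iters, converged = converged, sse_trace = sse_trace)
}

# one direct-fit ALS run from a given (H, S, C) initialization
parafac2_als <- function(slabs, R, H, S, C, settings) {
  K <- length(slabs); J <- ncol(slabs[[1L]])
  ss_total <- sum(vapply(slabs, function(X) sum(X^2), numeric(1)))
  sse_prev <- Inf
  sse_trace <- numeric(0)
  P <- vector("list", K)
  Y <- array(0, c(R, J, K))
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(settings$max_iterations)) {
    # elution-basis update: P_k = argmin ||X_k - P F_k||, P orthonormal
    for (k in seq_len(K)) {
      Fk <- H %*% (C[k, ] * t(S))           # R x J
      M <- slabs[[k]] %*% t(Fk)             # I x R
      sv <- svd(M, nu = R, nv = R)
      P[[k]] <- sv$u %*% t(sv$v)
      Y[, , k] <- crossprod(P[[k]], slabs[[k]])
    }
    ss_y <- sum(Y^2)
    # one PARAFAC-ALS pass on the transformed R x J x K array
    Y1 <- matrix(Y, R, J * K)                       # mode-1 unfolding
    Z <- khatri_rao(C, S)
    H <- t(ols_columns(Z, t(Y1)))
    Y2 <- matrix(aperm(Y, c(2, 1, 3)), J, R * K)    # mode-2 unfolding
    Z <- khatri_rao(C, H)
    S <- if (settings$nonneg_spectral) t(nnls_columns(Z, t(Y2), prev = t(S)))
         else t(ols_columns(Z, t(Y2)))
    Y3 <- matrix(aperm(Y, c(3, 1, 2)), K, R * J)    # mode-3 unfolding
    Z <- khatri_rao(S, H)
    C <- if (settings$nonneg_sample) t(nnls_columns(Z, t(Y3), prev = t(C)))
         else t(ols_columns(Z, t(Y3)))
    # rebalance scale into the sample mode (fix the indeterminacy)
    for (r in seq_len(R)) {
      ns <- sqrt(sum(S[, r]^2)); nh <- sqrt(sum(H[, r]^2))
      if (ns > 0) { S[, r] <- S[, r] / ns } else ns <- 1
      if (nh > 0) { H[, r] <- H[, r] / nh } else nh <- 1
      C[, r] <- C[, r] * ns * nh
    }
    # SSE of the full model (orthonormal P makes the split exact)
    fit_y <- 0
    for (k in seq_len(K)) {
      Mk <- H %*% (C[k, ] * t(S))
      fit_y <- fit_y + sum((Y[, , k] - Mk)^2)
    }
    sse <- (ss_total - ss_y) + fit_y
    sse_trace <- c(sse_trace, sse)
    iters <- it
    if (is.finite(sse_prev) &&
        abs(sse_prev - sse) <= settings$convergence_tol * ss_total) {
      converged <- TRUE
      sse_prev <- sse
      break
    }
    sse_prev <- sse
  }
  list(P = P, H = H, S = S, C = C, sse = sse_prev, ss_total = ss_total,
       iterations = iters, converged = converged, sse_trace = sse_trace)
}

#' Fit a PARAFAC2 model to an interval cube
#'
#' Direct-fitting alternating least squares for the model
#' `X_k ~ P_k H diag(c_k) t(S)` with `P_k` orthonormal (per-member elution
#' basis), `H` the common `R x R` factor, `S` the spectral loadings and
#' `c_k` the sample (concentration) loadings. Non-negativity is imposed on
#' the spectral and sample modes through non-negative least-squares
#' updates. The cross-product of every member's elution profiles
#' (`t(P_k H) %*% (P_k H) = t(H) %*% H`) is identical across members — the
#' defining PARAFAC2 constraint.
#'
#' One SVD-based start plus seeded random starts are run; the best SSE is
#' returned. After fitting, spectral and common-factor columns are
#' normalized to unit Euclidean norm with all magnitude absorbed into the
#' sample loadings.
#'
#' @param cube an [build_cube()] `interval_cube`.
#' @param R number of components (1 <= R <= min(I, J)).
#' @param settings a [fit_settings()].
#' @return object of class `parafac2_model`: `n_components`,
#'   `spectral_loadings` (J x R), `sample_loadings` (K x R),
#'   `elution_profiles` (list of K matrices I x R, `P_k %*% H`), `P`, `H`,
#'   `sse`, `ss_total`, `fit_percent`, `core_consistency`, `iterations`,
#'   `converged`, `start_index`, `settings`.
#' @export
fit_parafac2 <- function(cube, R, settings = fit_settings()) {
  stopifnot(inherits(cube, "interval_cube"))
  K <- length(cube$slabs)
  I <- nrow(cube$slabs[[1L]]); J <- ncol(cube$slabs[[1L]])
  if (R < 1L || R > min(I, J)) {
    stop(sprintf("R = %d outside the valid range 1..%d", R, min(I, J)))
  }
  ss_total <- sum(vapply(cube$slabs, function(X) sum(X^2), numeric(1)))
  if (ss_total == 0) stop("degenerate input: the cube carries no signal")

  best <- NULL
  for (start in seq_len(settings$n_starts)) {
    B0 <- NULL
    if (start == 1L) {
      # deterministic start: pure-channel elution profiles plus the
      # stacked slabs' leading right singular vectors for the spectra
      keys <- pure_channel_keys(cube$slabs, R)
      B0 <- lapply(cube$slabs, function(X) X[, keys, drop = FALSE])
      Xall <- do.call(rbind, cube$slabs)
      sv <- svd(Xall, nu = 0, nv = R)
      S0 <- abs(sv$v)
      C0 <- matrix(1, K, R)
      H0 <- diag(R)
    } else {
      set.seed(settings$rng_seed + start)
      S0 <- matrix(stats::runif(J * R), J, R)
      C0 <- matrix(stats::runif(K * R, 0.5, 1.5), K, R)
      H0 <- diag(R)
    }
    run <- if (isTRUE(settings$nonneg_elution)) {
      parafac2_als_flex(cube$slabs, R, H0, S0, C0, settings, B0 = B0)
    } else {
      parafac2_als(cube$slabs, R, H0, S0, C0, settings)
    }
    if (is.null(best) || run$sse < best$sse * (1 - 1e-12)) {
      best <- run
      best$start_index <- start
    }
  }

  # fix the scale indeterminacy: unit-norm spectral and common-factor
  # columns, magnitude absorbed into the sample loadings
  for (r in seq_len(R)) {
    ns <- sqrt(sum(best$S[, r]^2)); nh <- sqrt(sum(best$H[, r]^2))
    if (ns > 0) best$S[, r] <- best$S[, r] / ns else ns <- 1
    if (nh > 0) best$H[, r] <- best$H[, r] / nh else nh <- 1
    best$C[, r] <- best$C[, r] * ns * nh
  }

  fit_percent <- 100 * (1 - best$sse / ss_total)
  model <- structure(
    list(n_components = as.integer(R),
         spectral_loadings = best$S,
         sample_loadings = best$C,
         elution_profiles = lapply(best$P, function(Pk) Pk %*% best$H),
         P = best$P, H = best$H,
         sse = best$sse, ss_total = ss_total,
         fit_percent = fit_percent,
         core_consistency = NA_real_,
         iterations = best$iterations, converged = best$converged,
         sse_trace = best$sse_trace,
         start_index = best$start_index,
         interval = cube$interval, scan_times = cube$scan_times,
         mz_axis = cube$mz_axis,
         settings = settings),
    class = "parafac2_model")
  model$core_consistency <- core_consistency(model, cube)
  model
}

#' @export
print.parafac2_model <- function(x, ...) {
  cat(sprintf(
    "PARAFAC2 model '%s': R=%d, fit %.2f%%, core consistency %.1f, %d iter%s\n",
    x$interval$label, x$n_components, x$fit_percent, x$core_consistency,
    x$iterations, if (x$converged) " (converged)" else ""))
  invisible(x)
}

# array x matrix product along the given mode of a 3-way array
mode_product <- function(arr, M, mode) {
  d <- dim(arr)
  perm <- switch(mode, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  unf <- matrix(aperm(arr, perm), d[mode])
  res <- M %*% unf
  d[mode] <- nrow(M)
  out <- array(res, d[perm])
  aperm(out, order(perm))
}

#' Core consistency diagnostic (CORCONDIA)
#'
#' Computed on the PARAFAC representation implied by the PARAFAC2 model:
#' member slabs are projected onto their orthonormal elution bases,
#' `Y_k = t(P_k) %*% X_k`, where the model claims
#' `Y_k ~ H diag(c_k) t(S)` — a DIAGONAL interaction between elution
#' factors and spectral factors. The diagnostic compares the free
#' least-squares interaction core with that superdiagonal target:
#' `100 * (1 - sum((G - T)^2) / sum(T^2))`. Values near 100 indicate the
#' component count is appropriate; low or negative values indicate
#' overfactoring. For R = 1 the diagnostic is exactly 100 at any ALS
#' stationary point (scale optimality makes the single core element match
#' its target).
#'
#' Two forms are available. The default `"slabwise"` form computes, per
#' member, the free Tucker2 core `G_k = pinv(H) %*% Y_k %*% t(pinv(S))`
#' against the target `diag(c_k)`, pooling over members. It never inverts
#' the sample-loading matrix, so it remains numerically meaningful for
#' pseudo-replicate sets, where every component's concentration follows
#' the same member multipliers and the sample mode is nearly collinear
#' (inverting it amplifies residual noise without bound). The `"tucker3"`
#' form is the textbook three-way CORCONDIA (least-squares Tucker3 core
#' via pseudo-inverses of all three loading matrices against the
#' superdiagonal identity); it is appropriate when samples vary
#' independently.
#'
#' @param model a fitted [fit_parafac2()] model.
#' @param cube the `interval_cube` it was fitted to.
#' @param method `"slabwise"` (default) or `"tucker3"`.
#' @return a number <= 100 (possibly negative).
#' @export
core_consistency <- function(model, cube, method = c("slabwise", "tucker3")) {
  stopifnot(inherits(model, "parafac2_model"), inherits(cube, "interval_cube"))
  method <- match.arg(method)
  R <- model$n_components
  if (R < 1L) stop("model has no components")
  K <- length(cube$slabs); J <- ncol(cube$slabs[[1L]])
  Y <- array(0, c(R, J, K))
  for (k in seq_len(K)) Y[, , k] <- crossprod(model$P[[k]], cube$slabs[[k]])
  Hp <- pracma::pinv(model$H)
  Sp <- pracma::pinv(model$spectral_loadings)
  if (method == "slabwise") {
    num <- 0; den <- 0
    for (k in seq_len(K)) {
      Gk <- Hp %*% Y[, , k] %*% t(Sp)
      Tk <- diag(model$sample_loadings[k, ], R)
      num <- num + sum((Gk - Tk)^2)
      den <- den + sum(Tk^2)
    }
    if (den == 0) stop("degenerate model: all sample loadings are zero")
    return(100 * (1 - num / den))
  }
  G <- mode_product(Y, Hp, 1)
  G <- mode_product(G, Sp, 2)
  G <- mode_product(G, pracma::pinv(model$sample_loadings), 3)
  Tgt <- array(0, c(R, R, R))
  for (r in seq_len(R)) Tgt[r, r, r] <- 1
  100 * (1 - sum((G - Tgt)^2) / R)
}

#' Residual diagnostics for a fitted model
#'
#' @param model a [fit_parafac2()] model.
#' @param cube the `interval_cube` it was fitted to.
#' @return list with `per_member` (residual Frobenius norm per member),
#'   `per_channel` (residual norm per m/z bin, pooled over members),
#'   `relative_residual` (`1 - fit_percent/100`), and `sse`.
#' @export
residual_summary <- function(model, cube) {
  stopifnot(inherits(model, "parafac2_model"), inherits(cube, "interval_cube"))
  K <- length(cube$slabs); J <- ncol(cube$slabs[[1L]])
  per_member <- numeric(K)
  chan_ss <- numeric(J)
  sse_acc <- 0
  for (k in seq_len(K)) {
    recon <- model$P[[k]] %*% model$H %*%
      (model$sample_loadings[k, ] * t(model$spectral_loadings))
    resid <- cube$slabs[[k]] - recon
    per_member[k] <- sqrt(sum(resid^2))
    chan_ss <- chan_ss + colSums(resid^2)
    sse_acc <- sse_acc + sum(resid^2)
  }
  list(per_member = per_member,
       per_channel = sqrt(chan_ss),
       relative_residual = 1 - model$fit_percent / 100,
       sse = sse_acc)
}

#' Serialize a fitted model to JSON
#'
#' Portable bundle with loadings, diagnostics, settings and seed.
#'
#' @param model a `parafac2_model`.
#' @param path output JSON path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "parafac2_model"))
  payload <- list(
    n_components = model$n_components,
    interval = model$interval[c("start", "end", "label")],
    spectral_loadings = model$spectral_loadings,
    sample_loadings = model$sample_loadings,
    H = model$H,
    elution_profiles = model$elution_profiles,
    scan_times = model$scan_times,
    mz_axis = model$mz_axis,
    diagnostics = list(sse = model$sse, fit_percent = model$fit_percent,
                       core_consistency = model$core_consistency,
                       iterations = model$iterations,
                       converged = model$converged,
                       start_index = model$start_index),
    settings = unclass(model$settings))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
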