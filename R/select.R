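#' Sweep component counts and pick the smallest adequate model
#'
#' Fits PARAFAC2 for each candidate component count and applies the
#' acceptance rules: model fit above `fit_threshold` (default 90%), core
#' consistency above `cc_threshold` (default 90), convergence, and low
#' residuals (no member's residual norm above `residual_ratio` times the
#' median member residual). The chosen count is the SMALLEST candidate
#' passing all rules — parsimony, since overfactoring splits real spectra.
#' When nothing passes, `chosen_R` is `NA` and the interval is flagged for
#' manual review (possibly with an extended R range; badly overloaded
#' peaks can need 8 components).
#'
#' @param cube an `interval_cube`.
#' @param R_range integer vector of candidate component counts
#'   (default 1:7).
#' @param settings a [fit_settings()].
#' @param fit_threshold,cc_threshold acceptance thresholds, percent.
#' @param residual_ratio member-residual outlier multiplier (default 3).
#' @param residual_floor minimum relative residual (member residual norm
#'   over member signal norm) before the outlier rule can fire
#'   (default 0.05).
#' @return object of class `model_sweep`: `interval`, `candidates`
#'   (data.frame with R, fit_percent, core_consistency, sse, iterations,
#'   converged, accepted, reason), `chosen_R`, `models` (list keyed by R).
#' @export
sweep_models <- function(cube, R_range = 1:7, settings = fit_settings(),
                         fit_threshold = 90, cc_threshold = 90,
                         residual_ratio = 3, residual_floor = 0.05) {
  stopifnot(inherits(cube, "interval_cube"))
  R_range <- sort(unique(as.integer(R_range)))
  rows <- list(); models <- list()
  for (R in R_range) {
    res <- tryCatch(fit_parafac2(cube, R, settings), error = function(e) e)
    if (inherits(res, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        R = R, fit_percent = NA_real_, core_consistency = NA_real_,
        sse = NA_real_, iterations = NA_integer_, converged = FALSE,
        accepted = FALSE, reason = paste("fit error:", conditionMessage(res)),
        stringsAsFactors = FALSE)
      next
    }
    resid <- residual_summary(res, cube)
    reasons <- character(0)
    if (!(res$fit_percent > fit_threshold)) {
      reasons <- c(reasons, sprintf("fit %.1f%% <= %g%%",
                                    res$fit_percent, fit_threshold))
    }
    if (!(res$core_consistency > cc_threshold)) {
      reasons <- c(reasons, sprintf("core consistency %.1f <= %g",
                                    res$core_consistency, cc_threshold))
    }
    if (!res$converged) reasons <- c(reasons, "not converged")
    cmax <- apply(res$sample_loadings, 2, max)
    if (any(cmax <= 1e-9 * max(cmax))) {
      reasons <- c(reasons, "degenerate component (zero sample loading)")
    }
    # residual outlier rule: a member counts as badly described only when
    # its residual is both large relative to the other members AND a
    # substantive fraction of its own signal (pseudo-replicate sets leave
    # the original member with near-zero residual, which would otherwise
    # inflate the ratio over harmless interpolation error)
    rel <- resid$per_member /
      vapply(cube$slabs, function(x) sqrt(sum(x^2)), numeric(1))
    med <- stats::median(rel)
    if (max(rel) > residual_floor &&
        max(rel) > residual_ratio * max(med, 1e-12)) {
      reasons <- c(reasons, "member residual outlier")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      R = R, fit_percent = res$fit_percent,
      core_consistency = res$core_consistency, sse = res$sse,
      iterations = res$iterations, converged = res$converged,
      accepted = length(reasons) == 0L,
      reason = if (length(reasons)) paste(reasons, collapse = "; ") else "",
      stringsAsFactors = FALSE)
    models[[as.character(R)]] <- res
  }
  candidates <- do.call(rbind, rows)
  ok <- candidates$R[candidates$accepted]
  structure(
    list(interval = cube$interval, candidates = candidates,
         chosen_R = if (length(ok)) min(ok) else NA_integer_,
         models = models),
    class = "model_sweep")
}

#' @export
print.model_sweep <- function(x, ...) {
  cat(sprintf("model sweep for interval '%s': chosen R = %s\n",
              x$interval$label,
              if (is.na(x$chosen_R)) "none (manual review)" else x$chosen_R))
  print(x$candidates[, c("R", "fit_percent", "core_consistency",
                         "converged", "accepted")], row.names = FALSE)
  invisible(x)
}

#' Extract per-component records from an accepted model
#'
#' Each record carries the resolved spectrum rescaled to base peak 999,
#' the apex retention time (scan time of the maximum of the member-
#' averaged elution profile), per-member relative amounts (the sample
#' loadings), and a baseline flag from [label_baseline()].
#'
#' @param model a fitted `parafac2_model`.
#' @param cube the `interval_cube` it was fitted to.
#' @param background_ions integer m/z list used for baseline labeling
#'   (default the common siloxane ions 207, 281, 355).
#' @return list of `component_record` objects with fields `spectrum`
#'   (a [library_spectrum()]), `apex_rt`, `amounts`, `elution_mean`,
#'   `is_baseline`, `interval_label`, `component_index`.
#' @export
extract_components <- function(model, cube,
                               background_ions = c(207L, 281L, 355L)) {
  stopifnot(inherits(model, "parafac2_model"))
  R <- model$n_components
  K <- length(model$elution_profiles)
  records <- vector("list", R)
  for (r in seq_len(R)) {
    # member-averaged elution profile, weighted by each member's loading
    prof <- Reduce(`+`, lapply(seq_len(K), function(k) {
      model$elution_profiles[[k]][, r] * model$sample_loadings[k, r]
    })) / K
    s <- model$spectral_loadings[, r]
    s[s < 0] <- 0
    rec <- structure(
      list(spectrum = if (max(s) > 0)
             library_spectrum(sprintf("%s_comp%d", model$interval$label, r),
                              model$mz_axis[s > 0], s[s > 0] / max(s) * 999)
           else NULL,
           apex_rt = model$scan_times[which.max(abs(prof))],
           amounts = model$sample_loadings[, r],
           elution_mean = prof,
           interval_label = model$interval$label,
           component_index = r,
           is_baseline = NA),
      class = "component_record")
    rec$is_baseline <- label_baseline(rec, background_ions)
    records[[r]] <- rec
  }
  records
}

#' Decide whether a resolved component is background/baseline
#'
#' A component is labeled baseline when its member-averaged elution
#' profile is nearly flat over the interval (coefficient of variation
#' below `cv_threshold`) or when at least `share_threshold` of its
#' spectrum intensity sits on configured background ions (e.g., siloxane
#' ions from column bleed or pipette tips).
#'
#' @param record a `component_record` from [extract_components()].
#' @param background_ions integer m/z values considered background.
#' @param cv_threshold elution-profile coefficient-of-variation cutoff
#'   (default 0.2).
#' @param share_threshold background-ion intensity share cutoff
#'   (default 0.5).
#' @return logical.
#' @export
label_baseline <- function(record, background_ions = c(207L, 281L, 355L),
                           cv_threshold = 0.2, share_threshold = 0.5) {
  prof <- abs(record$elution_mean)
  if (mean(prof) > 0 && stats::sd(prof) / mean(prof) < cv_threshold) {
    return(TRUE)
  }
  sp <- record$spectrum
  if (!is.null(sp)) {
    share <- sum(sp$intensity[sp$mz %in% background_ions]) / sum(sp$intensity)
    if (share >= share_threshold) return(TRUE)
  }
  FALSE
}

#' Write a sweep report as CSV
#'
#' @param sweeps list of `model_sweep` objects.
#' @param path output CSV.
#' @export
write_sweep_csv <- function(sweeps, path) {
  rows <- lapply(sweeps, function(sw) {
    df <- sw$candidates
    df$interval <- sw$interval$label
    df$chosen <- !is.na(sw$chosen_R) & df$R == sw$chosen_R
    df[, c("interval", "R", "fit_percent", "core_consistency", "sse",
           "iterations", "converged", "accepted", "chosen", "reason")]
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(NULL)
}
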