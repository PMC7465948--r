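#' Forward match factor between a query and a library spectrum
#'
#' Weighted-cosine identity score in the Stein--Scott style: on the union
#' integer m/z grid both spectra are weighted by `w(m, I) = m * sqrt(I)`
#' and the match factor is `999 * cos^2` of the weighted vectors, rounded
#' to the nearest integer. The score is invariant to global intensity
#' scaling of either spectrum. Absolute values are NOT expected to equal
#' the NIST search engine's proprietary composite score.
#'
#' @param query a [library_spectrum()] or m/z-named numeric vector.
#' @param lib a [library_spectrum()].
#' @return integer in 0..999.
#' @export
match_factor <- function(query, lib) {
  vq <- spectrum_as_vector(query)
  vl <- spectrum_as_vector(lib)
  vq <- vq[vq > 0]; vl <- vl[vl > 0]
  if (length(vq) == 0L) stop("all-zero query spectrum: match factor undefined")
  if (length(vl) == 0L) stop("all-zero library spectrum: match factor undefined")
  weighted_cos2_score(vq, vl)
}

# shared weighted-cosine kernel on m/z-named sparse vectors
weighted_cos2_score <- function(vq, vl) {
  grid <- sort(unique(c(as.integer(names(vq)), as.integer(names(vl)))))
  dq <- dl <- numeric(length(grid))
  dq[match(as.integer(names(vq)), grid)] <- vq
  dl[match(as.integer(names(vl)), grid)] <- vl
  wq <- grid * sqrt(dq)
  wl <- grid * sqrt(dl)
  cosv <- sum(wq * wl) / (sqrt(sum(wq^2)) * sqrt(sum(wl^2)))
  as.integer(round(999 * cosv^2))
}

#' Reverse match factor
#'
#' The forward [match_factor()] computed after deleting query peaks at m/z
#' values absent from the library spectrum — a library-driven comparison
#' that ignores impurity ions in the unknown. `rmf >= mf` always, since
#' removing unmatched query mass is the only change and it can only raise
#' the weighted cosine.
#'
#' @inheritParams match_factor
#' @return integer in 0..999.
#' @export
reverse_match_factor <- function(query, lib) {
  vq <- spectrum_as_vector(query)
  vl <- spectrum_as_vector(lib)
  vq <- vq[vq > 0]; vl <- vl[vl > 0]
  if (length(vl) == 0L) stop("all-zero library spectrum: match factor undefined")
  vq <- vq[names(vq) %in% names(vl)]
  if (length(vq) == 0L) return(0L)
  weighted_cos2_score(vq, vl)
}

#' Classify a match factor into NIST-style quality bands
#'
#' 900 or greater is an excellent match; 800--899 good; 700--799 fair;
#' 600--699 poor; below 600 very poor. (The source bands leave 600--700
#' unnamed; "poor" is this package's convention for that gap.)
#'
#' @param mf integer match factor in 0..999.
#' @return one of `"excellent"`, `"good"`, `"fair"`, `"poor"`,
#'   `"very poor"`.
#' @export
classify_quality <- function(mf) {
  if (!is.numeric(mf) || length(mf) != 1L || mf < 0 || mf > 999) {
    stop("match factor must be a single value in 0..999")
  }
  if (mf >= 900) "excellent"
  else if (mf >= 800) "good"
  else if (mf >= 700) "fair"
  else if (mf >= 600) "poor"
  else "very poor"
}

#' Search a component spectrum against an MSP library
#'
#' Scores every library entry with forward and reverse match factors,
#' keeps hits with `mf >= min_mf`, sorts by mf descending (ties: rmf
#' descending, then library order) and returns the top `top_n`.
#'
#' @param query a `component_record`, [library_spectrum()] or m/z-named
#'   numeric vector.
#' @param library list of [library_spectrum()] entries.
#' @param top_n maximum number of hits returned (default 5).
#' @param min_mf minimum forward match factor (default 600).
#' @return data.frame with columns `rank`, `name`, `mf`, `rmf`,
#'   `quality_class` (zero rows allowed).
#' @export
search_library <- function(query, library, top_n = 5L, min_mf = 600L) {
  if (inherits(query, "component_record")) query <- query$spectrum
  if (length(library) == 0L) stop("spectral library is empty")
  mf <- vapply(library, function(l) match_factor(query, l), integer(1))
  rmf <- vapply(library, function(l) reverse_match_factor(query, l), integer(1))
  keep <- which(mf >= min_mf)
  ord <- keep[order(-mf[keep], -rmf[keep], keep)]
  ord <- ord[seq_len(min(length(ord), top_n))]
  data.frame(
    rank = seq_along(ord),
    name = vapply(library[ord], `[[`, character(1), "name"),
    mf = mf[ord], rmf = rmf[ord],
    quality_class = vapply(mf[ord], classify_quality, character(1)),
    stringsAsFactors = FALSE)
}
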