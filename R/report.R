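# half-up integer rounding (R's round() is round-half-even; AMF/ARMF
# aggregation uses conventional half-up)
round_half_up <- function(x) floor(x + 0.5)

#' Aggregate replicate identifications of one compound
#'
#' AMF and ARMF are the rounded means of the forward and reverse match
#' factors over all positive hits; `n_positive` counts the hits.
#'
#' @param compound compound name.
#' @param hits data.frame with columns `analysis`, `mf`, `rmf` (zero rows
#'   allowed).
#' @param expected_rt optional retention time, minutes.
#' @return object of class `compound_report` with fields `compound`,
#'   `expected_rt`, `hits`, `n_positive`, `amf`, `armf` (the latter two
#'   `NA` when there are no hits).
#' @export
aggregate_compound <- function(compound, hits, expected_rt = NA_real_) {
  if (is.null(hits) || nrow(hits) == 0L) {
    hits <- data.frame(analysis = character(0), mf = integer(0),
                       rmf = integer(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("mf", "rmf") %in% names(hits)))
  n <- nrow(hits)
  structure(
    list(compound = as.character(compound),
         expected_rt = as.numeric(expected_rt),
         hits = hits,
         n_positive = n,
         amf = if (n) as.integer(round_half_up(mean(hits$mf))) else NA_integer_,
         armf = if (n) as.integer(round_half_up(mean(hits$rmf))) else NA_integer_),
    class = "compound_report")
}

#' Study-level summary of compound reports
#'
#' Means are taken over compounds with at least one positive hit. The
#' ARMF-AMF difference is computed on the UNROUNDED means and rounded only
#' at the end (pre-rounded totals can shift the difference by one unit).
#'
#' @param reports list of [aggregate_compound()] objects.
#' @param amf_threshold threshold for the "share above" statistic
#'   (default 800).
#' @return list with `n_compounds`, `total_amf`, `total_armf`,
#'   `armf_amf_difference`, `min_amf`, `share_amf_above`,
#'   `amf_threshold`.
#' @export
summarize_study <- function(reports, amf_threshold = 800) {
  stopifnot(all(vapply(reports, inherits, logical(1), "compound_report")))
  amf <- vapply(reports, `[[`, integer(1), "amf")
  armf <- vapply(reports, `[[`, integer(1), "armf")
  ok <- !is.na(amf)
  if (!any(ok)) stop("no compound has a positive identification")
  amf <- amf[ok]; armf <- armf[ok]
  list(
    n_compounds = sum(ok),
    total_amf = as.integer(round_half_up(mean(amf))),
    total_armf = as.integer(round_half_up(mean(armf))),
    armf_amf_difference = as.integer(round_half_up(mean(armf) - mean(amf))),
    min_amf = as.integer(min(amf)),
    share_amf_above = mean(amf > amf_threshold),
    amf_threshold = amf_threshold)
}

#' Export compound reports and the study summary
#'
#' Writes a flat CSV table (one row per compound: No, Compound, RT, AMF,
#' ARMF, hit count) followed by summary rows. CSV is the interchange
#' format; it opens directly in spreadsheet software.
#'
#' @param reports list of [aggregate_compound()] objects.
#' @param summary result of [summarize_study()], or `NULL` to recompute.
#' @param path output CSV path.
#' @return invisibly, the exported data.frame.
#' @export
export_report <- function(reports, summary = NULL, path) {
  if (is.null(summary) &&
      any(vapply(reports, function(r) r$n_positive > 0, logical(1)))) {
    summary <- summarize_study(reports)
  }
  df <- data.frame(
    no = seq_along(reports),
    compound = vapply(reports, `[[`, character(1), "compound"),
    rt_min = vapply(reports, `[[`, numeric(1), "expected_rt"),
    amf = vapply(reports, `[[`, integer(1), "amf"),
    armf = vapply(reports, `[[`, integer(1), "armf"),
    n_positive = vapply(reports, `[[`, integer(1), "n_positive"),
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, na = "")
  if (!is.null(summary)) {
    writeLines("", con)
    writeLines("statistic,value", con)
    writeLines(sprintf("%s,%s",
                       c("n_compounds", "total_amf", "total_armf",
                         "armf_amf_difference", "min_amf",
                         sprintf("share_amf_above_%g", summary$amf_threshold)),
                       c(summary$n_compounds, summary$total_amf,
                         summary$total_armf, summary$armf_amf_difference,
                         summary$min_amf, summary$share_amf_above)), con)
  }
  invisible(df)
}

#' Load the bundled identification-report fixture
#'
#' A transcription of a published 40-compound PAH/PCB/pesticide
#' identification table: per-compound AMF/ARMF for a standard mixture and
#' for pooled real samples (three soils/cardboard), with replicate hit
#' counts. Used for aggregation tests and as a worked example.
#'
#' @return data.frame with columns `no`, `compound`, `rt_min`, `std_amf`,
#'   `std_armf`, `std_n`, `real_amf`, `real_armf`, `s1_n`, `s2_n`, `s3_n`.
#' @export
load_report_fixture <- function() {
  path <- system.file("extdata", "identification_report_fixture.csv",
                      package = "gcdeconv", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Build compound reports from a fixture-style AMF table
#'
#' Converts per-compound AMF/ARMF columns (already averaged) into
#' `compound_report` objects with a single synthetic hit carrying the
#' average, so [summarize_study()] can aggregate them.
#'
#' @param df data.frame with columns `compound`, an AMF column and an
#'   ARMF column.
#' @param amf_col,armf_col column names (default `"std_amf"`,
#'   `"std_armf"`).
#' @param rt_col optional retention-time column name.
#' @return list of `compound_report` objects.
#' @export
reports_from_table <- function(df, amf_col = "std_amf",
                               armf_col = "std_armf", rt_col = "rt_min") {
  lapply(seq_len(nrow(df)), function(i) {
    aggregate_compound(
      df$compound[i],
      data.frame(analysis = "mean", mf = df[[amf_col]][i],
                 rmf = df[[armf_col]][i], stringsAsFactors = FALSE),
      expected_rt = if (rt_col %in% names(df)) df[[rt_col]][i] else NA_real_)
  })
}
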