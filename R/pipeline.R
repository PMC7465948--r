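#' Run the full deconvolution-and-identification workflow
#'
#' Orchestrates: pseudo-replicate augmentation of a single chromatogram,
#' interval cube construction, per-interval PARAFAC2 component sweeps,
#' model selection, library search of the resolved spectra, and compound
#' aggregation. Writes per-interval model bundles, a sweep report, a hit
#' table, the compound report and a provenance manifest into `out_dir`.
#' Deterministic given identical config and seed.
#'
#' @param config named list (or path to a YAML file) with fields:
#'   \describe{
#'     \item{input}{path to a CDF or dense-CSV chromatogram, or a
#'       `chromatogram` object.}
#'     \item{replicate_specs}{list of `(rt_offset, multiplier)` pairs, or
#'       `NULL` to draw four from `seed`.}
#'     \item{denoise}{logical, apply the Savitzky-Golay filter to all
#'       members (default `FALSE`).}
#'     \item{intervals}{path to an interval config, a list of
#'       [rt_interval()], or an integer target count for
#'       [suggest_intervals()].}
#'     \item{R_range}{candidate component counts (default 1:7).}
#'     \item{fit}{list of [fit_settings()] overrides.}
#'     \item{library}{path to an MSP library (optional; skips matching
#'       when absent).}
#'     \item{top_n, min_mf}{library search thresholds (defaults 5, 600).}
#'     \item{seed}{integer seed (default 1).}
#'     \item{out_dir}{output directory.}
#'   }
#' @return invisibly, a list with `sweeps`, `components`, `hits`,
#'   `reports`, `summary` (NULL when nothing was identified), `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config error: out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("FAILED at stage %s: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  ch <- stage("input", {
    x <- config$input
    if (inherits(x, "chromatogram")) x
    else if (grepl("\\.cdf$", x, ignore.case = TRUE)) read_cdf(x)
    else read_chrom_csv(x)
  })

  set_ <- stage("augment", {
    specs <- config$replicate_specs
    if (!is.null(specs)) {
      specs <- lapply(specs, function(s) {
        replicate_spec(s$rt_offset %||% s[[1]], s$multiplier %||% s[[2]])
      })
    }
    make_replicate_set(ch, specs = specs,
                       denoise = isTRUE(config$denoise), rng_seed = seed)
  })

  ivs <- stage("intervals", {
    iv <- config$intervals
    if (is.character(iv)) load_interval_config(iv, isTRUE(config$allow_overlap))
    else if (is.numeric(iv)) suggest_intervals(set_, as.integer(iv))
    else if (is.list(iv) && all(vapply(iv, inherits, logical(1), "rt_interval"))) iv
    else stop("config error: intervals must be a path, a count, or rt_interval list")
  })

  fs <- do.call(fit_settings, utils::modifyList(
    list(rng_seed = seed), as.list(config$fit %||% list())))
  R_range <- config$R_range %||% 1:7

  lib <- if (!is.null(config$library)) read_msp(config$library) else NULL
  top_n <- config$top_n %||% 5L
  min_mf <- config$min_mf %||% 600L

  sweeps <- list(); components <- list(); hit_rows <- list()
  for (iv in ivs) {
    cube <- stage(paste0("cube:", iv$label), build_cube(set_, iv))
    sw <- stage(paste0("deconvolve:", iv$label),
                sweep_models(cube, R_range, fs))
    sweeps[[iv$label]] <- sw
    message(sprintf("interval %-12s chosen R = %s", iv$label,
                    if (is.na(sw$chosen_R)) "none" else sw$chosen_R))
    if (is.na(sw$chosen_R)) next
    model <- sw$models[[as.character(sw$chosen_R)]]
    write_model_json(model, file.path(out_dir,
                                      sprintf("model_%s.json", iv$label)))
    recs <- extract_components(model, cube,
                               config$background_ions %||% c(207L, 281L, 355L))
    for (rec in recs) {
      components[[length(components) + 1L]] <- rec
      if (is.null(lib) || rec$is_baseline || is.null(rec$spectrum)) next
      hits <- search_library(rec, lib, top_n = top_n, min_mf = min_mf)
      if (nrow(hits)) {
        hits$interval <- iv$label
        hits$component <- rec$component_index
        hits$apex_rt <- rec$apex_rt
        hit_rows[[length(hit_rows) + 1L]] <- hits
      }
    }
  }

  hits_df <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(rank = integer(0), name = character(0), mf = integer(0),
               rmf = integer(0), quality_class = character(0),
               interval = character(0), component = integer(0),
               apex_rt = numeric(0))
  write_sweep_csv(sweeps, file.path(out_dir, "sweep_report.csv"))
  utils::write.csv(hits_df, file.path(out_dir, "hits.csv"), row.names = FALSE)

  # aggregate rank-1 hits per library compound across intervals
  reports <- stage("report", {
    top <- hits_df[hits_df$rank == 1L, , drop = FALSE]
    lapply(split(top, top$name), function(g) {
      aggregate_compound(g$name[1L],
                         data.frame(analysis = g$interval, mf = g$mf,
                                    rmf = g$rmf, stringsAsFactors = FALSE),
                         expected_rt = g$apex_rt[1L])
    })
  })
  summary <- NULL
  if (length(reports)) {
    summary <- summarize_study(unname(reports))
    export_report(unname(reports), summary,
                  file.path(out_dir, "compound_report.csv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gcdeconv")),
    seed = seed,
    n_members = length(set_$members),
    replicate_specs = lapply(set_$specs, unclass),
    n_intervals = length(ivs),
    R_range = range(R_range),
    fit_settings = unclass(fs),
    library = config$library %||% NA,
    config_hash = digest_config(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(sweeps = sweeps, components = components, hits = hits_df,
                 reports = reports, summary = summary, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable fingerprint of the (serializable part of the) config
digest_config <- function(config) {
  config$input <- if (is.character(config$input)) config$input else "<object>"
  txt <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                          force = TRUE)
  # cheap polynomial rolling hash; no cryptographic strength needed
  bytes <- utf8ToInt(as.character(txt))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
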