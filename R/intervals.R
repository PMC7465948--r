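#' Define a retention-time interval
#'
#' Intervals are half-open `[start, end)` on scan time in minutes, so a
#' tiling set of intervals partitions every scan exactly once.
#'
#' @param start,end interval bounds, minutes; `start < end`.
#' @param label short name.
#' @return object of class `rt_interval`.
#' @export
rt_interval <- function(start, end, label = sprintf("%.3f-%.3f", start, end)) {
  if (!(start < end)) {
    stop(sprintf("interval '%s': start (%.4f) must be below end (%.4f)",
                 label, start, end))
  }
  structure(list(start = as.numeric(start), end = as.numeric(end),
                 label = as.character(label)),
            class = "rt_interval")
}

#' Load a retention-interval configuration
#'
#' Reads a YAML or JSON list of `(start, end, label)` records, validates
#' and sorts them. Overlapping intervals are rejected unless
#' `allow_overlap = TRUE` — deliberate multi-coverage of unresolved
#' regions (selecting the same peaks in more than one interval) is a
#' legitimate strategy and must be opted into.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @param allow_overlap permit overlapping intervals.
#' @return list of [rt_interval()] sorted by start time.
#' @export
load_interval_config <- function(path, allow_overlap = FALSE) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  ivs <- lapply(raw, function(r) {
    rt_interval(r$start, r$end,
                if (is.null(r$label)) sprintf("%.3f-%.3f", r$start, r$end)
                else r$label)
  })
  ivs <- ivs[order(vapply(ivs, `[[`, numeric(1), "start"))]
  if (!allow_overlap && length(ivs) > 1L) {
    for (i in seq_len(length(ivs) - 1L)) {
      if (ivs[[i + 1L]]$start < ivs[[i]]$end) {
        stop(sprintf(
          "intervals '%s' and '%s' overlap; pass allow_overlap = TRUE to keep both",
          ivs[[i]]$label, ivs[[i + 1L]]$label))
      }
    }
  }
  ivs
}

#' Suggest interval boundaries from TIC valleys
#'
#' Advisory helper for the otherwise manual interval definition: places
#' the `target_count - 1` boundaries at the deepest local minima (valleys)
#' of the mean member TIC, then tiles the run. On a flat TIC the valleys
#' degenerate and boundaries fall back to near-equal spacing (earliest
#' candidate wins ties).
#'
#' @param set a `replicate_set`.
#' @param target_count desired number of intervals (>= 1).
#' @return list of [rt_interval()] tiling the run.
#' @export
suggest_intervals <- function(set, target_count) {
  stopifnot(inherits(set, "replicate_set"))
  times <- set$members[[1L]]$scan_times
  I <- length(times)
  if (target_count < 1L) stop("target_count must be >= 1")
  if (target_count > I) stop("target_count exceeds the number of scans")
  if (target_count == 1L) {
    return(list(rt_interval(times[1L], times[I] + diff(times[I - (1:0)]),
                            "whole-run")))
  }
  mean_tic <- Reduce(`+`, lapply(set$members, tic)) / length(set$members)
  interior <- 2:(I - 1L)
  is_valley <- mean_tic[interior] <= mean_tic[interior - 1L] &
    mean_tic[interior] <= mean_tic[interior + 1L]
  cand <- interior[is_valley]
  n_b <- target_count - 1L
  if (length(cand) >= n_b && stats::sd(mean_tic) > 0) {
    # deepest valleys; ties and order resolved by earliest scan
    sel <- cand[order(mean_tic[cand], cand)][seq_len(n_b)]
  } else {
    sel <- round(seq(1L, I, length.out = target_count + 1L))[2:target_count]
  }
  bounds <- c(times[1L], times[sort(sel)],
              times[I] + diff(times[I - (1:0)]))
  lapply(seq_len(target_count), function(i) {
    rt_interval(bounds[i], bounds[i + 1L], sprintf("iv%02d", i))
  })
}

#' Assemble the sample x elution x mass cube for one interval
#'
#' Slab k holds member k's scans with `start <= scan_time < end`, all m/z
#' columns. All members of a co-registered set contribute the same scan
#' rows, so slabs share both dimensions.
#'
#' @param set a `replicate_set`.
#' @param interval an [rt_interval()].
#' @return object of class `interval_cube`: list with `slabs` (K matrices
#'   I_int x J), `interval`, `scan_times`, `mz_axis`.
#' @export
build_cube <- function(set, interval) {
  stopifnot(inherits(set, "replicate_set"), inherits(interval, "rt_interval"))
  times <- set$members[[1L]]$scan_times
  rows <- which(times >= interval$start & times < interval$end)
  if (length(rows) < 2L) {
    stop(sprintf("interval '%s' covers %d scan(s); at least 2 are required",
                 interval$label, length(rows)))
  }
  slabs <- lapply(set$members, function(m) {
    m$intensities[rows, , drop = FALSE]
  })
  structure(
    list(slabs = slabs, interval = interval,
         scan_times = times[rows], mz_axis = set$members[[1L]]$mz_axis),
    class = "interval_cube"
  )
}

#' @export
print.interval_cube <- function(x, ...) {
  cat(sprintf("interval_cube '%s': K=%d members, %d scans x %d m/z bins\n",
              x$interval$label, length(x$slabs),
              nrow(x$slabs[[1L]]), ncol(x$slabs[[1L]])))
  invisible(x)
}
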