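#' Per-assay differential thresholds
#'
#' The default thresholds used to call a site changed at a time point:
#' linear fold change above `fc_min` (strict inequality on
#' `|log2fc| > log2(fc_min)`) and FDR strictly below `fdr_max`. Accessibility
#' and histone-mark assays use FC > 1.5 with FDR < 1e-5; EP300 occupancy uses
#' the laxer FC > 1.2 with FDR < 0.2.
#'
#' @param assay One of `"accessibility"`, `"EP300"`, `"H3K27ac"`,
#'   `"H3K27me3"`, or `NULL` to set thresholds explicitly.
#' @param fc_min Minimum linear fold change (> 1).
#' @param fdr_max Maximum FDR (in (0, 1]).
#' @return A list of class `threshold_config` with elements `fc_min`,
#'   `fdr_max`.
#' @export
#' @examples
#' threshold_config("EP300")
threshold_config <- function(assay = NULL, fc_min = NULL, fdr_max = NULL) {
  if (!is.null(assay)) {
    assay <- match.arg(assay, ASSAYS)
    defaults <- if (assay == "EP300") list(fc_min = 1.2, fdr_max = 0.2)
                else list(fc_min = 1.5, fdr_max = 1e-5)
    fc_min <- fc_min %||% defaults$fc_min
    fdr_max <- fdr_max %||% defaults$fdr_max
  }
  if (is.null(fc_min) || is.null(fdr_max)) {
    abort("supply `assay` or both `fc_min` and `fdr_max`")
  }
  if (!(is.numeric(fc_min) && fc_min > 1)) abort("`fc_min` must be > 1")
  if (!(is.numeric(fdr_max) && fdr_max > 0 && fdr_max <= 1)) {
    abort("`fdr_max` must be in (0, 1]")
  }
  structure(list(fc_min = fc_min, fdr_max = fdr_max),
            class = "threshold_config")
}

#' Classify the first significant change of a single time course
#'
#' The first-change time is the smallest time point at which
#' `|log2fc| > log2(fc_min)` and `fdr < fdr_max` hold simultaneously; the
#' direction is the sign of the log2 fold change at that time point (negative
#' is `"lost"`). Later sign reversals do not reclassify the site.
#'
#' @param log2fc,fdr Numeric vectors named (or ordered) by the five time
#'   points in hours.
#' @param thresholds A [threshold_config()].
#' @return A list with `direction` (`"lost"`, `"gained"` or `"none"`) and
#'   `first_change_time` (hours, or `NA` for never).
#' @export
#' @examples
#' classify_first_change(c(-0.2, -0.7, -0.9, -1.0, -1.1), rep(1e-9, 5),
#'                       threshold_config("accessibility"))
classify_first_change <- function(log2fc, fdr, thresholds = threshold_config("accessibility")) {
  if (length(log2fc) != length(TIMEPOINTS_H) || length(fdr) != length(TIMEPOINTS_H) ||
      anyNA(log2fc) || anyNA(fdr)) {
    abort(sprintf("need complete log2fc and fdr values at all %d time points",
                  length(TIMEPOINTS_H)))
  }
  hit <- abs(log2fc) > log2(thresholds$fc_min) & fdr < thresholds$fdr_max
  if (!any(hit)) return(list(direction = "none", first_change_time = NA_real_))
  i <- which(hit)[1]
  list(direction = if (log2fc[i] < 0) "lost" else "gained",
       first_change_time = TIMEPOINTS_H[i])
}

#' Classify direction and earliest change time for a site table
#'
#' Vectorised classification of a long site time-course table. Each site is
#' classified independently of all others; per-site output equals
#' [classify_first_change()] on that site's five-point trajectory.
#'
#' @param sites Long tibble with columns `site_id`, `chrom`, `start`, `end`,
#'   `assay`, `time`, `log2fc`, `fdr` (planted truth columns, if present, are
#'   carried through).
#' @param thresholds A [threshold_config()], applied to every row; classify
#'   per-assay subsets separately when assays need different thresholds.
#' @return One row per site: the site metadata plus `direction` and
#'   `first_change_time` (`NA` = never).
#' @export
classify_changes <- function(sites, thresholds = threshold_config("accessibility")) {
  assert_timecourse(sites, "site_id", "site time courses")
  assert_intervals(sites, "site time courses")
  stopifnot(inherits(thresholds, "threshold_config"))
  meta_cols <- setdiff(names(sites), c("time", "log2fc", "fdr"))
  meta <- distinct(sites, across(dplyr::all_of(meta_cols)))
  if (anyDuplicated(meta$site_id)) {
    abort("site metadata (coordinates/assay/planted columns) must be constant within a site_id")
  }
  hits <- sites |>
    filter(abs(.data$log2fc) > log2(thresholds$fc_min),
           .data$fdr < thresholds$fdr_max) |>
    group_by(.data$site_id) |>
    slice_min(.data$time, n = 1, with_ties = FALSE) |>
    ungroup() |>
    mutate(direction = if_else(.data$log2fc < 0, "lost", "gained"),
           first_change_time = .data$time) |>
    select("site_id", "direction", "first_change_time")
  meta |>
    left_join(hits, by = "site_id") |>
    mutate(direction = dplyr::coalesce(.data$direction, "none")) |>
    as_tibble()
}

#' Order classified sites by first-change time
#'
#' Stable deterministic ordering used for first-change heatmaps: lost sites
#' first, then gained, then unchanged; within a direction by increasing
#' first-change time; ties broken by genomic coordinate.
#'
#' @param classifications Output of [classify_changes()].
#' @return The same tibble, reordered.
#' @export
order_sites <- function(classifications) {
  assert_cols(classifications, c("direction", "first_change_time", "chrom", "start"),
              "classifications")
  arrange(classifications,
          factor(.data$direction, levels = c("lost", "gained", "none")),
          .data$first_change_time, .data$chrom, .data$start, .data$end)
}

#' Consensus peaks across replicate peak sets
#'
#' Retains genomic loci where at least `min_overlap` replicate peak sets
#' overlap by >= 1 bp (assessed base-wise: positions covered by peaks from at
#' least `min_overlap` distinct replicates seed a consensus locus). The
#' reported consensus interval is the merged union of all replicate peaks
#' touching such a locus.
#'
#' @param peak_sets A list of interval tibbles (`chrom`, `start`, `end`), one
#'   per replicate.
#' @param min_overlap Minimum number of replicates that must share a base.
#' @return A tibble of merged consensus intervals.
#' @export
consensus_filter <- function(peak_sets, min_overlap = 3) {
  if (!is.list(peak_sets) || length(peak_sets) == 0) {
    abort("`peak_sets` must be a non-empty list of interval tables")
  }
  if (!is_count(min_overlap) || min_overlap < 1) {
    abort("`min_overlap` must be a positive count")
  }
  if (min_overlap > length(peak_sets)) {
    abort(sprintf("min_overlap (%d) exceeds the number of replicate sets (%d)",
                  min_overlap, length(peak_sets)))
  }
  purrr::walk(peak_sets, assert_intervals, what = "replicate peaks")
  all_peaks <- bind_rows(peak_sets, .id = ".rep")
  out <- all_peaks |>
    group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      width <- max(d$end)
      # per-replicate reduced coverage so replicate-internal overlap counts once
      cov <- Reduce(`+`, lapply(split(d, d$.rep), function(r) {
        IRanges::coverage(IRanges::reduce(as_iranges(r$start, r$end)),
                          width = width)
      }))
      cores <- IRanges::IRanges(IRanges::slice(cov, lower = min_overlap,
                                               rangesOnly = TRUE))
      ir <- as_iranges(d$start, d$end)
      keep <- IRanges::overlapsAny(ir, cores)
      iranges_to_bed(IRanges::reduce(ir[keep]))
    }) |>
    ungroup()
  as_tibble(out[, c("chrom", "start", "end")])
}
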