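# TSV/BED readers and writers for the documented schemas. Coordinates are
# 0-based half-open everywhere; time-course TSVs are wide
# (log2FC_<t>/FDR_<t> for t in {2,6,18,54,162}) as produced by upstream
# differential callers.

tc_wide_cols <- function() {
  c(paste0("log2FC_", TIMEPOINTS_H), paste0("FDR_", TIMEPOINTS_H))
}

#' Write a long time-course table as a wide TSV
#'
#' Non-measurement columns (ids, coordinates, assay, planted truth) are kept
#' as leading columns; `log2fc`/`fdr` are spread into `log2FC_<t>` and
#' `FDR_<t>` columns.
#'
#' @param x Long tibble with `time`, `log2fc`, `fdr` and any id columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_timecourse_tsv <- function(x, path) {
  assert_cols(x, c("time", "log2fc", "fdr"), "time course")
  wide <- x |>
    tidyr::pivot_wider(names_from = "time",
                       values_from = c("log2fc", "fdr"),
                       names_glue = "{.value}_{time}") |>
    dplyr::rename_with(~ sub("^log2fc_", "log2FC_", sub("^fdr_", "FDR_", .x)))
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read a wide time-course TSV into long form
#'
#' Validates that all five time points are present, that FDRs lie in
#' `[0, 1]` and (when coordinates are present) that `start < end`; offending
#' rows are reported by number.
#'
#' @param path TSV written by [write_timecourse_tsv()] or an upstream
#'   differential caller using the same schema.
#' @return A long tibble with `time`, `log2fc`, `fdr` and the id columns.
#' @export
read_timecourse_tsv <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(tc_wide_cols(), names(wide))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing column(s) %s", path,
                  paste(missing, collapse = ", ")))
  }
  if (all(c("start", "end") %in% names(wide))) {
    bad <- which(!(wide$start < wide$end))
    if (length(bad) > 0) {
      abort(sprintf("%s: start >= end in row(s) %s", path,
                    paste(head(bad, 5), collapse = ", ")))
    }
  }
  for (t in TIMEPOINTS_H) {
    f <- wide[[paste0("FDR_", t)]]
    bad <- which(is.na(f) | f < 0 | f > 1)
    if (length(bad) > 0) {
      abort(sprintf("%s: FDR_%s outside [0, 1] in row(s) %s", path, t,
                    paste(head(bad, 5), collapse = ", ")))
    }
  }
  long <- wide |>
    tidyr::pivot_longer(dplyr::all_of(tc_wide_cols()),
                        names_to = c(".value", "time"), names_sep = "_") |>
    dplyr::rename(log2fc = "log2FC", fdr = "FDR") |>
    mutate(time = as.numeric(.data$time))
  arrange(long, dplyr::pick(dplyr::any_of(c("gene_id", "site_id"))), .data$time)
}

#' Read a BED-style interval file
#'
#' Supports 3-6 columns (`chrom`, `start`, `end`, `name`, `score`,
#' `strand`); column names can be overridden for dialects such as 4-column
#' state segmentations. Tolerates a missing trailing newline. Rows with
#' `start >= end` are rejected with their line numbers.
#'
#' @param path BED file.
#' @param col_names Names to assign, by position.
#' @return A tibble.
#' @export
read_bed <- function(path, col_names = c("chrom", "start", "end", "name",
                                         "score", "strand")) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(raw) < 3) abort(sprintf("%s: BED needs at least 3 columns", path))
  names(raw) <- col_names[seq_len(min(ncol(raw), length(col_names)))]
  if (!is.numeric(raw$start) || !is.numeric(raw$end)) {
    abort(sprintf("%s: start/end must be integer coordinates", path))
  }
  bad <- which(!(raw$start < raw$end))
  if (length(bad) > 0) {
    abort(sprintf("%s: start >= end on line(s) %s", path,
                  paste(head(bad, 5), collapse = ", ")))
  }
  as_tibble(raw)
}

#' Write intervals as BED
#'
#' Writes the available columns among `chrom`, `start`, `end`, `name`,
#' `score`, `strand` (or an explicit column selection, e.g.
#' `c("chrom", "start", "end", "state")` for a segmentation), headerless and
#' tab-separated.
#'
#' @param x Interval tibble.
#' @param path Output file.
#' @param columns Columns to write, in order.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, columns = intersect(c("chrom", "start", "end",
                                                     "name", "score", "strand"),
                                                   names(x))) {
  assert_intervals(x, "bed intervals")
  readr::write_tsv(x[, columns, drop = FALSE], path, col_names = FALSE)
  invisible(path)
}

#' Write a site classification as BED6+2
#'
#' Columns: `chrom`, `start`, `end`, `site_id`, score 0, strand `.`,
#' `direction`, `first_change_time` (`"never"` for unchanged sites).
#'
#' @param classification Output of [classify_changes()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_classification_bed <- function(classification, path) {
  assert_cols(classification, c("chrom", "start", "end", "site_id",
                                "direction", "first_change_time"),
              "classification")
  out <- tibble(chrom = classification$chrom, start = classification$start,
                end = classification$end, name = classification$site_id,
                score = 0L, strand = ".",
                direction = classification$direction,
                first_change_time = ifelse(
                  is.na(classification$first_change_time), "never",
                  as.character(classification$first_change_time)))
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
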