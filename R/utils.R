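# Internal helpers shared across modules.

# Intervals are 0-based half-open [start, end) throughout (BED dialect);
# IRanges is 1-based closed, so conversion adds 1 to start only.
as_iranges <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

iranges_to_bed <- function(ir) {
  tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Validates a long time-course table: every id has exactly the five time
# points, FDR in [0, 1].
assert_timecourse <- function(df, id_col, what = "time course") {
  assert_cols(df, c(id_col, "time", "log2fc", "fdr"), what)
  bad_fdr <- which(is.na(df$fdr) | df$fdr < 0 | df$fdr > 1)
  if (length(bad_fdr) > 0) {
    abort(sprintf("%s: FDR outside [0, 1] in row(s) %s",
                  what, paste(head(bad_fdr, 5), collapse = ", ")))
  }
  tp <- tapply(df$time, df[[id_col]], function(t) {
    length(t) == length(TIMEPOINTS_H) && all(sort(t) == TIMEPOINTS_H)
  })
  if (!all(tp)) {
    offenders <- names(tp)[!tp]
    abort(sprintf("%s: missing or duplicated time points for %d id(s) (e.g. %s); expected exactly {%s} h",
                  what, length(offenders), paste(head(offenders, 3), collapse = ", "),
                  paste(TIMEPOINTS_H, collapse = ",")))
  }
  invisible(df)
}

assert_intervals <- function(df, what = "intervals") {
  assert_cols(df, c("chrom", "start", "end"), what)
  bad <- which(!(df$start < df$end))
  if (length(bad) > 0) {
    abort(sprintf("%s: start >= end in row(s) %s", what,
                  paste(head(bad, 5), collapse = ", ")))
  }
  invisible(df)
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)

is_prop <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
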