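# ggplot2 views of the main result types.

#' Plot a nucleosome midpoint metaprofile
#'
#' @param object A `nuc_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nuc_profile
#' @export
autoplot.nuc_profile <- function(object, ...) {
  y <- if ("enrichment" %in% names(object)) "enrichment" else "count"
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$offset, y = .data[[y]])) +
    ggplot2::geom_line(colour = "#b2182b") +
    ggplot2::labs(x = "distance from motif centre (bp)",
                  y = if (y == "enrichment") "midpoint enrichment"
                      else "midpoint count",
                  title = sprintf("%d sites%s", attr(object, "n_sites"),
                                  if (isTRUE(attr(object, "smoothed")))
                                    ", smoothed" else "")) +
    ggplot2::theme_minimal()
}

#' Plot per-quintile enrichment as -log10 PMF bars
#'
#' @param object An `enrichment_result` from [cohort_enrichment()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  d <- mutate(as_tibble(object),
              quintile = factor(dplyr::coalesce(as.character(.data$quintile),
                                                "all")))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$quintile,
                                       y = .data$neg_log10_pmf)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "fold-change quintile (1 = most repressed)",
                  y = expression(-log[10] ~ "PMF")) +
    ggplot2::theme_minimal()
  if ("change_key" %in% names(d)) {
    p + ggplot2::facet_grid(ggplot2::vars(.data$change_key),
                            ggplot2::vars(.data$cohort))
  } else {
    p + ggplot2::facet_wrap(ggplot2::vars(.data$cohort))
  }
}

#' Stacked percent-with-change bars by first-change time
#'
#' The Fig-style stacked decomposition: for each quintile, the percentage of
#' genes whose earliest linked chromatin change is first detected at each
#' time point.
#'
#' @param pct Output of [percent_with_change()] with
#'   `stratify_by_time = TRUE`.
#' @return A ggplot.
#' @export
plot_percent_with_change <- function(pct) {
  assert_cols(pct, c("cohort", "quintile", "first_change_time", "percent"),
              "pct")
  d <- mutate(pct,
              quintile = factor(dplyr::coalesce(as.character(.data$quintile),
                                                "all")),
              first_change_time = factor(.data$first_change_time,
                                         levels = TIMEPOINTS_H))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$quintile, y = .data$percent,
                                  fill = .data$first_change_time)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_viridis_d(name = "first change (h)") +
    ggplot2::facet_wrap(ggplot2::vars(.data$cohort)) +
    ggplot2::labs(x = "fold-change quintile (1 = most repressed)",
                  y = "% of genes with a linked change") +
    ggplot2::theme_minimal()
}
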