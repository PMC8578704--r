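#' Promoter and enhancer window configuration
#'
#' Windows are TSS-centred and symmetric: the promoter window is
#' `[TSS - promoter_halfwidth, TSS + promoter_halfwidth)` and the enhancer
#' window extends to `enhancer_halfwidth` either side of the TSS but excludes
#' the promoter window. Histone genes are excluded by default because many
#' other genes reside within 50 kb of them.
#'
#' @param promoter_halfwidth Promoter half-width in bp (default 500).
#' @param enhancer_halfwidth Enhancer half-width in bp (default 50,000).
#' @param exclude_histone_genes Drop histone-flagged genes before linkage.
#' @return A list of class `window_config`.
#' @export
window_config <- function(promoter_halfwidth = 500,
                          enhancer_halfwidth = 50000,
                          exclude_histone_genes = TRUE) {
  if (!(promoter_halfwidth > 0 && promoter_halfwidth < enhancer_halfwidth)) {
    abort("need 0 < promoter_halfwidth < enhancer_halfwidth")
  }
  structure(list(promoter_halfwidth = promoter_halfwidth,
                 enhancer_halfwidth = enhancer_halfwidth,
                 exclude_histone_genes = isTRUE(exclude_histone_genes)),
            class = "window_config")
}

#' Link classified chromatin sites to gene windows
#'
#' A site is promoter-linked to a gene when its interval overlaps the
#' promoter window by >= 1 bp, and enhancer-linked when it overlaps the
#' enhancer window by >= 1 bp without being promoter-linked to that gene
#' (the two are mutually exclusive per gene-site pair). A site may link to
#' several genes. Coordinates are 0-based half-open on both sides.
#'
#' @param genes Gene table with `gene_id`, `chrom`, `tss` and (if histone
#'   exclusion is on) `is_histone`.
#' @param sites Classified site table with `site_id`, `chrom`, `start`,
#'   `end`; extra columns such as `assay`, `direction`, `first_change_time`
#'   are carried through.
#' @param windows A [window_config()].
#' @return A pair tibble with one row per linked (gene, site) pair:
#'   `gene_id`, `site_id`, `linkage` (`"promoter"`/`"enhancer"`) plus the
#'   carried site columns.
#' @export
link_changes_to_genes <- function(genes, sites, windows = window_config()) {
  assert_cols(genes, c("gene_id", "chrom", "tss"), "genes")
  assert_intervals(sites, "sites")
  assert_cols(sites, "site_id", "sites")
  stopifnot(inherits(windows, "window_config"))
  if (windows$exclude_histone_genes) {
    assert_cols(genes, "is_histone", "genes")
    genes <- filter(genes, !.data$is_histone)
  }
  bad <- setdiff(unique(sites$chrom), unique(genes$chrom))
  if (length(bad) > 0) {
    abort(sprintf("sites on chromosome(s) absent from the gene table: %s",
                  paste(bad, collapse = ", ")))
  }
  carried <- setdiff(names(sites), c("chrom", "start", "end"))
  pairs_for <- function(halfwidth) {
    purrr::map_dfr(split(seq_len(nrow(sites)), sites$chrom), function(idx) {
      g <- genes[genes$chrom == sites$chrom[idx[1]], , drop = FALSE]
      if (nrow(g) == 0) return(NULL)
      win <- as_iranges(pmax(0, g$tss - halfwidth), g$tss + halfwidth)
      hit <- IRanges::findOverlaps(as_iranges(sites$start[idx], sites$end[idx]), win)
      tibble(gene_id = g$gene_id[S4Vectors::subjectHits(hit)],
             .row = idx[S4Vectors::queryHits(hit)])
    })
  }
  prom <- pairs_for(windows$promoter_halfwidth)
  enh <- pairs_for(windows$enhancer_halfwidth)
  prom$linkage <- "promoter"
  enh <- anti_join(enh, prom, by = c("gene_id", ".row"))
  enh$linkage <- "enhancer"
  out <- bind_rows(prom, enh)
  out <- dplyr::bind_cols(out["gene_id"], sites[out$.row, carried, drop = FALSE],
                          out["linkage"])
  arrange(as_tibble(out), .data$gene_id, .data$site_id)
}

#' Intersect two change-site sets
#'
#' Splits two interval sets by >= 1 bp overlap (half-open convention:
#' `[100,200)` and `[199,300)` share one base). `both` holds the intervals of
#' `a` that overlap at least one interval of `b`; symmetric counts for both
#' sides are attached as the `"counts"` attribute (`both_a` and `both_b`
#' report A-intervals-overlapping-B and vice versa, since the two sets need
#' not pair one-to-one).
#'
#' @param a,b Interval tibbles (`chrom`, `start`, `end`, extra columns kept).
#' @return A list with tibbles `a_only`, `b_only`, `both`, and a `counts`
#'   attribute.
#' @export
intersect_change_sets <- function(a, b) {
  assert_intervals(a, "a"); assert_intervals(b, "b")
  hit_a <- rep(FALSE, nrow(a))
  hit_b <- rep(FALSE, nrow(b))
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch); ib <- which(b$chrom == ch)
    ra <- as_iranges(a$start[ia], a$end[ia])
    rb <- as_iranges(b$start[ib], b$end[ib])
    hit_a[ia] <- IRanges::overlapsAny(ra, rb)
    hit_b[ib] <- IRanges::overlapsAny(rb, ra)
  }
  structure(list(a_only = a[!hit_a, , drop = FALSE],
                 b_only = b[!hit_b, , drop = FALSE],
                 both = a[hit_a, , drop = FALSE]),
            counts = c(a_only = sum(!hit_a), b_only = sum(!hit_b),
                       both_a = sum(hit_a), both_b = sum(hit_b)))
}

#' Annotate sites with chromatin states
#'
#' Assigns each site the state of maximal overlap with a tiling segmentation
#' (ties broken by the leftmost state) and reports the fraction of sites per
#' state, which sums to 1.
#'
#' @param sites Interval tibble with `site_id`, `chrom`, `start`, `end`.
#' @param segmentation Tiling segmentation (`chrom`, `start`, `end`, `state`).
#' @return A tibble `state`, `n_sites`, `fraction` (every segmentation state
#'   appears, zero counts included). Per-site assignments are attached as the
#'   `"assignments"` attribute.
#' @export
annotate_states <- function(sites, segmentation) {
  assert_intervals(sites, "sites"); assert_cols(sites, "site_id", "sites")
  assert_intervals(segmentation, "segmentation")
  assert_cols(segmentation, "state", "segmentation")
  bad <- setdiff(unique(sites$chrom), unique(segmentation$chrom))
  if (length(bad) > 0) {
    abort(sprintf("sites on chromosome(s) absent from the segmentation: %s",
                  paste(bad, collapse = ", ")))
  }
  assignments <- purrr::map_dfr(split(seq_len(nrow(sites)), sites$chrom), function(idx) {
    seg <- segmentation[segmentation$chrom == sites$chrom[idx[1]], , drop = FALSE]
    rs <- as_iranges(sites$start[idx], sites$end[idx])
    rg <- as_iranges(seg$start, seg$end)
    hit <- IRanges::findOverlaps(rs, rg)
    q <- S4Vectors::queryHits(hit); s <- S4Vectors::subjectHits(hit)
    if (length(q) < length(idx)) {
      miss <- setdiff(seq_along(idx), unique(q))
      abort(sprintf("site(s) not covered by the segmentation: %s",
                    paste(head(sites$site_id[idx[miss]], 5), collapse = ", ")))
    }
    ov <- IRanges::width(IRanges::pintersect(rs[q], rg[s]))
    tibble(site_id = sites$site_id[idx[q]], state = seg$state[s],
           overlap = ov, seg_start = seg$start[s]) |>
      group_by(.data$site_id) |>
      arrange(dplyr::desc(.data$overlap), .data$seg_start, .by_group = TRUE) |>
      dplyr::slice(1) |>
      ungroup()
  })
  counts <- table(factor(assignments$state, levels = unique(segmentation$state)))
  out <- tibble(state = names(counts), n_sites = as.integer(counts),
                fraction = as.integer(counts) / nrow(sites))
  attr(out, "assignments") <- select(assignments, "site_id", "state")
  out
}
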