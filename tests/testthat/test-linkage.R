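toy_genes <- function(tss, histone = FALSE) {
  tibble::tibble(gene_id = sprintf("g%02d", seq_along(tss)), chrom = "chrT",
                 tss = tss, strand = "+", is_histone = histone)
}

toy_sites <- function(start, end) {
  tibble::tibble(site_id = sprintf("s%03d", seq_along(start)), chrom = "chrT",
                 start = start, end = end, assay = "accessibility",
                 direction = "lost", first_change_time = 2)
}

test_that("promoter and enhancer windows use half-open overlap arithmetic", {
  genes <- toy_genes(1e6)
  link <- link_changes_to_genes(genes, toy_sites(1000300, 1000450))
  expect_equal(link$linkage, "promoter")
  link <- link_changes_to_genes(genes, toy_sites(1049000, 1049200))
  expect_equal(link$linkage, "enhancer")
  # just outside the 50-kb window (half-open): no link
  link <- link_changes_to_genes(genes, toy_sites(1050000, 1050100))
  expect_equal(nrow(link), 0)
  # 1-bp overlap with the promoter edge counts as promoter
  link <- link_changes_to_genes(genes, toy_sites(999499, 999501))
  expect_equal(link$linkage, "promoter")
  expect_error(
    link_changes_to_genes(genes, dplyr::mutate(toy_sites(10, 20), chrom = "chrX")),
    "chrX")
})

test_that("histone genes are excluded when configured", {
  genes <- dplyr::bind_rows(toy_genes(1e6, histone = TRUE),
                            dplyr::mutate(toy_genes(2e6), gene_id = "g99"))
  sites <- toy_sites(c(1000100, 2000100), c(1000200, 2000200))
  link <- link_changes_to_genes(genes, sites)
  expect_equal(unique(link$gene_id), "g99")
  link_all <- link_changes_to_genes(
    genes, sites, window_config(exclude_histone_genes = FALSE))
  expect_setequal(unique(link_all$gene_id), c("g01", "g99"))
})

test_that("linkage matches a brute-force all-pairs oracle", {
  set.seed(303)
  genes <- toy_genes(sort(sample(seq(60000, 2e6, by = 1), 20)))
  start <- sample(0:2.1e6, 200)
  sites <- toy_sites(start, start + sample(50:800, 200, replace = TRUE))
  link <- link_changes_to_genes(genes, sites)

  overlaps <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1
  oracle <- purrr::map_dfr(seq_len(nrow(genes)), function(gi) {
    purrr::map_dfr(seq_len(nrow(sites)), function(si) {
      tss <- genes$tss[gi]
      prom <- overlaps(sites$start[si], sites$end[si],
                       max(0, tss - 500), tss + 500)
      enh <- overlaps(sites$start[si], sites$end[si],
                      max(0, tss - 50000), tss + 50000) && !prom
      if (!prom && !enh) return(NULL)
      tibble::tibble(gene_id = genes$gene_id[gi], site_id = sites$site_id[si],
                     linkage = if (prom) "promoter" else "enhancer")
    })
  })
  expect_same_rows(dplyr::select(link, gene_id, site_id, linkage), oracle,
                   c("gene_id", "site_id"))
  # invariance to input ordering
  link_perm <- link_changes_to_genes(genes[sample(20), ], sites[sample(200), ])
  expect_same_rows(dplyr::select(link_perm, gene_id, site_id, linkage),
                   dplyr::select(link, gene_id, site_id, linkage),
                   c("gene_id", "site_id", "linkage"))
  # promoter and enhancer linkage are mutually exclusive per pair
  expect_equal(anyDuplicated(link[, c("gene_id", "site_id")]), 0)
})

test_that("change-set intersection follows the half-open 1-bp convention", {
  a <- tibble::tibble(chrom = "chrT", start = 100, end = 200)
  b_touch <- tibble::tibble(chrom = "chrT", start = 199, end = 300)
  b_abut <- tibble::tibble(chrom = "chrT", start = 200, end = 300)
  r <- intersect_change_sets(a, b_touch)
  expect_equal(nrow(r$both), 1)
  expect_equal(nrow(r$a_only), 0)
  r <- intersect_change_sets(a, b_abut)
  expect_equal(nrow(r$both), 0)
  expect_equal(nrow(r$a_only), 1)
  expect_equal(nrow(r$b_only), 1)

  r <- intersect_change_sets(a, a)
  expect_equal(nrow(r$both), 1)
  expect_equal(nrow(r$a_only) + nrow(r$b_only), 0)
  expect_equal(attr(r, "counts")[["both_b"]], 1)
})

test_that("state annotation assigns maximal overlap with leftmost tie-break", {
  seg <- tibble::tibble(chrom = "chrT", start = c(0, 1000, 2000),
                        end = c(1000, 2000, 3000),
                        state = c("A", "B", "C"))
  inside <- tibble::tibble(site_id = "s1", chrom = "chrT", start = 100, end = 300)
  res <- annotate_states(inside, seg)
  expect_equal(res$fraction[res$state == "A"], 1)
  expect_equal(sum(res$fraction), 1)

  straddle <- tibble::tibble(site_id = "s2", chrom = "chrT",
                             start = 940, end = 1040) # 60 bp in A, 40 in B
  res <- annotate_states(straddle, seg)
  expect_equal(attr(res, "assignments")$state, "A")

  tie <- tibble::tibble(site_id = "s3", chrom = "chrT", start = 950, end = 1050)
  expect_equal(attr(annotate_states(tie, seg), "assignments")$state, "A")

  expect_error(annotate_states(dplyr::mutate(inside, chrom = "chrZ"), seg), "chrZ")
  outside <- tibble::tibble(site_id = "s4", chrom = "chrT",
                            start = 5000, end = 5100)
  expect_error(annotate_states(outside, seg), "not covered")
})

test_that("uniform sites reproduce state genome fractions within multinomial bounds", {
  cfg <- small_cfg()
  seg <- simulate_state_segmentation(cfg)
  genome_frac <- seg |>
    dplyr::group_by(state) |>
    dplyr::summarise(frac = sum(end - start) / cfg$chrom_length)
  set.seed(404)
  n <- 4000
  start <- sample.int(cfg$chrom_length - 10, n)
  sites <- tibble::tibble(site_id = sprintf("s%04d", 1:n), chrom = cfg$chrom,
                          start = start, end = start + 10)
  res <- annotate_states(sites, seg)
  expect_equal(sum(res$fraction), 1, tolerance = 1e-12)
  joined <- dplyr::left_join(res, genome_frac, by = "state")
  for (i in seq_len(nrow(joined))) {
    lo <- qbinom(0.005, n, joined$frac[i]) / n
    hi <- qbinom(0.995, n, joined$frac[i]) / n
    expect_gte(joined$fraction[i], lo)
    expect_lte(joined$fraction[i], hi)
  }
})
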