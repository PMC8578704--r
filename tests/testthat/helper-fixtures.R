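# Shared fixtures: everything is generated in code at test time.

# A chromosome small enough for fast tests but wide enough for 50-kb windows.
small_cfg <- function(seed = 42, ...) {
  args <- utils::modifyList(list(seed = seed, chrom_length = 2.2e7,
                                 n_genes = 200), list(...))
  do.call(sim_config, args)
}

# Build a single-site long time course from per-time vectors.
make_site_tc <- function(log2fc, fdr, site_id = "s1", assay = "accessibility",
                         start = 1000, end = 1400) {
  tibble::tibble(site_id = site_id, chrom = "chrT", start = start, end = end,
                 assay = assay, time = c(2, 6, 18, 54, 162),
                 log2fc = log2fc, fdr = fdr)
}

make_gene_tc <- function(gene_id, log2fc, fdr) {
  tibble::tibble(gene_id = gene_id, time = c(2, 6, 18, 54, 162),
                 log2fc = log2fc, fdr = fdr)
}

# Exhaustive subset-enumeration oracle for the hypergeometric PMF: mark the
# first M of N elements, enumerate all size-n subsets, count those with
# exactly x marked. Exact for small N.
enumerate_hyper_pmf <- function(x, n, M, N) {
  if (n == 0) return(as.numeric(x == 0))
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= M)
  sum(hits == x) / ncol(subsets)
}

# Brute-force per-base replicate coverage used as the consensus-peak oracle.
brute_consensus_coverage <- function(peak_sets, pos) {
  vapply(pos, function(p) {
    sum(vapply(peak_sets, function(s) {
      any(s$start <= p & p < s$end)
    }, TRUE))
  }, 1L)
}

expect_same_rows <- function(a, b, key_cols) {
  expect_equal(dplyr::arrange(a, dplyr::across(dplyr::all_of(key_cols))),
               dplyr::arrange(b, dplyr::across(dplyr::all_of(key_cols))))
}

# Wrap a bare numeric vector (odd length) as an unsmoothed profile object.
new_profile_for_test <- function(v, n_sites = 1, total_reads = 1) {
  h <- (length(v) - 1) / 2
  new_nuc_profile(offset = seq(-h, h), count = v, n_sites = n_sites,
                  total_reads = total_reads)
}
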