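test_that("hypergeometric PMF matches exhaustive subset enumeration", {
  # frozen expected value computed with the enumeration oracle:
  # 36 of the 120 size-3 subsets of a 10-element set with 4 marked elements
  # contain exactly 2 marked, so pmf = 0.3
  expect_equal(enumerate_hyper_pmf(2, 3, 4, 10), 0.3)
  expect_identical(hypergeometric_pmf(2, 3, 4, 10), 0.3)

  expect_identical(hypergeometric_pmf(0, 0, 5, 10), 1)

  for (N in c(5, 8)) {
    for (M in 0:N) {
      for (n in 0:N) {
        for (x in max(0, n + M - N):min(n, M)) {
          expect_identical(hypergeometric_pmf(x, n, M, N),
                           enumerate_hyper_pmf(x, n, M, N))
        }
      }
    }
  }
})

test_that("hypergeometric PMF normalises, is symmetric and matches dhyper", {
  xs <- 0:5
  expect_equal(sum(hypergeometric_pmf(xs, 5, 6, 12)), 1, tolerance = 1e-12)

  set.seed(7)
  for (i in 1:25) {
    N <- sample(10:5000, 1)
    M <- sample(0:N, 1)
    n <- sample(0:N, 1)
    x <- sample(max(0, n + M - N):min(n, M), 1)
    p <- hypergeometric_pmf(x, n, M, N)
    expect_equal(p, hypergeometric_pmf(x, M, n, N), tolerance = 1e-12)
    expect_equal(p, dhyper(x, M, N - M, n), tolerance = 1e-12)
    if (p > 0) {
      expect_equal(hypergeometric_pmf(x, n, M, N, log10 = TRUE), -log10(p),
                   tolerance = 1e-12)
    }
  }
  # paper-scale parameters survive in log space
  nl <- hypergeometric_pmf(600, 3089, 5000, 12741, log10 = TRUE)
  expect_true(is.finite(nl))
  expect_equal(nl, -dhyper(600, 5000, 12741 - 5000, 3089, log = TRUE) / log(10),
               tolerance = 1e-9)

  expect_error(hypergeometric_pmf(4, 3, 10, 20), "inconsistent")
  expect_error(hypergeometric_pmf(2, 5, 1, 20), "inconsistent")
  expect_error(hypergeometric_pmf(0, 5, 19, 20), "inconsistent")
  expect_error(hypergeometric_pmf(1, 5, 4, 3), "N")
})

test_that("the PMF is maximal at the mode and shrinks toward the tail", {
  n <- 20; M <- 40; N <- 120
  xs <- 0:20
  p <- hypergeometric_pmf(xs, n, M, N)
  mode <- xs[which.max(p)]
  expect_equal(mode, floor((n + 1) * (M + 1) / (N + 2)))
  # strictly more surprising as x moves from the mode toward n
  expect_true(all(diff(p[xs >= mode]) < 0))
})

test_that("control-gene selection ranks by maximum squared fold change", {
  fcs <- c(0.3, 0.1, 0.5, 0.2, 0.4)
  expr <- purrr::map_dfr(1:5, function(i) {
    make_gene_tc(sprintf("g%d", i), c(0.01, fcs[i], 0.02, -0.03, 0.01),
                 rep(0.5, 5))
  })
  sel <- select_control_genes(expr, k = 3)
  expect_equal(sel$gene_id, c("g2", "g4", "g1"))

  # a gene significant at a single time point is excluded outright
  expr_sig <- dplyr::mutate(expr,
    fdr = ifelse(gene_id == "g2" & time == 54, 0.01, fdr))
  sel <- select_control_genes(expr_sig, k = 3)
  expect_equal(sel$gene_id, c("g4", "g1", "g5"))

  expect_warning(sel_all <- select_control_genes(expr, k = 10), "candidate")
  expect_equal(nrow(sel_all), 5)
  expect_false(attr(sel_all, "complete"))

  set.seed(8)
  shuffled <- expr[sample(nrow(expr)), ]
  expect_equal(select_control_genes(shuffled, k = 3)$gene_id,
               c("g2", "g4", "g1"))
})

test_that("control-gene selection matches a brute-force sort oracle", {
  cfg <- sim_config(seed = 15, n_genes = 1000, chrom_length = 1.1e8)
  expr <- simulate_expression_timecourse(simulate_genes(cfg), cfg)
  sel <- select_control_genes(expr, k = 200)
  wide <- expr |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(never = all(fdr >= 0.05), score = max(log2fc^2))
  oracle <- wide[wide$never, ]
  oracle <- oracle[order(oracle$score, oracle$gene_id), ]$gene_id[1:200]
  expect_equal(sel$gene_id, oracle)
})

test_that("cohort assignment splits early/late and builds deterministic quintiles", {
  mk <- function(id, fc6, fdr2 = 0.5, fdr6 = 0.01) {
    make_gene_tc(id, c(0, fc6, fc6, fc6, fc6), c(fdr2, fdr6, 0.01, 0.01, 0.01))
  }
  expr <- purrr::map_dfr(1:10, function(i) mk(sprintf("g%02d", i), i - 6))
  co <- assign_cohorts(expr)
  expect_true(all(co$cohort == "early"))
  expect_equal(sort(co$gene_id[co$quintile == 1]), c("g01", "g02"))
  expect_equal(sort(co$gene_id[co$quintile == 5]), c("g09", "g10"))

  expr11 <- dplyr::bind_rows(expr, mk("g11", 9))
  co11 <- assign_cohorts(expr11)
  expect_equal(as.integer(table(co11$quintile)), c(3L, 2L, 2L, 2L, 2L))
  expect_true(all(sort(co11$sort_log2fc[co11$quintile == 1]) ==
                    sort(head(sort(co11$sort_log2fc), 3))))

  # late gene: first significant at 54 h, sorted at 162 h
  late <- purrr::map_dfr(1:6, function(i) {
    make_gene_tc(sprintf("l%02d", i), c(0, 0, 0, i, i),
                 c(0.9, 0.9, 0.9, 0.01, 0.01))
  })
  both <- dplyr::bind_rows(expr, late)
  co2 <- assign_cohorts(both)
  expect_equal(sum(co2$cohort == "late"), 6)
  expect_equal(sum(co2$cohort == "early"), 10)
  expect_error(assign_cohorts(dplyr::bind_rows(expr, late[1:15, ])), "too small")

  fc_scheme <- assign_cohorts(both, scheme = "first_change")
  expect_setequal(unique(fc_scheme$cohort), c("6", "54"))

  # quintile sizes partition each cohort
  sizes <- dplyr::count(dplyr::filter(co2, cohort != "none"), cohort, quintile)
  expect_true(all(tapply(sizes$n, sizes$cohort, function(s) max(s) - min(s)) <= 1))
})

test_that("never-significant genes get no quintile", {
  ns <- make_gene_tc("gq", rep(0.01, 5), rep(0.6, 5))
  sig <- purrr::map_dfr(1:5, function(i) {
    make_gene_tc(sprintf("g%d", i), rep(i, 5), rep(0.01, 5))
  })
  co <- assign_cohorts(dplyr::bind_rows(ns, sig))
  expect_equal(co$cohort[co$gene_id == "gq"], "none")
  expect_true(is.na(co$quintile[co$gene_id == "gq"]))
})

test_that("percent_with_change counts genes once and stratifies additively", {
  cohorts <- tibble::tibble(gene_id = sprintf("g%d", 1:4), cohort = "early",
                            quintile = 1L)
  linkage <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g3"),  # duplicate linked site for g3
    site_id = c("s1", "s2", "s3", "s4"),
    assay = "accessibility", direction = "lost",
    first_change_time = c(2, 6, 2, 54), linkage = "enhancer")
  pct <- percent_with_change(cohorts, linkage)
  expect_equal(pct$percent, 75)
  expect_equal(pct$n_with_change, 3)

  none <- percent_with_change(cohorts, linkage[0, ])
  expect_equal(none$percent, 0)

  strat <- percent_with_change(cohorts, linkage, stratify_by_time = TRUE)
  expect_equal(sum(strat$percent), 75)
  # g3 is counted in its earliest stratum only
  expect_equal(strat$n_with_change[strat$first_change_time == 2], 2)
})

test_that("cohort enrichment reports consistent counts and probabilities", {
  cohorts <- tibble::tibble(gene_id = sprintf("g%02d", 1:20),
                            cohort = "early", quintile = rep(1:5, each = 4))
  linkage <- tibble::tibble(gene_id = sprintf("g%02d", 1:6),
                            site_id = sprintf("s%d", 1:6),
                            assay = "accessibility", direction = "lost",
                            first_change_time = 2, linkage = "enhancer")
  res <- cohort_enrichment(cohorts, linkage, universe = cohorts$gene_id)
  expect_equal(res$M[1], 6)
  expect_equal(res$N[1], 20)
  expect_equal(res$x[res$quintile == 1], 4)
  expect_equal(res$pmf,
               hypergeometric_pmf(res$x, res$n, res$M, res$N))
  expect_equal(res$neg_log10_pmf, -log10(res$pmf), tolerance = 1e-12)
  expect_error(cohort_enrichment(cohorts, linkage, universe = "g01"),
               "universe")
})
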