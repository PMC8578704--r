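# degrontime

Time-resolved integration of chromatin and transcription changes after acute
protein depletion.

When a chromatin regulator is destroyed within minutes by an inducible
degron, the genome responds in waves: accessibility and cofactor occupancy
change first at thousands of sites, transcription of a smaller gene cohort
follows, and indirect changes accumulate over days. The analytical problem
is to connect these layers: which chromatin changes are *functional*, i.e.
coupled to transcriptional change, and which are bystanders? `degrontime`
implements that integration for time-course designs measured at 2, 6, 18, 54
and 162 h versus an untreated reference, taking the per-site and per-gene
differential tables (log2 fold change + FDR) of upstream callers as input.
It is written for computational biologists analysing degron/perturbation
multi-omics (ATAC-seq, ChIP-seq, nascent-RNA-seq, MNase-seq).

## What it computes

* **First-change classification** — each site's direction (`lost`/`gained`)
  and the earliest time point where `|log2FC| > log2(fc_min)` and
  `FDR < fdr_max` (defaults: fold change > 1.5 at FDR < 1e-5;
  EP300: > 1.2 at FDR < 0.2), plus deterministic heatmap ordering and
  replicate consensus filtering.
* **Window linkage** — promoter (±500 bp of TSS) and enhancer (±50 kb,
  promoter excluded) assignment of classified sites to genes, change-set
  intersections (e.g. dual accessibility+EP300 loss), and chromatin-state
  annotation against a genome segmentation. All interval logic is 0-based
  half-open with ≥ 1 bp overlap.
* **Cohort enrichment** — gene cohorts by time of first significant
  expression change (FDR < 0.05), fold-change quintiles (1 = most
  repressed), a 500-gene minimum-change control set, percent-of-genes-with-
  change histograms, and enrichment scored by the exact hypergeometric
  point probability

  $$P(x)=\binom{M}{x}\binom{N-M}{n-x}\Big/\binom{N}{n},$$

  reported as −log₁₀ P, computed in log space so paper-scale inputs
  (N ≈ 12,741 transcribed genes, cohorts up to n ≈ 3,089) are exact.
* **Nucleosome metaprofiles** — fragment-midpoint aggregation over 2-kb
  windows at TF motifs, per-site/per-read enrichment normalisation, 30-bp
  moving-average smoothing, and the barrier metrics *w* (per-side
  half-width of the central dyad distribution) and *d* (distance to the
  adjacent nucleosome peak), plus between-condition profile comparison.
* **A seeded synthetic-data generator** with planted trajectory classes,
  coupled enhancer sites, background changes and nucleosome dyad mixtures,
  so the whole pipeline is testable end-to-end without downloads.

Everything takes and returns tibbles, chains with the pipe, and has
`autoplot()`/`tidy()`/`glance()` methods for the result objects.

## Worked example

```r
library(degrontime)
library(dplyr)

cfg   <- sim_config(seed = 1)                      # 2,000 genes, 220 Mb
genes <- simulate_genes(cfg)
expr  <- simulate_expression_timecourse(genes, cfg)
sites <- simulate_site_timecourses(genes, cfg)

cls  <- bind_rows(purrr::imap(split(sites, sites$assay),
                              \(tc, a) classify_changes(tc, threshold_config(a))))
dual <- intersect_change_sets(
  filter(cls, assay == "accessibility", direction == "lost"),
  filter(cls, assay == "EP300", direction == "lost"))$both

link    <- link_changes_to_genes(genes, dual)
cohorts <- assign_cohorts(expr)
cohort_enrichment(cohorts, link, universe = genes$gene_id,
                  linkage_types = "enhancer") |>
  filter(cohort == "early") |>
  select(quintile, x, n, M, N, percent, neg_log10_pmf)
#> # A tibble: 5 × 7
#>   quintile     x     n     M     N percent neg_log10_pmf
#>      <int> <int> <int> <int> <int>   <dbl>         <dbl>
#> 1        1    37    96   263  2000    38.5        10.1
#> 2        2    13    96   263  2000    13.5         0.919
#> 3        3    10    96   263  2000    10.4         1.02
#> 4        4    14    96   263  2000    14.6         0.967
#> 5        5    13    96   263  2000    13.5         0.919
```

Reading: of the 96 most-repressed early-responding genes, 38.5% have a site
losing both accessibility and EP300 within 50 kb of the TSS — against a
genome background of 263/2,000 ≈ 13% — an excess the hypergeometric PMF
puts at 10⁻¹⁰ by chance, while the other quintiles sit near the background
rate. This mirrors the planted generator truth (80% linked sites × 50% dual
loss = 40% of repressed genes).

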