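#' Configuration for the synthetic degron time-course generator
#'
#' Bundles every parameter of the synthetic-data module. The defaults describe
#' the study conditions the generator is meant to emulate: a mostly stable
#' transcriptome in which a small cohort of direct targets is repressed within
#' 2-6 h of depletion, larger indirect cohorts respond later, repressed genes
#' carry coupled enhancer accessibility loss (a configurable fraction of which
#' also loses EP300), and a genome-wide background of chromatin changes exists
#' that is not linked to any responsive gene. Nucleosome midpoints around
#' motifs are drawn from a central "barrier" component flanked by phased
#' nucleosomes at `flank_distance_d0 + k * nucleosome_repeat`.
#'
#' @param seed Integer seed; every stochastic draw of the generator flows from
#'   it (stage-specific offsets are derived internally, no global state is
#'   left behind).
#' @param chrom,chrom_length Chromosome name and length in bp. A single
#'   chromosome is simulated; multi-chromosome data can be built by repeated
#'   blocks with different `chrom`.
#' @param n_genes Number of genes.
#' @param tss_spacing Minimum spacing between adjacent TSSs in bp. The default
#'   (105 kb) keeps 50-kb enhancer windows of neighbouring genes disjoint so
#'   planted linkage rates are exactly recoverable.
#' @param histone_gene_fraction Fraction of genes flagged as histone genes
#'   (excluded from window linkage downstream).
#' @param trajectory_class_proportions Named proportions over
#'   `early_down`, `early_up`, `late_down`, `late_up`, `stable`; must sum to 1.
#' @param effect_size_log2fc Named per-class asymptotic log2 fold change.
#' @param noise_sd Gaussian noise sd added to every log2 fold change.
#' @param fdr_when_changed,fdr_when_stable FDR scale generated for time points
#'   after/before the onset of change (jittered multiplicatively). FDRs are
#'   generated directly because the pipeline consumes FDR columns from
#'   upstream differential callers; no p-value machinery is emulated.
#' @param linked_site_rate Probability that a changed gene carries one coupled
#'   chromatin site inside its enhancer window.
#' @param dual_loss_fraction Fraction of coupled accessibility-loss sites that
#'   also lose EP300 occupancy (same interval, second assay).
#' @param co_gain_fraction Fraction of coupled EP300-gain sites (upregulated
#'   genes, promoter-proximal) that also gain H3K27ac.
#' @param site_effect_log2fc Magnitude of the site-level log2 fold change once
#'   a site has changed.
#' @param site_width Width of simulated peaks in bp.
#' @param background_site_rate Background sites per Mb, placed uniformly
#'   genome-wide and not coupled to any gene.
#' @param background_category_weights Named weights over background site
#'   categories (`stable`, `accessibility_lost`, `EP300_lost`, `dual_lost`,
#'   `accessibility_gained`, `EP300_gained`, `H3K27ac_gained`); normalised
#'   internally. With the default total rate the implied per-gene-window
#'   background change probabilities are roughly 0.30 (accessibility-only
#'   loss), 0.22 (EP300-only loss) and 0.12 (dual loss), i.e. the 30-40%
#'   background of unlinked accessibility changes seen adjacent to
#'   non-responsive genes.
#' @param nuc_sites Number of motif sites for the nucleosome module.
#' @param nuc_reads_per_site Mean Poisson read depth per motif site.
#' @param central_weight Mixture weight of the central (barrier) component;
#'   the remainder is split equally over six flanking components
#'   (two sides, k = 0, 1, 2).
#' @param central_sd,flank_sd Gaussian sd (bp) of central and flanking dyad
#'   components.
#' @param flank_distance_d0 Distance (bp) from the motif centre to the first
#'   flanking nucleosome.
#' @param nucleosome_repeat Nucleosome repeat length (bp) between successive
#'   flanking nucleosomes.
#' @param state_labels,state_weights Chromatin-state alphabet and sampling
#'   weights for the segmentation module.
#' @param mean_segment_length Mean dwell length (bp) of segmentation states.
#'
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, n_genes = 50, chrom_length = 1e7, tss_spacing = 1e5)
#' genes <- simulate_genes(cfg)
sim_config <- function(seed = 1L,
                       chrom = "chrS",
                       chrom_length = 2.2e8,
                       n_genes = 2000,
                       tss_spacing = 105000,
                       histone_gene_fraction = 0.02,
                       trajectory_class_proportions = c(
                         early_down = 0.05, early_up = 0.20,
                         late_down = 0.01, late_up = 0.09, stable = 0.65),
                       effect_size_log2fc = c(
                         early_down = -2.0, early_up = 1.5,
                         late_down = -1.5, late_up = 1.5, stable = 0),
                       noise_sd = 0.2,
                       fdr_when_changed = 1e-8,
                       fdr_when_stable = 0.5,
                       linked_site_rate = 0.8,
                       dual_loss_fraction = 0.5,
                       co_gain_fraction = 0.5,
                       site_effect_log2fc = 1.5,
                       site_width = 400,
                       background_site_rate = 15.6,
                       background_category_weights = c(
                         stable = 4.0, accessibility_lost = 3.6,
                         EP300_lost = 2.5, dual_lost = 1.3,
                         accessibility_gained = 1.0, EP300_gained = 1.6,
                         H3K27ac_gained = 1.6),
                       nuc_sites = 200,
                       nuc_reads_per_site = 50,
                       central_weight = 0.25,
                       central_sd = 35,
                       flank_distance_d0 = 180,
                       flank_sd = 35,
                       nucleosome_repeat = 185,
                       state_labels = c("ActivePromoter", "BivalentPromoter",
                                        "StrongEnhancer", "WeakEnhancer",
                                        "Transcribed", "Polycomb",
                                        "Heterochromatin", "Intergenic"),
                       state_weights = c(0.02, 0.01, 0.03, 0.05,
                                         0.20, 0.03, 0.16, 0.50),
                       mean_segment_length = 20000) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  p <- cfg$trajectory_class_proportions
  if (!setequal(names(p), TRAJECTORY_CLASSES)) {
    abort(sprintf("trajectory_class_proportions must be named exactly {%s}",
                  paste(TRAJECTORY_CLASSES, collapse = ", ")))
  }
  if (abs(sum(p) - 1) > 1e-9) {
    abort("trajectory_class_proportions must sum to 1 (within 1e-9)")
  }
  if (any(p < 0 | p > 1)) abort("trajectory_class_proportions must lie in [0, 1]")
  if (!all(TRAJECTORY_CLASSES %in% names(cfg$effect_size_log2fc))) {
    abort("effect_size_log2fc must name every trajectory class")
  }
  for (fld in c("n_genes", "nuc_sites")) {
    if (!is_count(cfg[[fld]])) abort(sprintf("`%s` must be a non-negative count", fld))
  }
  for (fld in c("chrom_length", "tss_spacing", "site_width", "central_sd",
                "flank_distance_d0", "flank_sd", "nucleosome_repeat",
                "mean_segment_length")) {
    if (!(is.numeric(cfg[[fld]]) && length(cfg[[fld]]) == 1 && cfg[[fld]] > 0)) {
      abort(sprintf("`%s` must be a single positive number of bp", fld))
    }
  }
  for (fld in c("histone_gene_fraction", "linked_site_rate",
                "dual_loss_fraction", "co_gain_fraction", "central_weight",
                "fdr_when_changed", "fdr_when_stable")) {
    if (!is_prop(cfg[[fld]])) abort(sprintf("`%s` must be a proportion in [0, 1]", fld))
  }
  if (cfg$background_site_rate < 0) abort("`background_site_rate` must be >= 0")
  if (cfg$noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (cfg$nuc_reads_per_site < 0) abort("`nuc_reads_per_site` must be >= 0")
  if (length(cfg$state_labels) != length(cfg$state_weights) ||
      length(cfg$state_labels) < 1 || any(cfg$state_weights < 0)) {
    abort("state_labels/state_weights must be equal-length with non-negative weights")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d | %s:%g bp | %d genes | %d nuc sites\n",
              x$seed, x$chrom, x$chrom_length, x$n_genes, x$nuc_sites))
  cat("  class proportions:",
      paste(sprintf("%s=%.2f", names(x$trajectory_class_proportions),
                    x$trajectory_class_proportions), collapse = " "), "\n")
  invisible(x)
}

# All generator randomness flows from cfg$seed; each stage uses a fixed
# offset so stages are independently reproducible, and withr restores the
# caller's RNG state.
with_stage_seed <- function(cfg, stage, code) {
  offsets <- c(genes = 0L, expression = 1L, sites = 2L, fragments = 3L,
               segmentation = 4L)
  withr::with_seed(as.integer(cfg$seed) + offsets[[stage]], code)
}
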