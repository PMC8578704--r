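#' Simulate gene models with planted trajectory classes
#'
#' Places `n_genes` TSSs along the chromosome with a guaranteed minimum
#' spacing (regular grid plus bounded uniform jitter), assigns strands,
#' histone-gene flags, a trajectory class per
#' `trajectory_class_proportions`, and a planted onset time: early classes
#' change at 2 or 6 h with equal probability, late classes at 18, 54 or
#' 162 h uniformly, stable genes never.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `gene_id`, `chrom`, `tss`, `strand`,
#'   `is_histone`, `planted_class`, `planted_onset_h` (`Inf` for stable).
#' @export
simulate_genes <- function(config) {
  validate_sim_config(config)
  n <- config$n_genes
  empty <- tibble(gene_id = character(), chrom = character(), tss = integer(),
                  strand = character(), is_histone = logical(),
                  planted_class = character(), planted_onset_h = double())
  if (n == 0) return(empty)
  gap <- config$chrom_length / n
  if (gap < config$tss_spacing) {
    abort(sprintf(
      "cannot place %d TSSs with %g bp minimum spacing on a %g bp chromosome",
      n, config$tss_spacing, config$chrom_length))
  }
  with_stage_seed(config, "genes", {
    jitter <- (gap - config$tss_spacing) / 2
    tss <- as.integer(floor((seq_len(n) - 0.5) * gap +
                              runif(n, -jitter, jitter)))
    cls <- sample(TRAJECTORY_CLASSES, n, replace = TRUE,
                  prob = config$trajectory_class_proportions[TRAJECTORY_CLASSES])
    onset <- rep(Inf, n)
    early <- cls %in% c("early_down", "early_up")
    late <- cls %in% c("late_down", "late_up")
    onset[early] <- sample(c(2, 6), sum(early), replace = TRUE)
    onset[late] <- sample(c(18, 54, 162), sum(late), replace = TRUE)
    tibble(
      gene_id = sprintf("g%05d", seq_len(n)),
      chrom = config$chrom,
      tss = tss,
      strand = sample(c("+", "-"), n, replace = TRUE),
      is_histone = runif(n) < config$histone_gene_fraction,
      planted_class = cls,
      planted_onset_h = onset)
  })
}

# Shared log2FC/FDR emission model: zero before onset, class/site effect plus
# Gaussian noise afterwards; FDR drawn around fdr_when_changed after onset and
# around fdr_when_stable (clamped to <= 1) otherwise.
emit_timecourse <- function(n_units, onset, effect, config) {
  times <- rep(TIMEPOINTS_H, times = n_units)
  onset_l <- rep(onset, each = length(TIMEPOINTS_H))
  effect_l <- rep(effect, each = length(TIMEPOINTS_H))
  changed <- times >= onset_l
  m <- length(times)
  log2fc <- ifelse(changed, effect_l, 0) + rnorm(m, sd = config$noise_sd)
  fdr <- ifelse(changed,
                config$fdr_when_changed * runif(m, 0.1, 1),
                pmin(1, config$fdr_when_stable * runif(m, 0.2, 2)))
  tibble(time = times, log2fc = log2fc, fdr = fdr)
}

#' Simulate per-gene expression time courses
#'
#' Emits a long table of log2 fold changes and FDRs versus time 0 for each
#' gene at 2, 6, 18, 54 and 162 h. Changed genes step to their class effect
#' size at the planted onset; FDR drops below the 0.05 expression cutoff from
#' the onset onwards and stays well above it before.
#'
#' @param genes Output of [simulate_genes()].
#' @param config The same [sim_config()].
#' @return A tibble with columns `gene_id`, `time`, `log2fc`, `fdr`.
#' @export
simulate_expression_timecourse <- function(genes, config) {
  validate_sim_config(config)
  assert_cols(genes, c("gene_id", "planted_class", "planted_onset_h"), "genes")
  if (nrow(genes) == 0) abort("`genes` must be non-empty")
  unknown <- setdiff(unique(genes$planted_class), TRAJECTORY_CLASSES)
  if (length(unknown) > 0) {
    abort(sprintf("unknown trajectory class label(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  with_stage_seed(config, "expression", {
    tc <- emit_timecourse(nrow(genes), genes$planted_onset_h,
                          config$effect_size_log2fc[genes$planted_class],
                          config)
    dplyr::bind_cols(
      tibble(gene_id = rep(genes$gene_id, each = length(TIMEPOINTS_H))), tc)
  })
}

# Draws a coupled-site start position uniformly inside the enhancer window
# (within +/- enh of the TSS, outside +/- prom), clipped to the chromosome.
draw_enhancer_start <- function(tss, width, prom = 500, enh = 50000) {
  side <- sample(c(-1L, 1L), length(tss), replace = TRUE)
  lo <- ifelse(side < 0, tss - enh, tss + prom)
  hi <- ifelse(side < 0, tss - prom - width, tss + enh - width)
  floor(lo + runif(length(tss)) * (hi - lo))
}

#' Simulate site-level chromatin time courses with planted gene coupling
#'
#' Two site populations are generated. Coupled sites: a `linked_site_rate`
#' fraction of changed genes receives one site inside its enhancer window
#' (within 50 kb of the TSS, outside +/- 500 bp). For downregulated genes the
#' site loses accessibility at the gene's onset time and, with probability
#' `dual_loss_fraction`, the same interval also loses EP300. For upregulated
#' genes a promoter-proximal site gains EP300 and, with probability
#' `co_gain_fraction`, also gains H3K27ac. Background sites: placed uniformly
#' genome-wide at `background_site_rate` per Mb with per-category weights;
#' changed background categories draw their onset uniformly over the time
#' grid, the `stable` category never changes. Every site records its planted
#' truth (`is_coupled`, `planted_category`, `planted_direction`,
#' `planted_time`, `planted_gene`, `planted_dual`).
#'
#' @param genes Output of [simulate_genes()].
#' @param config The same [sim_config()].
#' @return A long tibble with one row per site, assay and time point:
#'   `site_id`, `chrom`, `start`, `end`, `assay`, `time`, `log2fc`, `fdr`
#'   plus the planted truth columns.
#' @export
simulate_site_timecourses <- function(genes, config) {
  validate_sim_config(config)
  assert_cols(genes, c("gene_id", "chrom", "tss", "planted_class",
                       "planted_onset_h"), "genes")
  w <- config$site_width
  with_stage_seed(config, "sites", {
    sites <- list()

    changed <- genes[genes$planted_class != "stable", , drop = FALSE]
    coupled <- changed[runif(nrow(changed)) < config$linked_site_rate, ,
                       drop = FALSE]
    down <- coupled[coupled$planted_class %in% c("early_down", "late_down"), ,
                    drop = FALSE]
    up <- coupled[coupled$planted_class %in% c("early_up", "late_up"), ,
                  drop = FALSE]

    if (nrow(down) > 0) {
      start <- draw_enhancer_start(down$tss, w)
      dual <- runif(nrow(down)) < config$dual_loss_fraction
      acc <- tibble(chrom = down$chrom, start = start, end = start + w,
                    assay = "accessibility", is_coupled = TRUE,
                    planted_category = ifelse(dual, "coupled_dual_lost",
                                              "coupled_accessibility_lost"),
                    planted_direction = "lost",
                    planted_time = down$planted_onset_h,
                    planted_gene = down$gene_id, planted_dual = dual)
      sites$acc_lost <- acc
      sites$ep_lost <- dplyr::mutate(acc[dual, , drop = FALSE], assay = "EP300")
    }
    if (nrow(up) > 0) {
      start <- floor(up$tss - 2000 + runif(nrow(up)) * (4000 - w))
      co <- runif(nrow(up)) < config$co_gain_fraction
      ep <- tibble(chrom = up$chrom, start = start, end = start + w,
                   assay = "EP300", is_coupled = TRUE,
                   planted_category = ifelse(co, "coupled_EP300_H3K27ac_gained",
                                             "coupled_EP300_gained"),
                   planted_direction = "gained",
                   planted_time = up$planted_onset_h,
                   planted_gene = up$gene_id, planted_dual = FALSE)
      sites$ep_gain <- ep
      sites$ac_gain <- dplyr::mutate(ep[co, , drop = FALSE], assay = "H3K27ac")
    }

    n_bg <- rpois(1, config$background_site_rate * config$chrom_length / 1e6)
    if (n_bg > 0) {
      wts <- config$background_category_weights
      cat <- sample(names(wts), n_bg, replace = TRUE, prob = wts / sum(wts))
      start <- floor(runif(n_bg, 0, config$chrom_length - w))
      onset <- sample(TIMEPOINTS_H, n_bg, replace = TRUE)
      bg <- tibble(chrom = config$chrom, start = start, end = start + w,
                   is_coupled = FALSE, planted_category = cat,
                   planted_gene = NA_character_,
                   planted_dual = cat == "dual_lost",
                   planted_direction = dplyr::case_when(
                     grepl("_lost$", cat) ~ "lost",
                     grepl("_gained$", cat) ~ "gained",
                     TRUE ~ "none"),
                   planted_time = ifelse(cat == "stable", Inf, onset))
      bg$assay <- dplyr::case_when(
        bg$planted_category == "stable" ~
          sample(c("accessibility", "EP300", "H3K27ac"), n_bg, replace = TRUE),
        bg$planted_category %in% c("accessibility_lost", "dual_lost",
                                   "accessibility_gained") ~ "accessibility",
        bg$planted_category %in% c("EP300_lost", "EP300_gained") ~ "EP300",
        TRUE ~ "H3K27ac")
      sites$bg <- bg
      dual_bg <- bg[bg$planted_category == "dual_lost", , drop = FALSE]
      sites$bg_dual_ep <- dplyr::mutate(dual_bg, assay = "EP300")
    }

    site_tbl <- bind_rows(sites)
    if (nrow(site_tbl) == 0) {
      return(tibble(site_id = character(), chrom = character(),
                    start = integer(), end = integer(), assay = character(),
                    time = double(), log2fc = double(), fdr = double(),
                    is_coupled = logical(), planted_category = character(),
                    planted_direction = character(), planted_time = double(),
                    planted_gene = character(), planted_dual = logical()))
    }
    site_tbl$site_id <- sprintf("s%06d", seq_len(nrow(site_tbl)))
    effect <- ifelse(site_tbl$planted_direction == "lost",
                     -config$site_effect_log2fc,
                     ifelse(site_tbl$planted_direction == "gained",
                            config$site_effect_log2fc, 0))
    tc <- emit_timecourse(nrow(site_tbl), site_tbl$planted_time, effect, config)
    out <- dplyr::bind_cols(
      site_tbl[rep(seq_len(nrow(site_tbl)), each = length(TIMEPOINTS_H)), ], tc)
    select(out, "site_id", "chrom", "start", "end", "assay", "time",
           "log2fc", "fdr", dplyr::everything())
  })
}

#' Simulate a chromatin-state segmentation
#'
#' Tiles the chromosome with contiguous, non-overlapping labelled segments.
#' States are sampled by `state_weights`, dwell lengths are exponential with
#' mean `mean_segment_length` (floored at 200 bp), and adjacent segments with
#' the same state are merged, so a one-state alphabet yields a single
#' chromosome-spanning interval.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `chrom`, `start`, `end`, `state` covering
#'   `[0, chrom_length)` without gaps or overlap.
#' @export
simulate_state_segmentation <- function(config) {
  validate_sim_config(config)
  with_stage_seed(config, "segmentation", {
    L <- config$chrom_length
    n_draw <- ceiling(L / config$mean_segment_length * 1.5) + 20
    repeat {
      len <- pmax(200, round(rexp(n_draw, 1 / config$mean_segment_length)))
      if (sum(len) >= L) break
      n_draw <- n_draw * 2
    }
    keep <- which(cumsum(len) >= L)[1]
    len <- len[seq_len(keep)]
    st <- sample(config$state_labels, keep, replace = TRUE,
                 prob = config$state_weights)
    ends <- pmin(cumsum(len), L)
    starts <- c(0, ends[-keep])
    seg <- tibble(chrom = config$chrom, start = starts, end = ends, state = st)
    # merge runs of identical state
    run <- cumsum(c(TRUE, st[-1] != st[-keep]))
    seg |>
      group_by(run = run) |>
      summarise(chrom = .data$chrom[1], start = min(.data$start),
                end = max(.data$end), state = .data$state[1],
                .groups = "drop") |>
      select("chrom", "start", "end", "state") |>
      arrange(.data$start)
  })
}

#' Simulate nucleosome fragment midpoints around motif sites
#'
#' For each of `nuc_sites` motif positions, a Poisson number of fragment
#' midpoints is drawn from a mixture: a central component `N(0, central_sd^2)`
#' with weight `central_weight`, and six flanking components at
#' `+/-(flank_distance_d0 + k * nucleosome_repeat)`, `k = 0..2`, sd
#' `flank_sd`, sharing the remaining weight equally. Fragments are emitted as
#' 147-bp intervals whose floor midpoint equals the drawn dyad position;
#' offsets are mirrored for minus-strand motifs so the planted offset is
#' strand-relative.
#'
#' @param config A [sim_config()].
#' @return A list with `fragments` (tibble `chrom`, `start`, `end`,
#'   `motif_id`, `planted_offset`) and `motifs` (BED6-style tibble `chrom`,
#'   `start`, `end`, `motif_id`, `score`, `strand`; interval midpoint is the
#'   motif centre).
#' @export
simulate_nucleosome_fragments <- function(config) {
  validate_sim_config(config)
  with_stage_seed(config, "fragments", {
    ns <- config$nuc_sites
    centers <- floor(runif(ns, 2000, config$chrom_length - 2000))
    strand <- sample(c("+", "-"), ns, replace = TRUE)
    motifs <- tibble(chrom = config$chrom, start = centers - 7L,
                     end = centers + 8L,
                     motif_id = sprintf("m%04d", seq_len(ns)),
                     score = 0L, strand = strand)
    depth <- rpois(ns, config$nuc_reads_per_site)
    total <- sum(depth)
    if (total == 0) {
      return(list(fragments = tibble(chrom = character(), start = integer(),
                                     end = integer(), motif_id = character(),
                                     planted_offset = integer()),
                  motifs = motifs))
    }
    site_of <- rep(seq_len(ns), times = depth)
    is_central <- runif(total) < config$central_weight
    side <- sample(c(-1, 1), total, replace = TRUE)
    k <- sample(0:2, total, replace = TRUE)
    mu <- ifelse(is_central, 0,
                 side * (config$flank_distance_d0 + k * config$nucleosome_repeat))
    sd <- ifelse(is_central, config$central_sd, config$flank_sd)
    offset <- round(rnorm(total, mean = mu, sd = sd))
    dir <- ifelse(strand[site_of] == "-", -1L, 1L)
    mid <- centers[site_of] + dir * offset
    list(
      fragments = tibble(chrom = config$chrom,
                         start = as.integer(mid - 73L),
                         end = as.integer(mid + 74L),
                         motif_id = motifs$motif_id[site_of],
                         planted_offset = as.integer(offset)),
      motifs = motifs)
  })
}
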