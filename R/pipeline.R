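#' Configuration for an end-to-end run
#'
#' Bundles the stage configurations of the full pipeline:
#' simulate (or load) -> classify -> link -> enrich -> nucleosome profile.
#' Every load-bearing constant (fold-change and FDR thresholds per assay,
#' window half-widths, control-set size, smoothing window, time grid) is
#' named here and overridable; the run manifest records the values actually
#' applied.
#'
#' @param sim A [sim_config()] (used when `simulate = TRUE`).
#' @param thresholds Named list of [threshold_config()]s per assay.
#' @param windows A [window_config()].
#' @param scheme Cohort scheme for [assign_cohorts()].
#' @param control_k Control-set size for [select_control_genes()].
#' @param smooth_window Moving-average weight (bp) for profiles.
#' @param simulate Generate inputs with the synthetic module; when `FALSE`,
#'   `inputs` must name existing files.
#' @param inputs Named paths (`expression`, `sites`, `segmentation`,
#'   `fragments`, `motifs`, `genes`) used when `simulate = FALSE`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       thresholds = list(
                         accessibility = threshold_config("accessibility"),
                         EP300 = threshold_config("EP300"),
                         H3K27ac = threshold_config("H3K27ac")),
                       windows = window_config(),
                       scheme = "early_late",
                       control_k = 500,
                       smooth_window = 30,
                       simulate = TRUE,
                       inputs = NULL) {
  validate_sim_config(sim)
  stopifnot(inherits(windows, "window_config"))
  purrr::walk(thresholds, function(t) stopifnot(inherits(t, "threshold_config")))
  structure(list(sim = sim, thresholds = thresholds, windows = windows,
                 scheme = scheme, control_k = control_k,
                 smooth_window = smooth_window, simulate = isTRUE(simulate),
                 inputs = inputs),
            class = "run_config")
}

run_stage <- function(stage, code) {
  tryCatch(code, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full integration pipeline
#'
#' Executes every stage against one configuration and writes all outputs
#' plus a manifest (file, md5 checksum, bytes) to `outdir`. Runs are fully
#' deterministic: two invocations with an identical configuration produce
#' checksum-identical outputs.
#'
#' Stages: (1) simulate or load gene/expression/site/segmentation/fragment
#' tables; (2) classify per-assay first changes; (3) intersect lost
#' accessibility and lost EP300 sites into dual/single categories and link
#' all classified change sites to gene windows; (4) select control genes,
#' assign cohorts and score per-quintile percent-with-change and
#' hypergeometric enrichment for the dual and single loss keys; (5) annotate
#' lost-accessibility sites with chromatin states; (6) aggregate, normalise
#' and smooth the nucleosome midpoint profile and extract barrier metrics.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   `manifest` tibble.
#' @export
run_all <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  if (!config$simulate) {
    req <- c("genes", "expression", "sites", "segmentation", "fragments",
             "motifs")
    paths <- unlist(config$inputs[req])
    missing <- req[!vapply(req, function(k) {
      !is.null(config$inputs[[k]]) && file.exists(config$inputs[[k]])
    }, TRUE)]
    if (length(missing) > 0) {
      abort(sprintf("simulation disabled but required input(s) missing: %s",
                    paste(missing, collapse = ", ")))
    }
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  dat <- run_stage("simulate", {
    if (config$simulate) {
      genes <- simulate_genes(config$sim)
      nuc <- simulate_nucleosome_fragments(config$sim)
      list(genes = genes,
           expression = simulate_expression_timecourse(genes, config$sim),
           sites = simulate_site_timecourses(genes, config$sim),
           segmentation = simulate_state_segmentation(config$sim),
           fragments = nuc$fragments, motifs = nuc$motifs)
    } else {
      genes <- read_bed(config$inputs$genes,
                        col_names = c("chrom", "start", "end", "gene_id",
                                      "score", "strand", "is_histone"))
      genes$tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
      genes$is_histone <- as.logical(genes$is_histone)
      list(genes = genes,
           expression = read_timecourse_tsv(config$inputs$expression),
           sites = read_timecourse_tsv(config$inputs$sites),
           segmentation = read_bed(config$inputs$segmentation,
                                   col_names = c("chrom", "start", "end",
                                                 "state")),
           fragments = read_bed(config$inputs$fragments),
           motifs = read_bed(config$inputs$motifs,
                             col_names = c("chrom", "start", "end", "name",
                                           "score", "strand")))
    }
  })

  classified <- run_stage("classify", {
    purrr::imap(split(dat$sites, dat$sites$assay), function(tc, assay) {
      thr <- config$thresholds[[assay]] %||% threshold_config("accessibility")
      order_sites(classify_changes(tc, thr))
    })
  })

  linkres <- run_stage("link", {
    lost_acc <- filter(classified$accessibility, .data$direction == "lost")
    lost_ep <- if (!is.null(classified$EP300)) {
      filter(classified$EP300, .data$direction == "lost")
    } else lost_acc[0, ]
    isect <- intersect_change_sets(lost_acc, lost_ep)
    categorised <- bind_rows(
      mutate(isect$both, change_category = "dual_lost"),
      mutate(isect$a_only, change_category = "accessibility_only_lost"),
      mutate(isect$b_only, change_category = "EP300_only_lost"))
    linkage <- link_changes_to_genes(
      dat$genes, filter(bind_rows(classified), .data$direction != "none"),
      config$windows)
    list(categories = categorised,
         linkage = linkage,
         category_linkage = link_changes_to_genes(dat$genes, categorised,
                                                  config$windows))
  })

  enrich <- run_stage("enrich", {
    cohorts <- assign_cohorts(dat$expression, config$scheme)
    control <- select_control_genes(dat$expression, k = config$control_k)
    control_tbl <- tibble(gene_id = control$gene_id, scheme = config$scheme,
                          cohort = "control", quintile = NA_integer_)
    groups <- bind_rows(select(cohorts, "gene_id", "scheme", "cohort",
                               "quintile"),
                        control_tbl)
    universe <- if (config$windows$exclude_histone_genes) {
      dat$genes$gene_id[!dat$genes$is_histone]
    } else dat$genes$gene_id
    groups <- filter(groups, .data$gene_id %in% universe)
    keys <- unique(linkres$categories$change_category)
    enrichment <- purrr::map_dfr(keys, function(k) {
      cohort_enrichment(groups,
                        filter(linkres$category_linkage,
                               .data$change_category == k),
                        universe, linkage_types = "enhancer") |>
        mutate(change_key = k)
    })
    pct <- percent_with_change(groups,
                               filter(linkres$category_linkage,
                                      .data$change_category == "dual_lost"),
                               linkage_types = "enhancer",
                               stratify_by_time = TRUE)
    list(cohorts = cohorts, control = control, enrichment = enrichment,
         percent_dual = pct)
  })

  states <- run_stage("annotate_states", {
    lost_acc <- filter(classified$accessibility, .data$direction == "lost")
    if (nrow(lost_acc) == 0) NULL
    else annotate_states(lost_acc, dat$segmentation)
  })

  nuc <- run_stage("nucprofile", {
    prof <- aggregate_midpoint_profile(dat$fragments, dat$motifs) |>
      normalize_enrichment() |>
      smooth_profile(config$smooth_window)
    list(profile = prof, metrics = barrier_metrics(prof))
  })

  manifest <- run_stage("write", {
    out <- function(name) file.path(outdir, name)
    write_bed(mutate(dat$genes, start = .data$tss, end = .data$tss + 1L,
                     name = .data$gene_id, score = 0L),
              out("genes.bed"),
              columns = c("chrom", "start", "end", "name", "score", "strand"))
    readr::write_tsv(select(dat$genes, "gene_id", "is_histone",
                            dplyr::any_of(c("planted_class"))),
                     out("gene_attributes.tsv"))
    write_timecourse_tsv(dat$expression, out("expression_timecourse.tsv"))
    write_timecourse_tsv(dat$sites, out("site_timecourse.tsv"))
    purrr::iwalk(classified, function(cls, assay) {
      write_classification_bed(cls, out(sprintf("classified_%s.bed", assay)))
    })
    write_bed(dat$segmentation, out("segmentation.bed"),
              columns = c("chrom", "start", "end", "state"))
    write_bed(dat$fragments, out("fragments.bed"),
              columns = c("chrom", "start", "end"))
    readr::write_tsv(linkres$category_linkage, out("linkage.tsv"))
    readr::write_tsv(enrich$enrichment, out("enrichment.tsv"))
    readr::write_tsv(enrich$percent_dual, out("percent_with_change.tsv"))
    if (!is.null(states)) readr::write_tsv(states, out("state_fractions.tsv"))
    readr::write_tsv(as_tibble(nuc$profile), out("nucleosome_profile.tsv"))
    readr::write_tsv(glance(nuc$metrics), out("barrier_metrics.tsv"))
    yaml::write_yaml(serialize_config(config), out("config.yaml"))
    files <- sort(list.files(outdir, full.names = TRUE))
    tibble(file = basename(files),
           md5 = unname(tools::md5sum(files)),
           bytes = file.size(files))
  })
  readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  invisible(list(data = dat, classified = classified, linkage = linkres,
                 enrichment = enrich, states = states, nucleosome = nuc,
                 manifest = manifest))
}

# Plain-list view of a run_config for the YAML audit record.
serialize_config <- function(config) {
  list(sim = unclass(config$sim)[!vapply(unclass(config$sim), is.function, TRUE)],
       thresholds = lapply(config$thresholds, unclass),
       windows = unclass(config$windows),
       scheme = config$scheme, control_k = config$control_k,
       smooth_window = config$smooth_window, simulate = config$simulate)
}
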