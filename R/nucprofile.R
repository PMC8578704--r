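new_nuc_profile <- function(offset, count, enrichment = NULL, n_sites,
                            total_reads, smoothed = FALSE) {
  out <- tibble(offset = offset, count = count)
  if (!is.null(enrichment)) out$enrichment <- enrichment
  structure(out, class = c("nuc_profile", class(tibble())),
            n_sites = n_sites, total_reads = total_reads, smoothed = smoothed)
}

profile_meta <- function(p) {
  list(n_sites = attr(p, "n_sites"), total_reads = attr(p, "total_reads"),
       smoothed = attr(p, "smoothed"))
}

#' Aggregate fragment midpoints around motif centres
#'
#' Sums the midpoints of nucleosomal fragments for each base pair of a
#' window centred on each motif. The fragment midpoint is
#' `floor((start + end) / 2)` (even-length fragments round down); the motif
#' centre is the interval midpoint. Offsets of fragments around minus-strand
#' motifs are mirrored. When a `bound_sites` interval set is supplied (e.g.
#' factor ChIP peaks), only motifs overlapping it by >= 1 bp are used.
#'
#' @param fragments Fragment intervals (`chrom`, `start`, `end`).
#' @param motifs Motif intervals (`chrom`, `start`, `end`, optional
#'   `strand`).
#' @param halfwidth Window half-width in bp (default 1000, i.e. a 2-kb
#'   window and 2001 offsets).
#' @param bound_sites Optional interval tibble restricting motifs to
#'   factor-bound ones.
#' @param total_reads Experiment-wide read count used later for
#'   normalisation; defaults to `nrow(fragments)` (every supplied fragment),
#'   not the in-window count.
#' @return A `nuc_profile`: a tibble `offset`, `count` of length
#'   `2 * halfwidth + 1` with attributes `n_sites`, `total_reads`,
#'   `smoothed`.
#' @export
aggregate_midpoint_profile <- function(fragments, motifs, halfwidth = 1000,
                                       bound_sites = NULL,
                                       total_reads = nrow(fragments)) {
  assert_intervals(fragments, "fragments")
  assert_intervals(motifs, "motifs")
  if (!is.null(bound_sites)) {
    assert_intervals(bound_sites, "bound_sites")
    keep <- rep(FALSE, nrow(motifs))
    for (ch in intersect(unique(motifs$chrom), unique(bound_sites$chrom))) {
      im <- which(motifs$chrom == ch)
      bs <- bound_sites[bound_sites$chrom == ch, , drop = FALSE]
      keep[im] <- IRanges::overlapsAny(
        as_iranges(motifs$start[im], motifs$end[im]),
        as_iranges(bs$start, bs$end))
    }
    motifs <- motifs[keep, , drop = FALSE]
  }
  if (nrow(motifs) == 0) abort("no motif sites to aggregate over")
  if (total_reads < nrow(fragments)) {
    abort("`total_reads` cannot be smaller than the supplied fragment count")
  }
  strand <- if ("strand" %in% names(motifs)) motifs$strand else rep("+", nrow(motifs))
  center <- floor((motifs$start + motifs$end) / 2)
  mid <- floor((fragments$start + fragments$end) / 2)
  counts <- integer(2 * halfwidth + 1)
  for (ch in unique(motifs$chrom)) {
    im <- which(motifs$chrom == ch)
    ifr <- which(fragments$chrom == ch)
    if (length(ifr) == 0) next
    win <- IRanges::IRanges(start = center[im] - halfwidth + 1L,
                            end = center[im] + halfwidth + 1L)
    pts <- IRanges::IRanges(start = mid[ifr] + 1L, width = 1L)
    hit <- IRanges::findOverlaps(pts, win)
    if (length(hit) == 0) next
    q <- ifr[S4Vectors::queryHits(hit)]
    s <- im[S4Vectors::subjectHits(hit)]
    off <- mid[q] - center[s]
    off <- ifelse(strand[s] == "-", -off, off)
    off <- off[abs(off) <= halfwidth]
    counts <- counts + tabulate(off + halfwidth + 1L, nbins = 2 * halfwidth + 1)
  }
  new_nuc_profile(offset = seq(-halfwidth, halfwidth), count = counts,
                  n_sites = nrow(motifs), total_reads = total_reads)
}

#' Normalise a midpoint profile to per-site, per-read enrichment
#'
#' `enrichment[i] = count[i] / (n_sites * total_reads)`, where `total_reads`
#' is the experiment-wide read count, not the in-window count. Doubling the
#' whole experiment (every site with its fragments, genome-wide reads
#' included) therefore leaves the enrichment unchanged.
#'
#' @param profile A `nuc_profile`.
#' @return The profile with an `enrichment` column added.
#' @export
normalize_enrichment <- function(profile) {
  stopifnot(inherits(profile, "nuc_profile"))
  m <- profile_meta(profile)
  if (m$n_sites <= 0 || m$total_reads <= 0) {
    abort("normalisation requires n_sites > 0 and total_reads > 0")
  }
  new_nuc_profile(profile$offset, profile$count,
                  enrichment = profile$count / (m$n_sites * m$total_reads),
                  n_sites = m$n_sites, total_reads = m$total_reads,
                  smoothed = m$smoothed)
}

# Symmetric centred moving average of total weight `window`. For even
# `window` the kernel has length `window + 1` with half weights at both ends
# (the classic centred even-order moving average), so smoothing commutes with
# mirroring the offset axis. At the edges the kernel is renormalised over the
# available positions.
moving_average <- function(x, window) {
  n <- length(x)
  if (window < 1 || window > n) abort("`window` must be in [1, length(profile)]")
  if (window %% 2 == 1) {
    h <- (window - 1) / 2
    wts <- rep(1, window)
  } else {
    h <- window / 2
    wts <- c(0.5, rep(1, window - 1), 0.5)
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    w <- wts[(lo - i + h + 1):(hi - i + h + 1)]
    out[i] <- sum(x[lo:hi] * w) / sum(w)
  }
  out
}

#' Smooth a profile with a centred moving average
#'
#' Applies a symmetric centred moving average of total weight `window`
#' (default 30 bp) to the count and, if present, enrichment columns. For an
#' even window the kernel spans `window + 1` offsets with half weights at its
#' ends, keeping the kernel symmetric; at the window edges the kernel
#' shrinks to the available offsets.
#'
#' @param profile A `nuc_profile`.
#' @param window Moving-average weight in bp.
#' @return The smoothed profile (`smoothed` attribute set).
#' @export
smooth_profile <- function(profile, window = 30) {
  stopifnot(inherits(profile, "nuc_profile"))
  m <- profile_meta(profile)
  enr <- if ("enrichment" %in% names(profile)) {
    moving_average(profile$enrichment, window)
  }
  new_nuc_profile(profile$offset, moving_average(profile$count, window),
                  enrichment = enr, n_sites = m$n_sites,
                  total_reads = m$total_reads, smoothed = TRUE)
}

profile_signal <- function(profile) {
  if ("enrichment" %in% names(profile)) profile$enrichment else profile$count
}

#' Barrier-nucleosome metrics d and w
#'
#' Operational definitions of the two Fig-style barrier metrics on a
#' smoothed metaprofile. Per side of the motif centre: `w` is the offset at
#' which the profile first falls below half of the central maximum (the
#' maximum within `center_halfwidth` of offset 0), i.e. the half-maximum
#' half-width of the central dyad distribution; `d` is the offset of the
#' first local maximum beyond `w + guard`, i.e. the distance from the motif
#' centre to the adjacent nucleosome peak. A local maximum must dominate a
#' `+/- peak_window` neighbourhood. Per-side values and their means are
#' reported; a side without a flanking maximum is flagged (`d` undefined),
#' not an error.
#'
#' @param profile A smoothed `nuc_profile`.
#' @param center_halfwidth Search half-width for the central maximum (bp).
#' @param guard Dead zone beyond `w` before flank-peak detection starts (bp).
#' @param peak_window Neighbourhood half-width a local maximum must dominate
#'   (bp).
#' @return A `barrier_metrics` object (list with `d`, `w`, `d_left`,
#'   `d_right`, `w_left`, `w_right`, `d_defined`).
#' @export
barrier_metrics <- function(profile, center_halfwidth = 100, guard = 20,
                            peak_window = 15) {
  stopifnot(inherits(profile, "nuc_profile"))
  if (!isTRUE(attr(profile, "smoothed"))) {
    abort("barrier_metrics() expects a smoothed profile; call smooth_profile() first")
  }
  v <- profile_signal(profile)
  off <- profile$offset
  halfwidth <- max(off)
  if (!identical(off, seq(-halfwidth, halfwidth))) {
    abort("profile offsets must form a symmetric contiguous grid")
  }
  central_max <- max(v[abs(off) <= center_halfwidth])
  half <- central_max / 2
  side_metrics <- function(sgn) {
    # values at offsets 0..halfwidth walking outwards on one side
    vv <- v[sgn * (0:halfwidth) + halfwidth + 1L]
    below <- which(vv < half)
    w_side <- if (length(below) == 0) NA_real_ else below[1] - 1
    d_side <- NA_real_
    if (!is.na(w_side) && w_side + guard + 1 <= halfwidth - peak_window) {
      for (o in seq(w_side + guard + 1, halfwidth - peak_window)) {
        nb <- vv[(o - peak_window):(o + peak_window) + 1L]
        if (vv[o + 1] == max(nb) && vv[o + 1] > min(nb)) { d_side <- o; break }
      }
    }
    c(w = w_side, d = d_side)
  }
  left <- side_metrics(-1)
  right <- side_metrics(1)
  structure(list(
    d = mean(c(left["d"], right["d"])),
    w = mean(c(left["w"], right["w"])),
    d_left = unname(left["d"]), d_right = unname(right["d"]),
    w_left = unname(left["w"]), w_right = unname(right["w"]),
    d_defined = !is.na(left["d"]) && !is.na(right["d"]),
    central_max = central_max),
    class = "barrier_metrics")
}

#' @export
print.barrier_metrics <- function(x, ...) {
  cat(sprintf("<barrier_metrics> d = %.1f bp (L %.1f / R %.1f)%s, w = %.1f bp (L %.1f / R %.1f)\n",
              x$d, x$d_left, x$d_right,
              if (x$d_defined) "" else " [flank peak undefined]",
              x$w, x$w_left, x$w_right))
  invisible(x)
}

#' Compare two normalised metaprofiles
#'
#' Differences are `condition - reference` per offset, with two scalar
#' summaries: the central delta (mean difference within the reference
#' barrier half-width `w`) and the flank phasing amplitude delta (change in
#' the peak-to-trough range around the reference flank-peak distance `d`,
#' averaged over both sides). After depletion of the organising remodeller a
#' positive central delta and a negative phasing amplitude delta indicate
#' midpoint gain over the motif and loss of flanking nucleosome
#' organisation.
#'
#' @param reference,condition Normalised `nuc_profile`s on the same offset
#'   grid.
#' @param metrics Optional precomputed [barrier_metrics()] of the (smoothed)
#'   reference; computed internally otherwise.
#' @param flank_halfwidth Half-width (bp) of the window around `+/- d` used
#'   for the phasing amplitude.
#' @return A `profile_comparison`: list with `difference` (tibble `offset`,
#'   `delta`), `central_delta`, `flank_amplitude_delta`, `w`, `d`.
#' @export
compare_conditions <- function(reference, condition, metrics = NULL,
                               flank_halfwidth = 90) {
  stopifnot(inherits(reference, "nuc_profile"), inherits(condition, "nuc_profile"))
  if (!identical(reference$offset, condition$offset)) {
    abort("profiles are on different offset grids")
  }
  if (!("enrichment" %in% names(reference)) ||
      !("enrichment" %in% names(condition))) {
    abort("both profiles must be normalised (call normalize_enrichment())")
  }
  if (is.null(metrics)) {
    ref_sm <- if (isTRUE(attr(reference, "smoothed"))) reference
              else smooth_profile(reference)
    metrics <- barrier_metrics(ref_sm)
  }
  delta <- condition$enrichment - reference$enrichment
  off <- reference$offset
  central_delta <- mean(delta[abs(off) <= metrics$w])
  amp <- function(p, d) {
    sel <- abs(abs(off) - d) <= flank_halfwidth
    max(p$enrichment[sel]) - min(p$enrichment[sel])
  }
  flank_delta <- if (is.na(metrics$d)) NA_real_ else
    amp(condition, metrics$d) - amp(reference, metrics$d)
  structure(list(difference = tibble(offset = off, delta = delta),
                 central_delta = central_delta,
                 flank_amplitude_delta = flank_delta,
                 w = metrics$w, d = metrics$d),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf("<profile_comparison> central delta %.3g, flank amplitude delta %.3g (w = %.0f, d = %.0f)\n",
              x$central_delta, x$flank_amplitude_delta, x$w, x$d))
  invisible(x)
}
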