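frag_at <- function(mid, chrom = "chrT") {
  tibble::tibble(chrom = chrom, start = mid - 73, end = mid + 74)
}

motif_at <- function(center, strand = "+", chrom = "chrT") {
  tibble::tibble(chrom = chrom, start = center - 7, end = center + 8,
                 strand = strand)
}

test_that("midpoint aggregation counts offsets around motif centres", {
  prof <- aggregate_midpoint_profile(frag_at(5000), motif_at(5000))
  expect_equal(sum(prof$count), 1)
  expect_equal(prof$count[prof$offset == 0], 1)

  # additivity: duplicated motif doubles every count
  two <- aggregate_midpoint_profile(frag_at(5000),
                                    dplyr::bind_rows(motif_at(5000),
                                                     motif_at(5000)))
  expect_equal(two$count, 2 * prof$count)

  # minus-strand motifs mirror offsets
  plus <- aggregate_midpoint_profile(frag_at(5030), motif_at(5000))
  minus <- aggregate_midpoint_profile(frag_at(5030), motif_at(5000, "-"))
  expect_equal(plus$count[plus$offset == 30], 1)
  expect_equal(minus$count[minus$offset == -30], 1)

  expect_error(aggregate_midpoint_profile(frag_at(5000), motif_at(5000)[0, ]),
               "motif")
})

test_that("aggregation equals a brute-force per-site per-fragment tally", {
  set.seed(505)
  centers <- sample(3000:50000, 5)
  motifs <- dplyr::bind_rows(purrr::map(centers, function(c) {
    motif_at(c, strand = sample(c("+", "-"), 1))
  }))
  mids <- sample(1000:52000, 50)
  frags <- dplyr::bind_rows(purrr::map(mids, frag_at))
  # odd fragment lengths are exact; also test even-length floor rounding
  frags$end[1:10] <- frags$end[1:10] + 1

  prof <- aggregate_midpoint_profile(frags, motifs, halfwidth = 1000)
  oracle <- integer(2001)
  for (i in seq_len(nrow(motifs))) {
    cen <- floor((motifs$start[i] + motifs$end[i]) / 2)
    for (j in seq_len(nrow(frags))) {
      mid <- floor((frags$start[j] + frags$end[j]) / 2)
      off <- mid - cen
      if (motifs$strand[i] == "-") off <- -off
      if (abs(off) <= 1000) oracle[off + 1001] <- oracle[off + 1001] + 1L
    }
  }
  expect_equal(prof$count, oracle)
})

test_that("enrichment normalisation divides by sites and experiment-wide reads", {
  prof <- aggregate_midpoint_profile(
    dplyr::bind_rows(frag_at(5000), frag_at(5000)),
    dplyr::bind_rows(motif_at(5000), motif_at(9000)), total_reads = 1000)
  norm <- normalize_enrichment(prof)
  expect_equal(norm$enrichment[norm$offset == 0], 2 / (2 * 1000))

  bad <- new_profile_for_test(rep(1, 201), total_reads = 0)
  expect_error(normalize_enrichment(bad), "total_reads")
  expect_error(
    aggregate_midpoint_profile(frag_at(5000), motif_at(5000), total_reads = 0),
    "total_reads")
})

test_that("profile enrichment is invariant to duplicating the experiment", {
  set.seed(9)
  mids <- sample(4000:6000, 200, replace = TRUE)
  frags <- dplyr::bind_rows(purrr::map(mids, frag_at))
  motifs <- motif_at(5000)
  one <- smooth_profile(normalize_enrichment(
    aggregate_midpoint_profile(frags, motifs)))
  doubled <- smooth_profile(normalize_enrichment(aggregate_midpoint_profile(
    dplyr::bind_rows(frags, frags), dplyr::bind_rows(motifs, motifs))))
  expect_equal(doubled$enrichment, one$enrichment, tolerance = 1e-12)
})

test_that("smoothing has the documented kernel and edge behaviour", {
  const <- new_profile_for_test(rep(2, 201))
  expect_equal(smooth_profile(const, 30)$count, rep(2, 201))

  impulse <- new_profile_for_test(c(rep(0, 100), 1, rep(0, 100)))
  sm <- smooth_profile(impulse, 30)$count
  expect_equal(sum(sm), 1)
  expect_equal(max(sm), 1 / 30)
  expect_equal(sum(sm == max(sm)), 29)  # interior plateau
  expect_equal(sum(abs(sm - 1 / 60) < 1e-12), 2)  # half-weight shoulders
  expect_equal(sm, rev(sm))  # symmetric kernel

  # ~30-fold variance reduction in the interior for white noise
  set.seed(10)
  noise <- new_profile_for_test(rnorm(2001))
  smn <- smooth_profile(noise, 30)$count
  ratio <- var(noise$count[200:1800]) / var(smn[200:1800])
  expect_gt(ratio, 20)
  expect_lt(ratio, 45)

  expect_error(smooth_profile(const, 0), "window")
  expect_error(smooth_profile(const, 500), "window")
})

test_that("barrier metrics recover an analytic central-plus-flank mixture", {
  off <- -1000:1000
  dens <- function(mu, sd) dnorm(off, mu, sd)
  shape <- 0.4 * dens(0, 35) +
    0.1 * Reduce(`+`, purrr::map(c(-1, 1), function(s) {
      Reduce(`+`, purrr::map(0:2, function(k) dens(s * (180 + k * 185), 35)))
    }))
  prof <- smooth_profile(new_profile_for_test(shape), 30)
  bm <- barrier_metrics(prof)
  expect_true(bm$d_defined)
  expect_equal(bm$w_left, bm$w_right)  # exact symmetry of an even profile
  expect_equal(bm$d_left, bm$d_right)
  expect_lte(abs(bm$w - 35 * sqrt(2 * log(2))), 6)
  expect_lte(abs(bm$d - 180), 10)

  expect_error(barrier_metrics(new_profile_for_test(shape)), "smoothed")
})

test_that("broader barriers push adjacent nucleosomes outwards (d-w relation)", {
  run_metrics <- function(central_sd, d0, seed) {
    cfg <- sim_config(seed = seed, central_sd = central_sd,
                      flank_distance_d0 = d0, nuc_sites = 150)
    nuc <- simulate_nucleosome_fragments(cfg)
    barrier_metrics(smooth_profile(normalize_enrichment(
      aggregate_midpoint_profile(nuc$fragments, nuc$motifs))))
  }
  narrow <- run_metrics(35, 180, seed = 21)
  broad <- run_metrics(70, 280, seed = 21)
  expect_gt(broad$w, narrow$w)
  expect_gt(broad$d, narrow$d)
})

test_that("mirroring fragments and motifs swaps the per-side metrics exactly", {
  cfg <- sim_config(seed = 33, nuc_sites = 40)
  nuc <- simulate_nucleosome_fragments(cfg)
  motifs <- dplyr::mutate(nuc$motifs, strand = "+")
  pipeline <- function(frags, mots) {
    barrier_metrics(smooth_profile(normalize_enrichment(
      aggregate_midpoint_profile(frags, mots))))
  }
  bm <- pipeline(nuc$fragments, motifs)
  # reflect everything through a fixed pivot; use even start+end sums so the
  # floor midpoint maps exactly
  pivot <- 2 * cfg$chrom_length
  mirror <- function(df) {
    dplyr::mutate(df, start2 = pivot - df$end + 1, end2 = pivot - df$start + 1,
                  start = .data$start2, end = .data$end2,
                  start2 = NULL, end2 = NULL)
  }
  bm_m <- pipeline(mirror(nuc$fragments), mirror(motifs))
  expect_identical(bm_m$w_left, bm$w_right)
  expect_identical(bm_m$w_right, bm$w_left)
  expect_identical(bm_m$d_left, bm$d_right)
  expect_identical(bm_m$d_right, bm$d_left)
})

test_that("condition comparison is antisymmetric and detects barrier loss", {
  cfg0 <- sim_config(seed = 12, nuc_sites = 150)
  # depleted condition: more central midpoints, blurrier flanks
  cfg2 <- sim_config(seed = 12, nuc_sites = 150, central_weight = 0.45,
                     flank_sd = 60)
  prof_of <- function(cfg) {
    nuc <- simulate_nucleosome_fragments(cfg)
    smooth_profile(normalize_enrichment(
      aggregate_midpoint_profile(nuc$fragments, nuc$motifs)))
  }
  p0 <- prof_of(cfg0); p2 <- prof_of(cfg2)
  cmp <- compare_conditions(p0, p2)
  expect_gt(cmp$central_delta, 0)
  expect_lt(cmp$flank_amplitude_delta, 0)

  same <- compare_conditions(p0, p0)
  expect_true(all(same$difference$delta == 0))

  swapped <- compare_conditions(p2, p0, metrics = barrier_metrics(p0))
  expect_equal(swapped$difference$delta, -cmp$difference$delta)
  expect_equal(swapped$central_delta, -cmp$central_delta)

  short <- new_profile_for_test(rep(1, 201))
  expect_error(compare_conditions(p0, normalize_enrichment(short)), "grid")
})
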