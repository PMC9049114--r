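#' Canned synthetic study scenarios
#'
#' Each `scenario_*()` function builds a seeded synthetic dataset with the
#' generator defaults, runs the corresponding pipeline stage end to end,
#' and returns the recovery metrics against the planted truth together
#' with the intermediate objects. They are the package's reproducible
#' validation experiments (used by the test suite and the acceptance
#' script) and double as worked examples.
#'
#' `scenario_anchoring()`: a 2-Mb TE-rich chromosome, ISBP markers
#' designed on the reference, a founder-mosaic copy fragmented into 40
#' shuffled scaffolds, and collinearity anchoring back to chromosome
#' order.
#'
#' @param seed Integer seed driving every random choice.
#' @return A list with `metrics` (named numerics) and scenario objects.
#' @export
scenario_anchoring <- function(seed = 1) {
  cfg <- panel_config(n_cultivars = 2, n_founders = 2, chrom_len = 2e6,
                      seed = seed)
  p <- simulate_panel(cfg)
  ref <- p$base
  markers <- filter_unique(design_isbp(ref, p$te_intervals), ref,
                           map_config(preset = "validate"))
  cv <- p$cultivars$seq[p$cultivars$cultivar == "cv01"]
  fr <- fragment_assembly(cv, cfg, "chr1", n_pieces = 40,
                          min_piece = 30000)
  hits <- map_markers(markers, fr$scaffolds[, c("id", "seq")],
                      map_config(preset = "anchor"))
  hits <- hits[order(hits$target_chrom, hits$target_start), ]
  acfg <- anchor_config()
  pairs <- pair_adjacent(hits, markers, acfg)
  anchors <- assign_chromosome(pairs, acfg, scaffolds = fr$scaffolds$id)
  layout <- order_scaffolds(anchors,
                            setNames(fr$scaffolds$length, fr$scaffolds$id),
                            acfg)
  truth <- fr$truth[order(fr$truth$rank), ]
  placed <- layout$chroms[["chr1"]]
  n <- nrow(truth)
  order_ok <- length(placed$scaffold) == n &&
    all(placed$scaffold == truth$scaffold)
  orient_acc <- if (is.null(placed)) 0 else {
    m <- match(truth$scaffold, placed$scaffold)
    mean(placed$orientation[m] == truth$orientation, na.rm = TRUE)
  }
  min_pairs <- min(anchors$n_valid_pairs)
  list(metrics = list(
         assignment_accuracy_pct = 100 * mean(anchors$assigned_chrom == "chr1"),
         order_accuracy_pct = if (order_ok) 100 else
           100 * mean(placed$scaffold[seq_len(min(n, nrow(placed)))] ==
                        truth$scaffold[seq_len(min(n, nrow(placed)))]),
         orientation_accuracy_pct = 100 * orient_acc,
         min_valid_pairs_per_scaffold = min_pairs),
       markers = markers, scaffolds = fr$scaffolds, truth = truth,
       anchors = anchors, layout = layout)
}

#' @describeIn scenario_anchoring An 11-cultivar, 6-founder panel on a
#'   2-Mb chromosome (0.7 % founder divergence) with two planted
#'   cultivar-specific donor segments, painted at k = 31, e = 0.95, 1-kb
#'   markers every 20 kb, merged to 1-Mb superblocks. Metrics: fraction
#'   of superblocks whose profile matches the planted sharing truth, the
#'   per-bin profile accuracy, and the fraction of planted
#'   cultivar-specific bins classified black.
#' @export
scenario_painting <- function(seed = 1) {
  spans <- tibble::tibble(cultivar = "cv05", chrom = "chr1",
                          start = c(300000, 1400000),
                          length = c(120000, 140000))
  cfg <- panel_config(seed = seed + 1L, introgressions = spans)
  p <- simulate_panel(cfg)
  hcfg <- haplo_config()
  panel <- tibble(cultivar = unique(p$cultivars$cultivar),
                  seq = p$cultivars$seq)
  pt <- paint_chromosome(panel, hcfg)

  truth_bins <- truth_sharing_profiles(p$truth, cfg,
                                       spacing = hcfg$spacing,
                                       marker_len = hcfg$marker_len)
  truth_sb <- truth_bins %>%
    group_by(.data$cultivar) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    dplyr::group_modify(~ merge_to_superblocks(.x, hcfg)) %>%
    ungroup()
  got_sb <- pt$superblocks %>%
    select("cultivar", "tile_start", got = "profile")
  cmp <- truth_sb %>%
    select("cultivar", "tile_start", want = "profile") %>%
    left_join(got_sb, by = c("cultivar", "tile_start"))
  bins_cmp <- pt$blocks %>%
    select("cultivar", "start", got = "profile") %>%
    left_join(truth_bins %>% select("cultivar", "start", want = "profile"),
              by = c("cultivar", "start"))
  black_bins <- pt$blocks %>%
    filter(.data$cultivar == "cv05",
           (.data$start >= 300000 & .data$start < 420000) |
             (.data$start >= 1400000 & .data$start < 1540000))
  list(metrics = list(
         superblock_recovery_pct = 100 * mean(cmp$got == cmp$want),
         bin_profile_accuracy_pct = 100 * mean(bins_cmp$got == bins_cmp$want,
                                               na.rm = TRUE),
         black_bin_rate_pct = 100 * mean(black_bins$cls == "black"),
         n_superblocks = nrow(cmp)),
       painting = pt, truth_bins = truth_bins, cfg = cfg)
}

#' @describeIn scenario_anchoring Donor introgression detection: a 4-Mb
#'   chromosome, 11 cultivars on a uniform background, three donor
#'   segments of 10/20/30 bins (20-kb grid) plus isolated single-bin
#'   minority noise planted in one cultivar, donor reads at 100x the
#'   background depth. Metrics: recall and precision of the calls at the
#'   default run/coverage thresholds and the largest boundary error in
#'   bins.
#' @export
scenario_introgression <- function(seed = 1) {
  bin <- 20000
  spans <- tibble::tibble(
    cultivar = "cv01", chrom = "chr1",
    start = c(10, 50, 110) * bin, length = c(10, 20, 30) * bin)
  noise <- tibble::tibble(
    cultivar = "cv01", chrom = "chr1",
    start = c(30, 90, 170) * bin, length = bin)
  cfg <- panel_config(n_cultivars = 11, n_founders = 1, chrom_len = 4e6,
                      seed = seed + 2L,
                      introgressions = dplyr::bind_rows(spans, noise))
  p <- simulate_panel(cfg)
  hcfg <- haplo_config(spacing = bin, merge_window = bin,
                       grey_min_share = 12)
  panel <- tibble(cultivar = unique(p$cultivars$cultivar),
                  seq = p$cultivars$seq)
  pt <- paint_chromosome(panel, hcfg)
  blocks <- pt$blocks %>%
    filter(.data$cultivar == "cv01") %>%
    arrange(.data$start)
  donor_spans <- dplyr::bind_rows(spans, noise) %>%
    mutate(chrom = "chr1", end = .data$start + .data$length)
  reads <- simulate_donor_alignments(donor_spans[, c("chrom", "start", "end")],
                                     c(chr1 = cfg$chrom_len),
                                     depth_in = 20, depth_bg = 0.2,
                                     seed = seed + 3L)
  icfg <- intro_config(bin_len = bin)
  bins <- bin_coverage(reads, c(chr1 = cfg$chrom_len), icfg)
  calls <- call_introgressions(blocks, bins, icfg)
  truth_spans <- spans %>% mutate(end = .data$start + .data$length)
  match_call <- function(s, e) {
    any(abs(calls$start - s) <= bin & abs(calls$end - e) <= bin)
  }
  recalled <- mapply(match_call, truth_spans$start, truth_spans$end)
  call_is_true <- vapply(seq_len(nrow(calls)), function(i)
    any(abs(truth_spans$start - calls$start[i]) <= bin &
          abs(truth_spans$end - calls$end[i]) <= bin), logical(1))
  boundary_err <- if (nrow(calls) == 0) NA_real_ else
    max(vapply(seq_len(nrow(calls)), function(i)
      min(pmax(abs(truth_spans$start - calls$start[i]),
               abs(truth_spans$end - calls$end[i]))) / bin, numeric(1)))
  list(metrics = list(
         recall = sum(recalled) / nrow(truth_spans),
         precision = if (nrow(calls) == 0) NA_real_ else mean(call_is_true),
         n_calls = nrow(calls),
         max_boundary_error_bins = boundary_err),
       calls = calls, blocks = blocks, bins = bins, truth = truth_spans)
}

#' @describeIn scenario_anchoring Conservation and consensus-quality QC
#'   on planted truth: marker conservation with 6 % of tagged loci
#'   deleted (expected 94 %), exon conservation with 3.8 % of exon loci
#'   deleted (expected 96.2 %), the perfect-match marker fraction against
#'   a 0.7 %-divergent target, and the k-mer QV of an assembly mutated at
#'   1e-3 per base (expected QV 30).
#' @export
scenario_qc <- function(seed = 1) {
  cfg <- panel_config(n_cultivars = 2, n_founders = 2, chrom_len = 1e6,
                      seed = seed + 4L)
  fd <- simulate_founders(cfg)
  ref <- fd$base
  markers <- filter_unique(design_isbp(ref, fd$te_intervals), ref,
                           map_config(preset = "validate"))
  markers <- markers[order(markers$start), ]
  keep <- rep(TRUE, nrow(markers))
  last_end <- -1
  for (i in seq_len(nrow(markers))) {
    if (markers$start[i] < last_end) keep[i] <- FALSE
    else last_end <- markers$end[i]
  }
  markers <- head(markers[keep, ], 300)

  withr::with_seed(seed + 5L, {
    # delete exactly 6% of tagged loci in a derived target
    n_del <- round(0.06 * nrow(markers))
    del <- sort(sample(nrow(markers), n_del))
    tseq <- ref$seq[1]
    for (i in del)
      tseq <- splice_span(tseq, markers$start[i], markers$end[i],
                          random_dna(150))
    target_del <- tibble(id = "chr1", seq = tseq)
    # independent 0.7%-divergent target for the perfect-match fraction
    target_div <- tibble(id = "chr1", seq = mutate_seq(ref$seq[1], 0.007))
  })
  cons_del <- conservation_rate(markers, target_del)
  cons_div <- conservation_rate(markers, target_div)

  es <- emit_exon_set(ref, n_exons = 500, del_fraction = 0.038,
                      mut_fraction = 0, avoid = fd$te_intervals,
                      seed = seed + 6L)
  exon_rep <- exon_conservation(es$exons, es$target)

  genome_seq <- substring(ref$seq[1], 1, 5e5)
  trusted <- kmer_set(genome_seq, k = 21)
  mut <- withr::with_seed(seed + 7L, mutate_seq(genome_seq, 1e-3))
  qv <- kmer_qv(mut, trusted, k = 21)

  list(metrics = list(
         isbp_conservation_pct = 100 * cons_del$conserved_fraction,
         exon_conservation_pct = 100 * exon_rep$conserved_fraction,
         perfect_match_pct = 100 * cons_div$perfect_fraction,
         kmer_qv_at_1e3 = qv$qv,
         qv35p9_error_spacing_kb = round(qv_to_spacing(35.9) / 1000, 1),
         presence_min_count_1kb = presence_min_count(1000, 31, 0.95)),
       markers = markers, exons = es, qv = qv)
}
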