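mk_hits <- function(scaffold, starts, ids) {
  tibble::tibble(marker_id = ids, target_chrom = scaffold,
                 target_start = starts)
}

mk_ref <- function(ids, chroms, pos) {
  tibble::tibble(id = ids, chrom = chroms, junction_pos = pos)
}

test_that("adjacent pairing applies both gap conditions and orientation", {
  hits <- mk_hits("s1", c(1000, 20000), c("a", "b"))
  ref <- mk_ref(c("a", "b"), c("chr1", "chr1"), c(101000, 120000))
  p <- pair_adjacent(hits, ref)
  expect_equal(nrow(p), 1)
  expect_equal(p$pair_orientation, "+")
  expect_equal(p$ref_mid, 110500)
  expect_equal(p$scaffold_gap, 19000)
  expect_equal(p$ref_gap, 19000)

  # 60-kb scaffold gap: no pair
  hits2 <- mk_hits("s1", c(1000, 61000), c("a", "b"))
  expect_equal(nrow(pair_adjacent(hits2, ref)), 0)

  # reversed reference order: valid pair, orientation -
  ref3 <- mk_ref(c("a", "b"), c("chr1", "chr1"), c(120000, 101000))
  p3 <- pair_adjacent(hits, ref3)
  expect_equal(p3$pair_orientation, "-")

  # different reference chromosomes: no pair
  ref4 <- mk_ref(c("a", "b"), c("chr1", "chr2"), c(101000, 120000))
  expect_equal(nrow(pair_adjacent(hits, ref4)), 0)

  # unsorted input errors
  expect_error(pair_adjacent(mk_hits("s1", c(20000, 1000), c("a", "b")),
                             ref), "sorted")
})

test_that("chromosome assignment follows the >=50% single-winner rule", {
  mkpairs <- function(chroms, orients = NULL) {
    n <- length(chroms)
    tibble::tibble(scaffold = "s1", marker_a = letters[1:n],
                   marker_b = LETTERS[1:n], scaffold_gap = 1000,
                   ref_chrom = chroms, ref_gap = 1000,
                   ref_mid = seq(1e6, by = 1e4, length.out = n),
                   pair_orientation = if (is.null(orients)) rep("+", n)
                                      else orients)
  }
  a <- assign_chromosome(mkpairs(rep(c("chr1A", "chr1B"), c(7, 3))))
  expect_equal(a$assigned_chrom, "chr1A")
  expect_equal(a$support_fraction, 0.7)

  # 5/5 split: ambiguous, chrUn
  a2 <- assign_chromosome(mkpairs(rep(c("chr1A", "chr1B"), c(5, 5))))
  expect_equal(a2$assigned_chrom, "chrUn")

  # orientation votes: majority, tie -> +
  a3 <- assign_chromosome(mkpairs(rep("chr1A", 3), c("+", "+", "-")))
  expect_equal(a3$orientation, "+")
  expect_equal(c(a3$votes_plus, a3$votes_minus), c(2L, 1L))
  a4 <- assign_chromosome(mkpairs(rep("chr1A", 4), c("+", "+", "-", "-")))
  expect_equal(a4$orientation, "+")
  a5 <- assign_chromosome(mkpairs(rep("chr1A", 3), c("-", "-", "+")))
  expect_equal(a5$orientation, "-")

  # zero valid pairs -> chrUn row, not an error
  a6 <- assign_chromosome(mkpairs("chr1A")[0, ], scaffolds = "lonely")
  expect_equal(a6$assigned_chrom, "chrUn")
  expect_equal(a6$n_valid_pairs, 0L)
})

test_that("ordering sorts by median with length/id tie-breaks", {
  anchors <- tibble::tibble(
    scaffold = c("A", "B", "C", "D"),
    assigned_chrom = c("chr1", "chr1", "chr1", "chrUn"),
    n_valid_pairs = 5L, n_pairs_on_assigned = 5L, support_fraction = 1,
    median_ref_pos = c(5e6, 2e6, 2e6, NA),
    orientation = "+", votes_plus = 5L, votes_minus = 0L)
  lens <- c(A = 40000, B = 10000 + 30000, C = 50000, D = 60000)
  lay <- order_scaffolds(anchors, lens, anchor_config(min_scaffold_len = 1000))
  # ties at 2e6 resolve to the longer scaffold (C, 50 kb) first
  expect_equal(lay$chroms$chr1$scaffold, c("C", "B", "A"))
  expect_equal(lay$unplaced, "D")
  # short scaffolds are unplaced
  lay2 <- order_scaffolds(anchors, lens, anchor_config(min_scaffold_len = 45000))
  expect_equal(lay2$chroms$chr1$scaffold, "C")
  expect_setequal(lay2$unplaced, c("A", "B", "D"))
  expect_error(order_scaffolds(anchors[c(1, 1, 2), ], lens), "duplicate")
})

test_that("pseudomolecule assembly joins oriented scaffolds with 100 N", {
  s1 <- rand_dna(1000, seed = 1)
  s2 <- rand_dna(1000, seed = 2)
  scafs <- tibble::tibble(id = c("s1", "s2"), seq = c(s1, s2))
  lay <- structure(list(
    chroms = list(chr1 = tibble::tibble(scaffold = c("s1", "s2"),
                                        orientation = c("+", "+"))),
    unplaced = character(), gap_len = 100L), class = "pseudo_layout")
  ps <- build_pseudomolecule(lay, scafs)
  expect_equal(ps$length, 2100)
  expect_equal(substring(ps$seq, 1001, 1100), strrep("N", 100))

  lay_m <- structure(list(
    chroms = list(chr1 = tibble::tibble(scaffold = "s1", orientation = "-")),
    unplaced = character(), gap_len = 100L), class = "pseudo_layout")
  expect_equal(build_pseudomolecule(lay_m, scafs)$seq,
               reverse_complement(s1))
  lay_bad <- structure(list(
    chroms = list(chr1 = tibble::tibble(scaffold = "sX", orientation = "+")),
    unplaced = character(), gap_len = 100L), class = "pseudo_layout")
  expect_error(build_pseudomolecule(lay_bad, scafs), "sX")
})

test_that("break snapping picks the nearest gap, lower coordinate on ties", {
  gaps <- tibble::tibble(start = c(5000, 20000), end = c(5100, 20100))
  expect_equal(snap_break_to_gap(gaps, 4990)$start, 5000)
  expect_equal(snap_break_to_gap(gaps, 19000)$start, 20000)
  # equidistant from midpoints 5050 and 20050 -> 12550 -> lower coordinate
  expect_equal(snap_break_to_gap(gaps, 12550)$start, 5000)
  expect_error(snap_break_to_gap(gaps[0, ], 100), "no internal gap")
})

test_that("anchoring recovers a fragmented chromosome exactly and resists noise", {
  sp <- small_panel()
  p <- sp$panel
  ref <- p$base
  mku <- filter_unique(design_isbp(ref, p$te_intervals), ref,
                       map_config(preset = "validate"))
  cv <- p$cultivars$seq[p$cultivars$cultivar == "cv01" &
                          p$cultivars$chrom == "chr1"]
  fr <- fragment_assembly(cv, sp$cfg, "chr1", n_pieces = 8,
                          min_piece = 20000)
  hits <- map_markers(mku, fr$scaffolds[, c("id", "seq")],
                      map_config(preset = "anchor"))
  hits <- hits[order(hits$target_chrom, hits$target_start), ]
  cfg <- anchor_config(min_scaffold_len = 5000)
  pairs <- pair_adjacent(hits, mku, cfg)
  anch <- assign_chromosome(pairs, cfg, scaffolds = fr$scaffolds$id)
  lay <- order_scaffolds(anch, setNames(fr$scaffolds$length,
                                        fr$scaffolds$id), cfg)
  tr <- fr$truth[order(fr$truth$rank), ]
  expect_equal(lay$chroms$chr1$scaffold, tr$scaffold)
  expect_equal(lay$chroms$chr1$orientation, tr$orientation)
  expect_equal(length(lay$unplaced), 0)

  # conservation: sum of pseudomolecule length minus gaps = scaffold total
  ps <- build_pseudomolecule(lay, fr$scaffolds)
  expect_equal(ps$length - 100 * (nrow(fr$scaffolds) - 1),
               sum(fr$scaffolds$length))

  # inject 10% isolated mis-mapped single hits: assignments unchanged
  withr::with_seed(20, {
    n_noise <- round(0.1 * nrow(hits))
    noise <- tibble::tibble(
      marker_id = sample(mku$id, n_noise),
      target_chrom = sample(fr$scaffolds$id, n_noise, replace = TRUE),
      target_start = runif(n_noise, 0, 3e4),
      strand = "+", identity = 1, query_coverage = 1, mismatches = 0L,
      is_unique = TRUE)
  })
  noisy <- dplyr::bind_rows(hits, noise)
  noisy <- noisy[order(noisy$target_chrom, noisy$target_start), ]
  anch2 <- assign_chromosome(pair_adjacent(noisy, mku, cfg), cfg,
                             scaffolds = fr$scaffolds$id)
  expect_equal(anch2$assigned_chrom, anch$assigned_chrom)
  lay2 <- order_scaffolds(anch2, setNames(fr$scaffolds$length,
                                          fr$scaffolds$id), cfg)
  expect_equal(lay2$chroms$chr1$scaffold, tr$scaffold)
  expect_equal(lay2$chroms$chr1$orientation, tr$orientation)

  # monotonicity: widening the pair gap never loses valid pairs
  n_narrow <- nrow(pair_adjacent(hits, mku, anchor_config(max_pair_gap = 20000)))
  n_wide <- nrow(pair_adjacent(hits, mku, anchor_config(max_pair_gap = 80000)))
  expect_gte(n_wide, n_narrow)
})
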