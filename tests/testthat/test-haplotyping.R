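tiny_cfg <- function(...) haplo_config(k = 4, marker_len = 6, spacing = 6,
                                       grey_min_share = 10, ...)

test_that("coloured index stores canonical k-mers with per-colour bits", {
  # "ACGTACGTAC", k=4: canonical set {ACGT, CGTA, GTAC} (TACG -> CGTA)
  panel <- tibble::tibble(cultivar = c("a", "b"),
                          seq = c("ACGTACGTAC", "ACGTACGTAC"))
  idx <- build_colored_index(panel, tiny_cfg())
  expect_equal(idx$n_kmers, 3)
  qp <- query_presence("ACGTACGTAC", idx, tiny_cfg())
  expect_equal(qp$profile, "11")

  # k-mer present only in cultivar 2
  panel2 <- tibble::tibble(cultivar = c("a", "b"),
                           seq = c("AAAAAAAAAA", "AAAACCAAAA"))
  idx2 <- build_colored_index(panel2, tiny_cfg())
  qp2 <- query_presence("AACC", idx2, tiny_cfg(e = 1))
  expect_equal(qp2$profile, "01")
  expect_error(build_colored_index(
    tibble::tibble(cultivar = c("a", "b"), seq = c("ACG", "ACGT")),
    tiny_cfg()), "shortest")
})

test_that("marker grid extraction is anchored at 0 and skips N windows", {
  cfg <- haplo_config(spacing = 20000, marker_len = 1000)
  seq100k <- rand_dna(1e5, seed = 41)
  mk <- extract_query_markers(seq100k, cfg)
  expect_equal(mk$start, c(0, 20000, 40000, 60000, 80000) )
  expect_equal(unique(nchar(mk$seq)), 1000)
  expect_equal(nrow(extract_query_markers(rand_dna(900, seed = 1), cfg)), 0)
  # a window that is mostly N is skipped
  seqN <- paste0(substring(seq100k, 1, 20000), strrep("N", 1000),
                 substring(seq100k, 21001, 1e5))
  mkN <- extract_query_markers(seqN, cfg)
  expect_false(20000 %in% mkN$start)
})

test_that("presence ratio threshold matches the closed-form count", {
  expect_equal(presence_min_count(1000, 31, 0.95), 922L)
  expect_equal(presence_min_count(1000, 31, 1), 970L)
})

test_that("one substitution keeps a marker present, two spread ones drop it", {
  withr::with_seed(42, {
    backbone <- rand_dna(5e4)
    marker <- substring(backbone, 10001, 11000)
    one_snp <- sub_at(marker, 500)
    two_snp <- sub_at(marker, c(300, 700))  # >= 31 bases apart
  })
  cfg <- haplo_config()  # k=31, e=0.95
  panel <- tibble::tibble(
    cultivar = c("carrier", "other"),
    seq = c(backbone, rand_dna(5e4, seed = 43)))
  idx <- build_colored_index(panel, cfg)
  q1 <- query_presence(one_snp, idx, cfg)
  expect_equal(substring(q1$profile, 1, 1), "1")   # 939/970 >= 0.95
  q2 <- query_presence(two_snp, idx, cfg)
  expect_equal(substring(q2$profile, 1, 1), "0")   # 908/970 < 0.95
  expect_equal(q2$n_kmers_valid, 970L)
})

test_that("query_presence agrees with an index-free scan", {
  sp <- small_panel()
  cfg <- haplo_config(spacing = 3000, marker_len = 1000)
  panel <- sp$panel$cultivars[sp$panel$cultivars$cultivar %in%
                                c("cv01", "cv02", "cv03"), ]
  panel <- tibble::tibble(cultivar = panel$cultivar,
                          seq = substring(panel$seq, 1, 30000))
  idx <- build_colored_index(panel, cfg)
  mk <- extract_query_markers(panel$seq[1], cfg)
  qp <- query_presence(mk, idx, cfg)
  for (i in seq_len(nrow(qp))) {
    bits <- vapply(panel$seq, function(cs)
      naive_presence(mk$seq[i], cs, cfg$k, cfg$e), logical(1))
    expect_equal(qp$profile[i], paste(as.integer(bits), collapse = ""))
  }
})

test_that("lowering e never clears a presence bit", {
  sp <- small_panel()
  panel <- tibble::tibble(
    cultivar = c("cv01", "cv02"),
    seq = substring(sp$panel$cultivars$seq[sp$panel$cultivars$cultivar %in%
                                             c("cv01", "cv02")], 1, 50000))
  cfg <- haplo_config(spacing = 5000)
  idx <- build_colored_index(panel, cfg)
  mk <- extract_query_markers(panel$seq[1], cfg)
  prev <- NULL
  for (e in c(1.0, 0.95, 0.9, 0.8)) {
    qp <- query_presence(mk, idx, haplo_config(spacing = 5000, e = e))
    if (!is.null(prev)) {
      # every bit set at the higher e stays set at the lower e
      for (i in seq_len(nrow(qp))) {
        hi <- strsplit(prev$profile[i], "")[[1]] == "1"
        lo <- strsplit(qp$profile[i], "")[[1]] == "1"
        expect_true(all(lo[hi]))
      }
    }
    prev <- qp
  }
})

test_that("profiles are invariant to reverse-complementing one cultivar", {
  sp <- small_panel()
  cfg <- haplo_config(spacing = 10000)
  cvs <- c("cv01", "cv02", "cv03")
  seqs <- vapply(cvs, function(cv)
    substring(sp$panel$cultivars$seq[sp$panel$cultivars$cultivar == cv],
              1, 60000), character(1))
  panel <- tibble::tibble(cultivar = cvs, seq = unname(seqs))
  panel_rc <- panel
  panel_rc$seq[2] <- reverse_complement(panel_rc$seq[2])
  mk <- extract_query_markers(panel$seq[1], cfg)
  qp_a <- query_presence(mk, build_colored_index(panel, cfg), cfg)
  qp_b <- query_presence(mk, build_colored_index(panel_rc, cfg), cfg)
  expect_equal(qp_a$profile, qp_b$profile)
})

test_that("index completeness: a cultivar always sees its own markers", {
  sp <- small_panel()
  cfg <- haplo_config(spacing = 10000)
  panel <- tibble::tibble(
    cultivar = unique(sp$panel$cultivars$cultivar),
    seq = sp$panel$cultivars$seq)
  idx <- build_colored_index(panel, cfg)
  for (i in c(1, 4)) {
    mk <- extract_query_markers(panel$seq[i], cfg)
    qp <- query_presence(mk, idx, haplo_config(spacing = 10000, e = 1))
    own_bit <- substring(qp$profile, i, i)
    expect_true(all(own_bit == "1"))
  }
})

test_that("palette ranking and tie-breaking are deterministic", {
  profs <- c(rep("0110", 5), rep("1100", 3), rep("0011", 3), rep("1111", 2))
  pal <- top_profiles(profs, haplo_config(top_n = 2))
  expect_equal(pal$profile, c("0110", "0011"))  # tie 3/3 -> lower bit value
  expect_equal(pal$palette_rank, 1:2)
  pal_all <- top_profiles(rep("1010", 7), haplo_config())
  expect_equal(nrow(pal_all), 1)
})

test_that("superblock merging takes the modal profile, leftmost on ties", {
  cfg <- haplo_config(spacing = 20000, merge_window = 1e6)
  blocks <- tibble::tibble(
    start = seq(0, by = 20000, length.out = 50),
    profile = rep(c("Y", "X"), c(20, 30)))
  sb <- merge_to_superblocks(blocks, cfg)
  expect_equal(sb$profile, "X")
  # 25/25 tie -> the profile seen first in the tile
  blocks2 <- blocks
  blocks2$profile <- rep(c("B", "A"), each = 25)
  expect_equal(merge_to_superblocks(blocks2, cfg)$profile, "B")
  # trailing partial tile uses its members
  blocks3 <- tibble::tibble(start = seq(1e6, by = 20000, length.out = 10),
                            profile = rep(c("Z", "W"), c(6, 4)))
  sb3 <- merge_to_superblocks(dplyr::bind_rows(blocks, blocks3), cfg)
  expect_equal(nrow(sb3), 2)
  expect_equal(sb3$profile[2], "Z")
  expect_equal(sb3$n_members[2], 10)
})

test_that("block classification follows black > grey > palette > white", {
  cfg <- haplo_config(grey_min_share = 10, black_share = 1)
  pal <- tibble::tibble(profile = c("00001111000", "01100000000"),
                        n_markers = c(5, 4), palette_rank = 1:2)
  blocks <- tibble::tibble(
    profile = c("00000001000",            # popcount 1 -> black
                "11111111110",            # popcount 10 -> grey
                "00001111000",            # popcount 4, in palette
                "00110011000",            # popcount 4, not in palette
                NA_character_),           # empty profile
    popcount = c(1, 10, 4, 4, NA))
  cls <- classify_blocks(blocks, pal, cfg)
  expect_equal(cls$cls, c("black", "grey", "coloured", "white", "white"))
  expect_equal(cls$palette_rank[3], 1)
  expect_true(is.na(cls$palette_rank[4]))
})

test_that("locus mode localizes a planted region and recovers sharing", {
  withr::with_seed(50, {
    region <- rand_dna(3e4)
    backs <- replicate(4, rand_dna(1.2e5))
  })
  # plant the region identically in cultivars 1 and 2; 3 carries it
  # reverse-complemented; 4 lacks it
  panel <- tibble::tibble(
    cultivar = c("c1", "c2", "c3", "c4"),
    seq = c(paste0(substring(backs[1], 1, 4e4), region,
                   substring(backs[1], 4e4 + 1, 9e4)),
            paste0(substring(backs[2], 1, 6e4), region,
                   substring(backs[2], 6e4 + 1, 9e4)),
            paste0(substring(backs[3], 1, 5e4),
                   reverse_complement(region),
                   substring(backs[3], 5e4 + 1, 9e4)),
            backs[4]))
  res <- locus_haplotypes(region, panel)
  loc <- res$localization
  expect_equal(loc$localized, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(loc$strand[1:3], c("+", "+", "-"))
  expect_equal(loc$start[1], 4e4)
  # c1..c3 share one profile over the locus
  blocks <- res$painting$blocks
  shared <- blocks[blocks$cultivar == "c1", ]
  expect_true(all(shared$profile == "111"))
})
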