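test_that("panel generation is a pure function of (cfg, seed)", {
  cfg <- panel_config(n_cultivars = 3, n_founders = 2, chrom_len = 5e4,
                      segment_len_mean = 2e4, seed = 5)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$founders$seq, b$founders$seq)
  expect_identical(a$cultivars$seq, b$cultivars$seq)
  expect_identical(a$truth$mosaic, b$truth$mosaic)
})

test_that("zero founder divergence yields founders identical to base", {
  cfg <- panel_config(n_cultivars = 2, n_founders = 3, chrom_len = 5e4,
                      founder_divergence = 0, seed = 8)
  fd <- simulate_founders(cfg)
  for (i in seq_len(nrow(fd$founders)))
    expect_identical(fd$founders$seq[i], fd$base$seq[1])
})

test_that("founder pairwise divergence matches the closed form", {
  cfg <- panel_config(n_cultivars = 2, n_founders = 2, chrom_len = 3e5,
                      founder_divergence = 0.007, seed = 9)
  fd <- simulate_founders(cfg)
  obs <- mismatch_frac_str(fd$founders$seq[1], fd$founders$seq[2])
  d <- 0.007
  # each founder mutated i.i.d.: differ where exactly one mutated, or both
  # mutated to different bases (2/3 of double hits)
  p <- 2 * d * (1 - d) + d^2 * 2 / 3
  n <- nchar(fd$founders$seq[1])
  expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("cultivars assigned the same founder share sequence over the span", {
  cfg <- panel_config(n_cultivars = 3, n_founders = 2, chrom_len = 2e5,
                      segment_len_mean = 5e4, seed = 10)
  p <- simulate_panel(cfg)
  mos <- p$truth$mosaic
  found <- FALSE
  for (i in seq_len(nrow(mos))) {
    r <- mos[i, ]
    other <- mos[mos$cultivar != r$cultivar & mos$founder == r$founder &
                   mos$start <= r$start & mos$end >= r$end, ]
    if (nrow(other) > 0) {
      s1 <- substring(p$cultivars$seq[p$cultivars$cultivar == r$cultivar],
                      r$start + 1, r$end)
      s2 <- substring(p$cultivars$seq[p$cultivars$cultivar == other$cultivar[1]],
                      r$start + 1, r$end)
      expect_identical(s1, s2)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("planted introgressions and inversions are applied and recorded", {
  cfg <- panel_config(
    n_cultivars = 3, n_founders = 2, chrom_len = 2e5,
    segment_len_mean = 5e4, donor_divergence = 0.03, seed = 10,
    introgressions = tibble::tibble(cultivar = "cv01", chrom = "chr1",
                                    start = 50000, length = 30000),
    inversions = tibble::tibble(cultivar = "cv02", chrom = "chr1",
                                start = 120000, length = 20000))
  p <- simulate_panel(cfg)
  # introgressed span diverges from base at ~donor_divergence
  cv1 <- p$cultivars$seq[p$cultivars$cultivar == "cv01"]
  obs <- mismatch_frac_str(substring(cv1, 50001, 80000),
                           substring(p$base$seq[1], 50001, 80000))
  expect_lt(abs(obs - 0.03), 3 * sqrt(0.03 * 0.97 / 30000))
  expect_equal(p$truth$introgressions$cultivar, "cv01")
  expect_equal(p$truth$introgressions$end - p$truth$introgressions$start,
               30000)
  # inversion recorded; chromosome length unchanged; span equals the
  # reverse complement of the uninverted mosaic there
  inv <- p$truth$inversions
  expect_equal(inv$cultivar, "cv02")
  cv2 <- p$cultivars$seq[p$cultivars$cultivar == "cv02"]
  expect_equal(nchar(cv2), cfg$chrom_len)
  cfg_noinv <- cfg
  cfg_noinv$inversions <- NULL
  p2 <- simulate_panel(cfg_noinv)
  cv2_plain <- p2$cultivars$seq[p2$cultivars$cultivar == "cv02"]
  expect_identical(substring(cv2, inv$start + 1, inv$end),
                   reverse_complement(substring(cv2_plain, inv$start + 1,
                                                inv$end)))
})

test_that("fragment_assembly is invertible from its truth layout", {
  cfg <- panel_config(n_cultivars = 2, n_founders = 2, chrom_len = 1e5,
                      scaffold_len_mean = 1.5e4, seed = 12)
  genome <- rand_dna(1e5, seed = 99)
  fr <- fragment_assembly(genome, cfg, "chrX")
  tr <- fr$truth[order(fr$truth$rank), ]
  pieces <- vapply(seq_len(nrow(tr)), function(i) {
    s <- fr$scaffolds$seq[fr$scaffolds$id == tr$scaffold[i]]
    if (tr$orientation[i] == "-") reverse_complement(s) else s
  }, character(1))
  expect_identical(paste(pieces, collapse = ""), genome)

  # single piece: the chromosome itself
  fr1 <- fragment_assembly(genome, cfg, "chrX", n_pieces = 1)
  expect_equal(nrow(fr1$scaffolds), 1)
  expect_true(fr1$scaffolds$seq[1] %in%
                c(genome, reverse_complement(genome)))
})

test_that("scaffold orientation flips are ~50% over many pieces", {
  cfg <- panel_config(n_cultivars = 2, n_founders = 2, chrom_len = 2e6,
                      scaffold_len_mean = 1e4, seed = 13)
  genome <- rand_dna(2e6, seed = 100)
  fr <- fragment_assembly(genome, cfg, "chrX", n_pieces = 200)
  frac <- mean(fr$truth$orientation == "-")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 200))
})

test_that("donor alignment simulation respects depth and mapq structure", {
  spans <- tibble::tibble(chrom = "chr1", start = 2e5, end = 4e5)
  reads <- simulate_donor_alignments(spans, c(chr1 = 1e6), depth_in = 10,
                                     depth_bg = 0, read_len = 100,
                                     low_mapq_frac = 0.2, seed = 21)
  expect_true(all(reads$start >= 2e5 & reads$end <= 4e5))
  # mean depth inside span ~ depth_in (Poisson, 3 SD)
  total_bases <- sum(reads$end - reads$start)
  depth <- total_bases / 2e5
  expect_lt(abs(depth - 10), 3 * sqrt(10 * 100 / 2e5))
  # mapq < 10 fraction ~ low_mapq_frac
  frac_low <- mean(reads$mapq < 10)
  expect_lt(abs(frac_low - 0.2),
            3 * sqrt(0.2 * 0.8 / nrow(reads)))
})

test_that("exon set planting gives exact ledger counts and clean exons", {
  genome <- tibble::tibble(id = "chr1", seq = rand_dna(2e5, seed = 31))
  es <- emit_exon_set(genome, n_exons = 100, del_fraction = 0.04,
                      mut_fraction = 0.05, seed = 32)
  expect_equal(sum(es$ledger$class == "deleted"), 4)
  expect_equal(sum(es$ledger$class == "mutated"), 5)
  expect_equal(sum(es$ledger$class == "conserved"), 91)
  expect_true(all(nchar(es$exons$seq) >= 31))
  expect_false(any(grepl("N", es$exons$seq, fixed = TRUE)))
  # no planting: target is the genome itself
  es0 <- emit_exon_set(genome, n_exons = 20, seed = 33)
  expect_identical(es0$target$seq, genome$seq)
  expect_true(all(es0$ledger$class == "conserved"))
})

test_that("mosaic truth tiles each chromosome exactly", {
  sp <- small_panel()
  mos <- sp$panel$truth$mosaic
  for (cv in unique(mos$cultivar)) {
    m <- mos[mos$cultivar == cv, ]
    expect_equal(m$start[1], 0)
    expect_equal(m$end[nrow(m)], sp$cfg$chrom_len)
    if (nrow(m) > 1)
      expect_equal(m$start[-1], m$end[-nrow(m)])
  }
})
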