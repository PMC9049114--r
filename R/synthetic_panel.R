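#' Configuration for the synthetic cultivar panel generator
#'
#' Defines the study conditions the generator emulates: a panel of cultivar
#' chromosomes built as mosaics of a small set of founder haplotypes, with
#' TE-rich sequence in which repeat bodies recur while their insertion
#' junctions stay unique, optional planted introgressions from a more
#' divergent donor, large inversions and a translocation, plus scaffold
#' fragmentation. Every output is a pure function of the configuration
#' (including its `seed`).
#'
#' Defaults mirror the panel structure of chromosome-scale bread-wheat
#' comparisons at desk scale: 11 cultivars drawn from 6 founder haplotypes
#' diverged at 0.7 % per base, with 3 % donor divergence for introgressed
#' segments, on 2-Mb chromosomes.
#'
#' @param n_cultivars Number of cultivars in the panel.
#' @param chrom_names Chromosome names.
#' @param chrom_len Chromosome length in bases.
#' @param n_founders Number of founder haplotypes.
#' @param founder_divergence Per-base substitution rate between each founder
#'   and the ancestral base sequence.
#' @param segment_len_mean Mean founder-segment length (bases) of the
#'   cultivar mosaics (exponential lengths).
#' @param donor_divergence Per-base substitution rate of the donor genome.
#' @param introgressions Tibble with columns `cultivar` (list-column or
#'   comma-separated string of cultivar names), `chrom`, `start`, `length`.
#' @param inversions Tibble with columns `cultivar`, `chrom`, `start`,
#'   `length`.
#' @param translocation Optional list `(cultivar, src_chrom, src_start,
#'   src_end, dest_chrom, dest_pos)`.
#' @param te_density Fraction of the genome covered by planted repeat
#'   bodies; must be < 0.9 or junction uniqueness is unattainable.
#' @param te_body_lengths Length range of repeat bodies.
#' @param scaffold_len_mean Mean scaffold length for [fragment_assembly()].
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return A `panel_config` list.
#' @export
panel_config <- function(n_cultivars = 11,
                         chrom_names = "chr1",
                         chrom_len = 2e6,
                         n_founders = 6,
                         founder_divergence = 0.007,
                         segment_len_mean = 2e5,
                         donor_divergence = 0.03,
                         introgressions = NULL,
                         inversions = NULL,
                         translocation = NULL,
                         te_density = 0.5,
                         te_body_lengths = c(500, 5000),
                         scaffold_len_mean = 5e4,
                         seed = 1L) {
  stopifnot(founder_divergence >= 0, founder_divergence <= 0.1,
            donor_divergence >= 0, donor_divergence <= 0.1,
            n_cultivars >= 1, n_founders >= 1, chrom_len >= 1e4)
  cfg <- list(n_cultivars = n_cultivars, chrom_names = chrom_names,
              chrom_len = as.integer(chrom_len), n_founders = n_founders,
              founder_divergence = founder_divergence,
              segment_len_mean = segment_len_mean,
              donor_divergence = donor_divergence,
              introgressions = introgressions, inversions = inversions,
              translocation = translocation, te_density = te_density,
              te_body_lengths = te_body_lengths,
              scaffold_len_mean = scaffold_len_mean,
              seed = as.integer(seed))
  feats <- rbind(
    if (!is.null(introgressions)) introgressions[, c("chrom", "start", "length")],
    if (!is.null(inversions)) inversions[, c("chrom", "start", "length")])
  if (!is.null(feats) && nrow(feats) > 0 &&
      any(feats$start < 0 | feats$start + feats$length > chrom_len))
    abort("planted feature spans must lie within chromosomes")
  structure(cfg, class = "panel_config")
}

cultivar_names <- function(cfg) sprintf("cv%02d", seq_len(cfg$n_cultivars))

#' Simulate founder haplotypes over a TE-rich base chromosome
#'
#' Builds one ancestral base sequence per chromosome as an alternation of
#' unique single-copy flanks and repeat bodies drawn from a shared library
#' of 20 motifs (each copy carries 1 % internal divergence, so bodies are
#' multi-mapping while the junctions flanking them are unique — the
#' property ISBP marker design relies on). Each founder is the base
#' mutated independently at `founder_divergence` (substitutions only).
#'
#' @param cfg A [panel_config()].
#' @return List with `base` (sequence tibble), `founders` (tibble
#'   `founder`, `chrom`, `seq`), and `te_intervals` (0-based half-open
#'   spans of the planted bodies on the base/founder coordinates, shared by
#'   all founders since divergence is substitution-only).
#' @export
simulate_founders <- function(cfg) {
  stopifnot(inherits(cfg, "panel_config"))
  if (cfg$te_density >= 0.9)
    abort("te_density >= 0.9: junction uniqueness unattainable")
  withr::with_seed(cfg$seed, {
    lib_lens <- round(runif(20, cfg$te_body_lengths[1], cfg$te_body_lengths[2]))
    te_library <- vapply(lib_lens, random_dna, character(1))
    # mean flank length chosen so bodies cover te_density of the sequence
    mean_body <- mean(lib_lens)
    mean_flank <- mean_body * (1 - cfg$te_density) / cfg$te_density
    base <- list()
    te_rows <- list()
    for (chrom in cfg$chrom_names) {
      pieces <- character(0)
      pos <- 0L
      repeat {
        flank_len <- max(150L, as.integer(rexp(1, 1 / mean_flank)))
        flank_len <- min(flank_len, cfg$chrom_len - pos)
        if (flank_len > 0) {
          pieces <- c(pieces, random_dna(flank_len))
          pos <- pos + flank_len
        }
        if (pos >= cfg$chrom_len) break
        body <- mutate_seq(sample(te_library, 1), 0.01)
        body <- substring(body, 1, min(nchar(body), cfg$chrom_len - pos))
        pieces <- c(pieces, body)
        te_rows[[length(te_rows) + 1]] <-
          tibble(chrom = chrom, start = pos, end = pos + nchar(body))
        pos <- pos + nchar(body)
        if (pos >= cfg$chrom_len) break
      }
      base[[chrom]] <- paste(pieces, collapse = "")
    }
    founders <- tidyr::expand_grid(
      founder = sprintf("f%d", seq_len(cfg$n_founders)),
      chrom = cfg$chrom_names)
    founders$seq <- purrr::map2_chr(
      founders$founder, founders$chrom,
      function(f, ch) mutate_seq(base[[ch]], cfg$founder_divergence))
    list(base = tibble(id = cfg$chrom_names,
                       seq = unname(unlist(base[cfg$chrom_names])),
                       length = nchar(unlist(base[cfg$chrom_names]))),
         founders = founders,
         te_intervals = bind_rows(te_rows))
  })
}

intro_cultivars <- function(x) {
  if (is.list(x)) unlist(x) else strsplit(x, ",", fixed = TRUE)[[1]]
}

#' Compose cultivar chromosomes as founder mosaics
#'
#' Each cultivar chromosome is a concatenation of founder segments with
#' exponential lengths (mean `segment_len_mean`). Configured introgression
#' spans are replaced by donor sequence (the base mutated at
#' `donor_divergence`), inversions are reverse-complemented in the listed
#' cultivars, and the optional translocation moves a span between
#' chromosomes. All planted features are recorded in the returned truth.
#'
#' @param founders Result of [simulate_founders()].
#' @param cfg The same [panel_config()].
#' @return List with `cultivars` (tibble `cultivar`, `chrom`, `seq`),
#'   `donor` (sequence tibble), and `truth` (list of `mosaic`,
#'   `introgressions`, `inversions`, `translocation` tibbles; spans 0-based
#'   half-open).
#' @export
compose_cultivars <- function(founders, cfg) {
  stopifnot(inherits(cfg, "panel_config"))
  cvs <- cultivar_names(cfg)
  fseq <- split(founders$founders$seq,
                paste(founders$founders$founder, founders$founders$chrom))
  withr::with_seed(cfg$seed + 1L, {
    donor <- tibble(
      id = founders$base$id,
      seq = vapply(founders$base$seq,
                   function(s) mutate_seq(s, cfg$donor_divergence),
                   character(1), USE.NAMES = FALSE))
    donor$length <- nchar(donor$seq)

    mosaic_rows <- list()
    out <- list()
    for (cv in cvs) {
      for (chrom in cfg$chrom_names) {
        len <- cfg$chrom_len
        segs <- integer(0)
        while (sum(segs) < len)
          segs <- c(segs, max(1000L, as.integer(rexp(1, 1 / cfg$segment_len_mean))))
        ends <- pmin(cumsum(segs), len)
        starts <- c(0L, head(ends, -1))
        keep <- ends > starts
        starts <- starts[keep]; ends <- ends[keep]
        fid <- sample(cfg$n_founders, length(starts), replace = TRUE)
        pieces <- purrr::pmap_chr(
          list(starts, ends, fid),
          function(s, e, f) substring(fseq[[paste0("f", f, " ", chrom)]][1],
                                      s + 1, e))
        out[[paste(cv, chrom)]] <- paste(pieces, collapse = "")
        mosaic_rows[[length(mosaic_rows) + 1]] <- tibble(
          cultivar = cv, chrom = chrom, start = starts, end = ends,
          founder = paste0("f", fid))
      }
    }

    intro_truth <- list()
    if (!is.null(cfg$introgressions)) {
      for (i in seq_len(nrow(cfg$introgressions))) {
        row <- cfg$introgressions[i, ]
        targets <- intro_cultivars(row$cultivar)
        dseq <- donor$seq[donor$id == row$chrom]
        s <- row$start; e <- row$start + row$length
        for (cv in targets) {
          key <- paste(cv, row$chrom)
          out[[key]] <- splice_span(out[[key]], s, e, substring(dseq, s + 1, e))
        }
        intro_truth[[i]] <- tibble(cultivar = targets, chrom = row$chrom,
                                   start = s, end = e, donor_span = i)
      }
    }

    inv_truth <- list()
    if (!is.null(cfg$inversions)) {
      for (i in seq_len(nrow(cfg$inversions))) {
        row <- cfg$inversions[i, ]
        for (cv in intro_cultivars(row$cultivar)) {
          key <- paste(cv, row$chrom)
          s <- row$start; e <- row$start + row$length
          out[[key]] <- splice_span(out[[key]], s, e,
                                    reverse_complement(substring(out[[key]], s + 1, e)))
          inv_truth[[length(inv_truth) + 1]] <-
            tibble(cultivar = cv, chrom = row$chrom, start = s, end = e)
        }
      }
    }

    trans_truth <- NULL
    if (!is.null(cfg$translocation)) {
      tr <- cfg$translocation
      src_key <- paste(tr$cultivar, tr$src_chrom)
      dst_key <- paste(tr$cultivar, tr$dest_chrom)
      seg <- substring(out[[src_key]], tr$src_start + 1, tr$src_end)
      out[[src_key]] <- paste0(substring(out[[src_key]], 1, tr$src_start),
                               substring(out[[src_key]], tr$src_end + 1,
                                         nchar(out[[src_key]])))
      out[[dst_key]] <- splice_span(out[[dst_key]], tr$dest_pos, tr$dest_pos + 1,
                                    paste0(substring(out[[dst_key]], tr$dest_pos + 1,
                                                     tr$dest_pos + 1), seg))
      trans_truth <- tibble(cultivar = tr$cultivar, src_chrom = tr$src_chrom,
                            src_start = tr$src_start, src_end = tr$src_end,
                            dest_chrom = tr$dest_chrom, dest_pos = tr$dest_pos)
    }

    grid <- tidyr::expand_grid(cultivar = cvs, chrom = cfg$chrom_names)
    cultivars <- grid %>%
      mutate(seq = purrr::map2_chr(.data$cultivar, .data$chrom,
                                   function(cv, ch) out[[paste(cv, ch)]]))
    list(cultivars = cultivars, donor = donor,
         truth = list(mosaic = bind_rows(mosaic_rows),
                      introgressions = if (length(intro_truth))
                        bind_rows(intro_truth) else NULL,
                      inversions = if (length(inv_truth))
                        bind_rows(inv_truth) else NULL,
                      translocation = trans_truth))
  })
}

#' Simulate a full synthetic panel
#'
#' Convenience wrapper: [simulate_founders()] then [compose_cultivars()].
#'
#' @param cfg A [panel_config()].
#' @return List with `base`, `founders`, `te_intervals`, `cultivars`,
#'   `donor`, `truth`.
#' @export
simulate_panel <- function(cfg) {
  fd <- simulate_founders(cfg)
  cc <- compose_cultivars(fd, cfg)
  c(fd, cc)
}

#' Fragment a chromosome into shuffled, randomly oriented scaffolds
#'
#' Cuts the chromosome at random breakpoints (exponential piece lengths,
#' mean `scaffold_len_mean`), shuffles the pieces and reverse-complements
#' each with probability 0.5 — the input state of reference-guided
#' pseudomolecule anchoring. The truth layout records source span,
#' orientation and true rank of every scaffold.
#'
#' @param seq A single chromosome sequence.
#' @param cfg A [panel_config()].
#' @param chrom Chromosome name recorded in the truth.
#' @param n_pieces Optional fixed number of pieces (overrides exponential
#'   cutting with even-ish random cuts).
#' @param min_piece Minimum piece length in bases (default 5000).
#' @return List with `scaffolds` (tibble `id`, `seq`, `length`) and
#'   `truth` (tibble `scaffold`, `source_chrom`, `source_start`,
#'   `source_end`, `orientation`, `rank`).
#' @export
fragment_assembly <- function(seq, cfg, chrom = "chr1", n_pieces = NULL,
                              min_piece = 5000) {
  withr::with_seed(cfg$seed + 2L, {
    len <- nchar(seq)
    if (is.null(n_pieces)) {
      cuts <- integer(0)
      pos <- 0
      repeat {
        pos <- pos + max(min_piece,
                         as.integer(rexp(1, 1 / cfg$scaffold_len_mean)))
        if (pos >= len) break
        cuts <- c(cuts, pos)
      }
      if (length(cuts) > 0 && len - cuts[length(cuts)] < min_piece)
        cuts <- cuts[-length(cuts)]
    } else if (n_pieces <= 1) {
      cuts <- integer(0)
    } else {
      if (n_pieces * min_piece > len)
        abort("cannot cut into n_pieces pieces of at least min_piece bases")
      # random piece lengths with a guaranteed floor: min_piece plus an
      # exponential share of the remainder
      raw <- rexp(n_pieces)
      extra <- floor(raw / sum(raw) * (len - n_pieces * min_piece))
      lens_p <- min_piece + extra
      lens_p[n_pieces] <- lens_p[n_pieces] + (len - sum(lens_p))
      cuts <- cumsum(lens_p[-n_pieces])
    }
    starts <- c(0L, cuts)
    ends <- c(cuts, len)
    n <- length(starts)
    ord <- sample(n)
    flip <- runif(n) < 0.5
    truth <- tibble(
      scaffold = sprintf("scaf%03d", seq_len(n)),
      source_chrom = chrom,
      source_start = starts[ord], source_end = ends[ord],
      orientation = ifelse(flip[ord], "-", "+"))
    truth$rank <- rank(truth$source_start)  # true left-to-right order
    seqs <- vapply(seq_len(n), function(i) {
      s <- substring(seq, truth$source_start[i] + 1, truth$source_end[i])
      if (truth$orientation[i] == "-") reverse_complement(s) else s
    }, character(1))
    list(scaffolds = tibble(id = truth$scaffold, seq = seqs,
                            length = nchar(seqs)),
         truth = truth)
  })
}

#' Simulate donor-read alignment intervals
#'
#' Places read intervals of `read_len` bases uniformly at rate
#' `depth_in / read_len` per base inside the introgressed spans and
#' `depth_bg / read_len` elsewhere (Poisson counts), emulating the coverage
#' track obtained by aligning donor-species short reads to a cultivar
#' chromosome. Each read carries a `mapq` (a configured fraction falls
#' below 10) and a proper-pair flag.
#'
#' @param spans Tibble of introgressed spans (`chrom`, `start`, `end`);
#'   may be NULL/empty.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param depth_in,depth_bg Mean depth inside / outside spans.
#' @param read_len Read length in bases.
#' @param low_mapq_frac Fraction of reads drawn with mapq < 10.
#' @param improper_frac Fraction of reads not flagged as proper pairs.
#' @param seed Integer seed.
#' @return Tibble `chrom`, `start`, `end`, `mapq`, `proper_pair`.
#' @export
simulate_donor_alignments <- function(spans, chrom_lengths,
                                      depth_in, depth_bg, read_len = 150,
                                      low_mapq_frac = 0.1,
                                      improper_frac = 0.05, seed = 1L) {
  stopifnot(depth_in >= 0, depth_bg >= 0)
  withr::with_seed(as.integer(seed), {
    out <- list()
    for (chrom in names(chrom_lengths)) {
      len <- chrom_lengths[[chrom]]
      sp <- if (is.null(spans)) NULL else spans[spans$chrom == chrom, ]
      regions <- tibble(start = 0, end = len, depth = depth_bg)
      if (!is.null(sp) && nrow(sp) > 0) {
        sp <- sp[order(sp$start), ]
        bounds <- sort(unique(c(0, sp$start, sp$end, len)))
        regions <- tibble(start = head(bounds, -1), end = tail(bounds, -1))
        regions$depth <- ifelse(
          purrr::map_lgl(regions$start,
                         function(s) any(s >= sp$start & s < sp$end)),
          depth_in, depth_bg)
      }
      for (i in seq_len(nrow(regions))) {
        rl <- regions$end[i] - regions$start[i]
        if (rl < read_len || regions$depth[i] <= 0) next
        n_reads <- rpois(1, rl * regions$depth[i] / read_len)
        if (n_reads == 0) next
        starts <- floor(runif(n_reads, regions$start[i],
                              regions$end[i] - read_len))
        out[[length(out) + 1]] <- tibble(
          chrom = chrom, start = starts, end = starts + read_len,
          mapq = ifelse(runif(n_reads) < low_mapq_frac,
                        sample(0:9, n_reads, replace = TRUE), 60L),
          proper_pair = runif(n_reads) >= improper_frac)
      }
    }
    if (length(out) == 0)
      return(tibble(chrom = character(), start = numeric(),
                    end = numeric(), mapq = integer(),
                    proper_pair = logical()))
    bind_rows(out) %>% arrange(.data$chrom, .data$start)
  })
}

#' Sample an exon set and derive a target genome with planted losses
#'
#' Samples N-free exons from the genome, then derives a modified copy of
#' the genome in which a deterministic count (`round(n_exons *
#' del_fraction)`) of exon loci is overwritten with random sequence
#' ("deleted") and `round(n_exons * mut_fraction)` loci are mutated well
#' below the 95 % identity threshold. The ledger records the class of every
#' exon, giving an exact expected conservation rate.
#'
#' @param genome Sequence tibble (`id`, `seq`).
#' @param n_exons Number of exons to sample.
#' @param del_fraction Fraction of exons whose target locus is deleted.
#' @param mut_fraction Fraction of exons whose target locus is heavily
#'   mutated (12 % substitutions).
#' @param exon_len_range Exon length range (bases, min 31).
#' @param avoid Optional tibble of intervals (`chrom`, `start`, `end`)
#'   exons must not overlap — typically the planted repeat bodies, so
#'   that a deleted exon locus cannot be rescued by a paralogous repeat
#'   copy.
#' @param seed Integer seed.
#' @return List with `exons` (tibble `id`, `chrom`, `start`, `end`, `seq`,
#'   `class`), `target` (modified genome tibble), `ledger` (id + class).
#' @export
emit_exon_set <- function(genome, n_exons, del_fraction = 0,
                          mut_fraction = 0, exon_len_range = c(60, 300),
                          avoid = NULL, seed = 1L) {
  stopifnot(exon_len_range[1] >= 31)
  withr::with_seed(as.integer(seed), {
    rows <- list()
    tries <- 0
    while (length(rows) < n_exons && tries < n_exons * 50) {
      tries <- tries + 1
      gi <- sample(nrow(genome), 1)
      len <- sample(seq(exon_len_range[1], exon_len_range[2]), 1)
      maxs <- nchar(genome$seq[gi]) - len
      if (maxs < 1) next
      s <- sample(maxs, 1)
      sq <- substring(genome$seq[gi], s + 1, s + len)
      if (grepl("N", sq, fixed = TRUE)) next
      if (!is.null(avoid)) {
        av <- avoid[avoid$chrom == genome$id[gi], ]
        if (any(s < av$end & s + len > av$start)) next
      }
      # non-overlapping loci keep the planted classes independent
      clash <- any(vapply(rows, function(r)
        r$chrom == genome$id[gi] && s < r$end && s + len > r$start,
        logical(1)))
      if (clash) next
      rows[[length(rows) + 1]] <- list(chrom = genome$id[gi],
                                       start = s, end = s + len, seq = sq)
    }
    if (length(rows) < n_exons)
      abort("could not place the requested number of exons")
    exons <- bind_rows(lapply(seq_along(rows), function(i)
      tibble(id = sprintf("exon%04d", i), chrom = rows[[i]]$chrom,
             start = rows[[i]]$start, end = rows[[i]]$end,
             seq = rows[[i]]$seq)))
    n_del <- round(n_exons * del_fraction)
    n_mut <- round(n_exons * mut_fraction)
    cls <- rep("conserved", n_exons)
    pick <- sample(n_exons, n_del + n_mut)
    cls[pick[seq_len(n_del)]] <- "deleted"
    if (n_mut > 0) cls[pick[n_del + seq_len(n_mut)]] <- "mutated"
    exons$class <- cls
    target <- genome
    for (i in seq_len(n_exons)) {
      if (cls[i] == "conserved") next
      gi <- which(target$id == exons$chrom[i])
      repl <- if (cls[i] == "deleted") {
        random_dna(exons$end[i] - exons$start[i])
      } else {
        mutate_seq(exons$seq[i], 0.12)
      }
      target$seq[gi] <- splice_span(target$seq[gi], exons$start[i],
                                    exons$end[i], repl)
    }
    target$length <- nchar(target$seq)
    list(exons = exons, target = target,
         ledger = exons[, c("id", "class")])
  })
}

#' True k-mer sharing profiles of a panel on a marker grid
#'
#' For each cultivar and marker offset, computes the profile the painting
#' stage should recover from the planted truth: the set of cultivars whose
#' sequence is identical over the marker span (same founder segment, or the
#' same planted donor span). Assignment uses the marker midpoint.
#'
#' @param truth Truth list from [compose_cultivars()].
#' @param cfg The [panel_config()] used.
#' @param spacing Marker grid spacing (bases).
#' @param marker_len Marker length (bases).
#' @return Tibble `cultivar`, `chrom`, `start`, `profile` (bit string over
#'   cultivars in panel order), `popcount`.
#' @export
truth_sharing_profiles <- function(truth, cfg, spacing = 20000,
                                   marker_len = 1000) {
  cvs <- cultivar_names(cfg)
  mos <- truth$mosaic
  intro <- truth$introgressions
  rows <- list()
  for (chrom in cfg$chrom_names) {
    starts <- seq(0, cfg$chrom_len - marker_len, by = spacing)
    mids <- starts + marker_len / 2
    m <- mos[mos$chrom == chrom, ]
    owner <- matrix("", nrow = length(mids), ncol = length(cvs),
                    dimnames = list(NULL, cvs))
    for (cv in cvs) {
      mc <- m[m$cultivar == cv, ]
      idx <- findInterval(mids, mc$start)
      owner[, cv] <- mc$founder[idx]
      if (!is.null(intro)) {
        ic <- intro[intro$cultivar == cv & intro$chrom == chrom, ]
        if (nrow(ic) > 0) {
          for (j in seq_len(nrow(ic))) {
            hit <- mids >= ic$start[j] & mids < ic$end[j]
            owner[hit, cv] <- paste0("donor", ic$donor_span[j])
          }
        }
      }
    }
    for (cv in cvs) {
      share <- owner == owner[, cv]
      bits <- apply(share, 1, function(r) paste(as.integer(r), collapse = ""))
      rows[[length(rows) + 1]] <- tibble(
        cultivar = cv, chrom = chrom, start = starts, profile = bits,
        popcount = rowSums(share))
    }
  }
  bind_rows(rows)
}
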