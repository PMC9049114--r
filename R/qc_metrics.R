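#' QC configuration
#'
#' Thresholds and constants for assembly quality assessment: exon
#' conservation at 95 % identity over 95 % of the query, exons at least
#' 31 bp and N-free, the plant telomeric repeat `TTTAGGG`, and NG
#' statistics computed against an assumed genome size (15 Gb for
#' hexaploid wheat).
#'
#' @param genome_size_g Assumed genome size G for NGxx statistics.
#' @param exon_min_identity,exon_min_coverage Exon conservation
#'   thresholds.
#' @param exon_min_len Minimum exon length (bases).
#' @param telomere_motif Telomeric repeat motif.
#' @param telomere_min_copies Minimum tandem copies to report an array.
#' @param telomere_end_window Window at each chromosome end to scan.
#' @param telomere_max_mismatch Mismatches tolerated per motif copy.
#' @param kmer_k K-mer size for consensus-QV estimation.
#' @return A `qc_config` list.
#' @export
qc_config <- function(genome_size_g = 15e9, exon_min_identity = 0.95,
                      exon_min_coverage = 0.95, exon_min_len = 31,
                      telomere_motif = "TTTAGGG",
                      telomere_min_copies = 10,
                      telomere_end_window = 10000,
                      telomere_max_mismatch = 1,
                      kmer_k = 21) {
  stopifnot(exon_min_identity > 0, exon_min_identity <= 1,
            exon_min_coverage > 0, exon_min_coverage <= 1,
            nchar(telomere_motif) > 0)
  structure(list(genome_size_g = genome_size_g,
                 exon_min_identity = exon_min_identity,
                 exon_min_coverage = exon_min_coverage,
                 exon_min_len = as.integer(exon_min_len),
                 telomere_motif = telomere_motif,
                 telomere_min_copies = as.integer(telomere_min_copies),
                 telomere_end_window = as.integer(telomere_end_window),
                 telomere_max_mismatch = as.integer(telomere_max_mismatch),
                 kmer_k = as.integer(kmer_k)),
            class = "qc_config")
}

nxx_walk <- function(lens_sorted, threshold) {
  cum <- cumsum(lens_sorted)
  i <- which(cum >= threshold)[1]
  if (is.na(i)) return(list(n = NA_real_, l = NA_integer_))
  list(n = lens_sorted[i], l = i)
}

#' Assembly contiguity statistics
#'
#' Nxx is the length of the sequence at which the cumulative
#' sorted-descending length first reaches xx % of the assembly total; Lxx
#' is its rank. NGxx uses xx % of an assumed genome size G instead and is
#' `NA` when the assembly never reaches that quantile.
#'
#' @param lengths Numeric vector of sequence lengths (or a sequence
#'   tibble with a `length` column).
#' @param cfg A [qc_config()] (supplies G).
#' @param n_bases Optional count of N bases for the `pct_n` field.
#' @return One-row tibble: `n_seqs`, `total_len`, `n50`, `l50`, `n90`,
#'   `l90`, `ng50`, `lg50`, `ng90`, `lg90`, `longest`, `pct_n`.
#' @export
assembly_stats <- function(lengths, cfg = qc_config(), n_bases = NA) {
  if (is.data.frame(lengths)) lengths <- lengths$length
  if (length(lengths) == 0) abort("no sequence lengths supplied")
  stopifnot(all(lengths > 0))
  lens <- sort(lengths, decreasing = TRUE)
  total <- sum(lens)
  g <- cfg$genome_size_g
  s50 <- nxx_walk(lens, 0.5 * total)
  s90 <- nxx_walk(lens, 0.9 * total)
  g50 <- nxx_walk(lens, 0.5 * g)
  g90 <- nxx_walk(lens, 0.9 * g)
  tibble(n_seqs = length(lens), total_len = total,
         n50 = s50$n, l50 = s50$l, n90 = s90$n, l90 = s90$l,
         ng50 = g50$n, lg50 = g50$l, ng90 = g90$n, lg90 = g90$l,
         longest = lens[1],
         pct_n = if (is.na(n_bases)) NA_real_ else 100 * n_bases / total)
}

#' Exon conservation report
#'
#' Searches each exon in the target with the same seed-and-extend engine
#' used for markers, generalized to variable query length. An exon is
#' conserved when its best hit reaches the identity/coverage thresholds
#' (default 95/95). The strictly-identical fraction counts exons with a
#' perfect full-length hit — and, when a chromosome map is supplied, on
#' the expected chromosome.
#'
#' @param exons Tibble `id`, `seq` (plus `chrom` if `same_chrom_map` is
#'   used). Exons shorter than `exon_min_len` or containing N are dropped
#'   (counted in the report).
#' @param target Sequence tibble.
#' @param cfg A [qc_config()].
#' @param same_chrom_map Optional named vector mapping exon source
#'   chromosomes to expected target chromosome ids.
#' @param map_cfg A [map_config()] controlling the search; thresholds are
#'   taken from `cfg`.
#' @return List with `conserved_fraction`, `identical_fraction`,
#'   `mean_hit_identity`, `n_dropped`, and `per_exon` tibble.
#' @export
exon_conservation <- function(exons, target, cfg = qc_config(),
                              same_chrom_map = NULL,
                              map_cfg = map_config()) {
  if (nrow(exons) == 0) abort("empty exon set")
  ok <- nchar(exons$seq) >= cfg$exon_min_len &
    !grepl("N", exons$seq, fixed = TRUE)
  n_dropped <- sum(!ok)
  exons <- exons[ok, ]
  if (nrow(exons) == 0) abort("no exon passes the length/N filters")
  search_cfg <- map_cfg
  search_cfg$min_identity <- cfg$exon_min_identity
  search_cfg$min_coverage <- cfg$exon_min_coverage
  search_cfg$max_mismatches <- NULL
  hits <- map_markers(exons[, c("id", "seq")], target, search_cfg)
  tab <- exons %>%
    left_join(hits, by = c(id = "marker_id")) %>%
    mutate(conserved = !is.na(.data$identity),
           identical = !is.na(.data$identity) & .data$identity == 1 &
             .data$query_coverage == 1)
  if (!is.null(same_chrom_map) && "chrom" %in% names(exons))
    tab <- tab %>%
      mutate(identical = .data$identical & !is.na(.data$target_chrom) &
               .data$target_chrom == same_chrom_map[.data$chrom])
  list(conserved_fraction = mean(tab$conserved),
       identical_fraction = mean(tab$identical),
       mean_hit_identity = mean(tab$identity[tab$conserved]),
       n_dropped = n_dropped,
       per_exon = tab)
}

# maximal tandem chain of motif copies (<= max_mm mismatches per copy)
# in seq, scanning from a given set of anchor positions
tandem_copies <- function(window, motif, max_mm) {
  ml <- nchar(motif)
  n <- nchar(window)
  if (n < ml) return(0L)
  starts <- seq(1, n - ml + 1)
  copy_ok <- vapply(starts, function(s) {
    sum(charToRaw(substring(window, s, s + ml - 1)) !=
          charToRaw(motif)) <= max_mm
  }, logical(1))
  best <- 0L
  s <- 1L
  while (s <= length(starts)) {
    if (copy_ok[s]) {
      run <- 1L
      p <- s
      while (p + ml <= length(starts) && copy_ok[p + ml]) {
        run <- run + 1L
        p <- p + ml
      }
      best <- max(best, run)
      s <- s + 1L
    } else s <- s + 1L
  }
  best
}

#' Detect telomeric repeat arrays at chromosome ends
#'
#' Scans a window at each end of every chromosome for maximal tandem
#' arrays of the telomere motif, in both orientations (the forward motif
#' is expected at the 5' end, its reverse complement — `CCCTAAA` for the
#' plant motif — at the 3' end, but both are scanned at both ends).
#' Individual copies may carry up to `telomere_max_mismatch` mismatches,
#' since natural arrays are imperfect. A chromosome is telomere-complete
#' when both ends report an array of at least `telomere_min_copies`.
#'
#' @param genome Sequence tibble (`id`, `seq`).
#' @param cfg A [qc_config()].
#' @return Tibble `chrom`, `end` (`5prime`/`3prime`), `copies`,
#'   `has_array`, plus `telomere_complete` per chromosome.
#' @export
find_telomere_arrays <- function(genome, cfg = qc_config()) {
  motif_f <- cfg$telomere_motif
  motif_r <- reverse_complement(motif_f)
  w <- cfg$telomere_end_window
  rows <- purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    s <- genome$seq[i]
    n <- nchar(s)
    win5 <- substring(s, 1, min(w, n))
    win3 <- substring(s, max(1, n - w + 1), n)
    c5 <- max(tandem_copies(win5, motif_f, cfg$telomere_max_mismatch),
              tandem_copies(win5, motif_r, cfg$telomere_max_mismatch))
    c3 <- max(tandem_copies(win3, motif_f, cfg$telomere_max_mismatch),
              tandem_copies(win3, motif_r, cfg$telomere_max_mismatch))
    tibble(chrom = genome$id[i], end = c("5prime", "3prime"),
           copies = c(c5, c3))
  })
  rows %>%
    mutate(has_array = .data$copies >= cfg$telomere_min_copies) %>%
    group_by(.data$chrom) %>%
    mutate(telomere_complete = all(.data$has_array)) %>%
    ungroup()
}

#' Convert between Phred consensus QV, error rate and error spacing
#'
#' `error_rate = 10^(-qv/10)`; the spacing is `1 / error_rate` bases
#' (e.g. QV 35.9 is one error every ~3.9 kb, QV 30 exactly one error per
#' 1000 bp). Unrounded values are returned; display rounding is the
#' caller's business.
#'
#' @param qv Phred-scaled quality value.
#' @return `qv_to_error_rate`: errors per base. `qv_to_spacing`: bases
#'   per error. `error_rate_to_qv`: the QV.
#' @export
qv_to_error_rate <- function(qv) {
  stopifnot(all(qv > 0))
  10^(-qv / 10)
}

#' @rdname qv_to_error_rate
#' @export
qv_to_spacing <- function(qv) 1 / qv_to_error_rate(qv)

#' @rdname qv_to_error_rate
#' @param error_rate Errors per base, in (0, 1).
#' @export
error_rate_to_qv <- function(error_rate) {
  stopifnot(all(error_rate > 0), all(error_rate < 1))
  -10 * log10(error_rate)
}

#' K-mer based consensus quality value
#'
#' Re-implementation of the published k-mer survey formula for consensus
#' accuracy: with `b` of `t` assembly k-mers absent from a trusted read
#' k-mer set, the per-base error estimate solves
#' `1 - (1 - E)^k = b / t`, and `QV = -10 log10(E)`. With no absent
#' k-mers the QV is reported as the declared cap.
#'
#' @param assembly Sequence tibble (or character vector) of assembly
#'   sequences.
#' @param trusted Sequence tibble/character vector of trusted sequence
#'   (read set), or a k-mer set built by [kmer_set()].
#' @param k K-mer size (default from [qc_config()]).
#' @param cap QV reported when no assembly k-mer is absent (default 99).
#' @return List with `qv`, `error_rate`, `t`, `b`.
#' @export
kmer_qv <- function(assembly, trusted, k = 21, cap = 99) {
  seqs <- if (is.data.frame(assembly)) assembly$seq else assembly
  set <- if (inherits(trusted, "kmer_set")) trusted else kmer_set(trusted, k)
  if (set$k != k) abort("k mismatch between assembly and trusted set")
  res <- cpp_count_absent(seqs, set$ptr, k)
  t <- res[["t"]]
  b <- res[["b"]]
  if (t == 0) abort("assembly has no valid k-mer")
  if (b == 0)
    return(list(qv = cap, error_rate = 10^(-cap / 10), t = t, b = 0))
  e <- 1 - (1 - b / t)^(1 / k)
  list(qv = -10 * log10(e), error_rate = e, t = t, b = b)
}

#' Build a canonical k-mer set
#'
#' @param x Sequence tibble or character vector.
#' @param k K-mer size.
#' @return A `kmer_set` (in-memory, canonical, unique).
#' @export
kmer_set <- function(x, k = 21) {
  seqs <- if (is.data.frame(x)) x$seq else x
  ptr <- cpp_kmer_set(seqs, k)
  structure(list(ptr = ptr, k = as.integer(k),
                 n_kmers = cpp_kmer_set_size(ptr)),
            class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat("<kmer_set> k=", x$k, ", ", format(x$n_kmers, big.mark = ","),
      " canonical k-mers\n", sep = "")
  invisible(x)
}
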