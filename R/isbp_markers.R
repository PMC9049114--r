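#' Marker-mapping configuration
#'
#' Holds identity/coverage thresholds and search parameters for the
#' seed-and-extend marker search. Presets mirror the threshold sets used at
#' the different pipeline stages:
#'
#' * `"anchor"` — at least 80 % identity over at least 90 % of the query
#'   (scaffold anchoring),
#' * `"validate"` — at least 90 % identity over 90 % of the query (marker
#'   conservation),
#' * `"exon"` — at least 95 % identity over 95 % of the query (exon
#'   conservation),
#' * `"dotplot"` — at most 2 mismatches at 100 % query coverage (strict
#'   anchor tables for dot plots).
#'
#' @param min_identity Minimum alignment identity (fraction of aligned
#'   columns that match).
#' @param min_coverage Minimum fraction of the query aligned.
#' @param seed_len Exact seed length for the search (default 21).
#' @param max_mismatches Optional hard cap on mismatches (used by the
#'   `dotplot` preset).
#' @param min_second_best_gap A best hit is flagged non-unique when a
#'   second passing hit lies within this many edit-distance units.
#' @param band Band half-width of the banded global alignment that verifies
#'   candidate loci.
#' @param preset Optional preset name (overrides the threshold arguments).
#' @return A `map_config` list.
#' @export
map_config <- function(min_identity = 0.90, min_coverage = 0.90,
                       seed_len = 21, max_mismatches = NULL,
                       min_second_best_gap = 5, band = 15,
                       preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("anchor", "validate", "exon", "dotplot"))
    vals <- switch(preset,
      anchor   = list(0.80, 0.90, NULL),
      validate = list(0.90, 0.90, NULL),
      exon     = list(0.95, 0.95, NULL),
      dotplot  = list(0.00, 1.00, 2L))
    min_identity <- vals[[1]]
    min_coverage <- vals[[2]]
    max_mismatches <- vals[[3]]
  }
  stopifnot(min_identity >= 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1, seed_len >= 4)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 seed_len = as.integer(seed_len),
                 max_mismatches = max_mismatches,
                 min_second_best_gap = min_second_best_gap,
                 band = as.integer(band)),
            class = "map_config")
}

#' Design ISBP junction markers from TE annotations
#'
#' For every transposable-element interval, emits one 2x`flank`-bp tag
#' centred on each of its two junctions (element start and element end),
#' i.e. `flank` bases on each side of the junction. Markers that would
#' overlap a chromosome end or that contain `N` are dropped. Junctions
#' between a TE body (multi-copy) and its insertion site (single-copy) are
#' effectively unique sequences even in repeat-rich genomes, which is what
#' makes these tags genome-wide mappable markers.
#'
#' @param genome Sequence tibble (`id`, `seq`).
#' @param te_intervals Tibble `chrom`, `start`, `end` (0-based half-open),
#'   sorted, within chromosome bounds.
#' @param flank Bases on each side of the junction (default 75, giving
#'   150-bp markers).
#' @return Tibble `id`, `chrom`, `junction_pos`, `side` (`5prime` at the
#'   element start, `3prime` at the end), `start`, `end`, `seq`.
#' @export
design_isbp <- function(genome, te_intervals, flank = 75) {
  if (flank <= 0) abort("flank must be positive")
  seqs <- setNames(genome$seq, genome$id)
  lens <- setNames(nchar(genome$seq), genome$id)
  if (!all(te_intervals$chrom %in% names(seqs)))
    abort("te_intervals reference chromosomes absent from genome")
  cand <- bind_rows(
    te_intervals %>% mutate(junction_pos = .data$start, side = "5prime"),
    te_intervals %>% mutate(junction_pos = .data$end, side = "3prime")) %>%
    mutate(mstart = .data$junction_pos - flank,
           mend = .data$junction_pos + flank) %>%
    filter(.data$mstart >= 0, .data$mend <= lens[.data$chrom])
  cand$seq <- unname(substring(seqs[cand$chrom], cand$mstart + 1,
                               cand$mend))
  cand <- cand[!grepl("N", cand$seq, fixed = TRUE), ]
  cand %>%
    mutate(id = paste0(.data$chrom, ":", .data$junction_pos, ":",
                       .data$side)) %>%
    select("id", "chrom", "junction_pos", "side",
           start = "mstart", end = "mend", "seq") %>%
    arrange(.data$chrom, .data$start, .data$side) %>%
    distinct(.data$id, .keep_all = TRUE)
}

# Collapse near-identical placements (same query/target/strand within the
# alignment band) to the best one, so one physical locus yields one hit.
dedupe_hits <- function(hits, band) {
  hits %>%
    arrange(.data$query, .data$target, .data$strand, .data$start,
            .data$dist) %>%
    group_by(.data$query, .data$target, .data$strand) %>%
    mutate(locus = cumsum(c(1, diff(.data$start) > band))) %>%
    group_by(.data$query, .data$target, .data$strand, .data$locus) %>%
    arrange(.data$dist, .data$start, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select(-"locus")
}

#' Map markers to a target genome
#'
#' Seed-and-extend search on both strands: exact `seed_len`-mer seeds
#' locate candidate loci, each verified by a banded edit-distance alignment
#' of the full query. Hits below the identity/coverage thresholds are
#' discarded. By default the best hit per marker is reported, flagged
#' non-unique when a second passing locus lies within
#' `min_second_best_gap` edits of the best.
#'
#' @param markers Tibble with `id` and `seq` (any query length >=
#'   `seed_len`).
#' @param target Sequence tibble (`id`, `seq`).
#' @param cfg A [map_config()].
#' @param all_hits If TRUE, return every passing placement instead of the
#'   best per marker.
#' @return Tibble `marker_id`, `target_chrom`, `target_start` (0-based),
#'   `strand`, `identity`, `query_coverage`, `mismatches`, `is_unique`
#'   (best-hit mode only).
#' @export
map_markers <- function(markers, target, cfg = map_config(),
                        all_hits = FALSE) {
  stopifnot(inherits(cfg, "map_config"))
  qlen <- nchar(markers$seq)
  if (cfg$seed_len > min(qlen))
    abort("seed_len exceeds the shortest query")
  max_edit <- if (!is.null(cfg$max_mismatches)) {
    rep(as.integer(cfg$max_mismatches), length(qlen))
  } else {
    as.integer(floor((1 - cfg$min_identity) * qlen))
  }
  raw <- cpp_map_queries(markers$seq, target$seq, cfg$seed_len,
                         max_edit, cfg$band)
  empty <- tibble(marker_id = character(), target_chrom = character(),
                  target_start = numeric(), strand = character(),
                  identity = numeric(), query_coverage = numeric(),
                  mismatches = integer(), is_unique = logical())
  if (nrow(raw) == 0) return(empty)
  hits <- as_tibble(raw) %>%
    dedupe_hits(cfg$band) %>%
    mutate(qlen = qlen[.data$query],
           aligned = .data$qlen - .data$clip,
           mismatches = .data$dist - .data$clip,
           identity = (.data$aligned - .data$mismatches) / .data$aligned,
           query_coverage = .data$aligned / .data$qlen) %>%
    filter(.data$identity >= cfg$min_identity,
           .data$query_coverage >= cfg$min_coverage)
  if (!is.null(cfg$max_mismatches))
    hits <- filter(hits, .data$mismatches <= cfg$max_mismatches)
  if (nrow(hits) == 0) return(empty)
  hits$marker_id <- markers$id[hits$query]
  hits$target_chrom <- target$id[hits$target]
  hits$strand <- ifelse(hits$strand > 0, "+", "-")
  if (all_hits) {
    return(hits %>%
             select("marker_id", "target_chrom", target_start = "start",
                    "strand", "identity", "query_coverage", "mismatches") %>%
             mutate(is_unique = NA))
  }
  hits %>%
    group_by(.data$query) %>%
    arrange(.data$dist, .data$target, .data$start, .by_group = TRUE) %>%
    mutate(second_gap = if (n() > 1) .data$dist[2] - .data$dist[1] else NA_integer_,
           is_unique = n() == 1 |
             (!is.na(.data$second_gap) &
                .data$second_gap > cfg$min_second_best_gap)) %>%
    slice(1) %>%
    ungroup() %>%
    select("marker_id", "target_chrom", target_start = "start", "strand",
           "identity", "query_coverage", "mismatches", "is_unique")
}

#' Keep only uniquely mappable markers
#'
#' A marker is unique iff exactly one placement in the genome it was
#' designed from passes the configured thresholds — its own source locus.
#' Markers with additional passing placements (e.g. tagged loci duplicated
#' verbatim elsewhere) are removed.
#'
#' @param markers Tibble from [design_isbp()].
#' @param genome The source genome the markers were designed from.
#' @param cfg A [map_config()].
#' @return The subset of `markers` that map uniquely, with `is_unique`
#'   set to TRUE.
#' @export
filter_unique <- function(markers, genome, cfg = map_config()) {
  hits <- map_markers(markers, genome, cfg, all_hits = TRUE)
  n_place <- hits %>% count(.data$marker_id)
  uniq <- n_place$marker_id[n_place$n == 1]
  markers %>%
    filter(.data$id %in% uniq) %>%
    mutate(is_unique = TRUE)
}

#' Marker conservation rate against a target assembly
#'
#' Fraction of markers with a passing hit in the target under the given
#' thresholds (default: at least 90 % identity over 90 % of the query
#' length). The per-marker table also flags the perfect-match subset
#' (identity 1 at full coverage), the quantity used to monitor consensus
#' polishing. `mode = "aligned_nt"` switches the conservation test to the
#' alternate criterion of at least `min_aligned_nt` aligned bases at the
#' identity threshold.
#'
#' @param markers Tibble with `id`, `seq`.
#' @param target Sequence tibble.
#' @param cfg A [map_config()] (defaults to the `validate` preset).
#' @param mode `"coverage"` (identity + coverage thresholds) or
#'   `"aligned_nt"` (identity over >= `min_aligned_nt` aligned bases).
#' @param min_aligned_nt Aligned-base floor for `mode = "aligned_nt"`.
#' @return List with `conserved_fraction`, `perfect_fraction`, and
#'   `per_marker` (tibble `id`, `conserved`, `perfect`, plus best-hit
#'   columns).
#' @export
conservation_rate <- function(markers, target,
                              cfg = map_config(preset = "validate"),
                              mode = c("coverage", "aligned_nt"),
                              min_aligned_nt = 145) {
  mode <- match.arg(mode)
  if (nrow(markers) == 0) abort("empty marker set")
  search_cfg <- cfg
  if (mode == "aligned_nt") search_cfg$min_coverage <- 0.5
  hits <- map_markers(markers, target, search_cfg)
  tab <- markers %>%
    select("id") %>%
    left_join(hits, by = c(id = "marker_id")) %>%
    mutate(qlen = nchar(markers$seq),
           aligned_nt = round(.data$query_coverage * .data$qlen),
           conserved = !is.na(.data$identity) &
             if (mode == "coverage") {
               .data$identity >= cfg$min_identity &
                 .data$query_coverage >= cfg$min_coverage
             } else {
               .data$identity >= cfg$min_identity &
                 .data$aligned_nt >= min_aligned_nt
             },
           perfect = !is.na(.data$identity) & .data$identity == 1 &
             .data$query_coverage == 1)
  list(conserved_fraction = mean(tab$conserved),
       perfect_fraction = mean(tab$perfect),
       per_marker = tab)
}
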