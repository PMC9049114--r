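#' Anchoring configuration
#'
#' Constants of collinearity-guided pseudomolecule construction: marker
#' pairs must be separated by less than `max_pair_gap` on both the
#' reference and the scaffold, a scaffold is assigned to a chromosome only
#' when at least `min_support` of its valid pairs agree on it, neighbour
#' scaffolds are joined by `gap_len` Ns, and scaffolds shorter than
#' `min_scaffold_len` stay unplaced.
#'
#' @param max_pair_gap Maximum marker-pair separation (bases) on either
#'   genome (default 50 kb).
#' @param min_support Minimum fraction of valid pairs on the assigned
#'   chromosome (default 0.5).
#' @param gap_len Length of the N join between neighbour scaffolds
#'   (default 100).
#' @param min_scaffold_len Minimum scaffold length to place (default
#'   30 kb).
#' @return An `anchor_config` list.
#' @export
anchor_config <- function(max_pair_gap = 50000, min_support = 0.5,
                          gap_len = 100, min_scaffold_len = 30000) {
  stopifnot(max_pair_gap > 0, min_support > 0, gap_len > 0,
            min_scaffold_len > 0)
  structure(list(max_pair_gap = max_pair_gap, min_support = min_support,
                 gap_len = as.integer(gap_len),
                 min_scaffold_len = min_scaffold_len),
            class = "anchor_config")
}

#' Pair adjacent marker hits on each scaffold
#'
#' Considers markers by consecutive pairs along each scaffold and emits a
#' pair only when the two hits are separated by less than `max_pair_gap`
#' on both the scaffold and the reference and their source junctions lie
#' on the same reference chromosome. Pairing filters out isolated
#' mis-mapped markers, which single hits cannot. The pair orientation is
#' `+` when reference order equals scaffold order (derived from marker
#' order, not marker strand, so it is robust to individually flipped
#' hits).
#'
#' @param hits Tibble from [map_markers()] against the scaffolds
#'   (`marker_id`, `target_chrom` = scaffold, `target_start`), sorted by
#'   `target_start` within each scaffold.
#' @param markers Marker table with reference coordinates (`id`, `chrom`,
#'   `junction_pos`).
#' @param cfg An [anchor_config()].
#' @return Tibble `scaffold`, `marker_a`, `marker_b`, `scaffold_gap`,
#'   `ref_chrom`, `ref_gap`, `ref_mid`, `pair_orientation`.
#' @export
pair_adjacent <- function(hits, markers, cfg = anchor_config()) {
  stopifnot(inherits(cfg, "anchor_config"))
  srt <- hits %>% group_by(.data$target_chrom) %>%
    summarise(ok = !is.unsorted(.data$target_start))
  if (!all(srt$ok))
    abort("hits must be sorted by position within each scaffold")
  ref <- markers %>% select("id", ref_chrom = "chrom",
                            ref_pos = "junction_pos")
  hits %>%
    left_join(ref, by = c(marker_id = "id")) %>%
    group_by(scaffold = .data$target_chrom) %>%
    mutate(marker_a = .data$marker_id, marker_b = lead(.data$marker_id),
           scaffold_gap = lead(.data$target_start) - .data$target_start,
           chrom_b = lead(.data$ref_chrom),
           ref_pos_b = lead(.data$ref_pos)) %>%
    ungroup() %>%
    filter(!is.na(.data$marker_b),
           .data$scaffold_gap < cfg$max_pair_gap,
           abs(.data$ref_pos_b - .data$ref_pos) < cfg$max_pair_gap,
           .data$ref_chrom == .data$chrom_b) %>%
    mutate(ref_gap = abs(.data$ref_pos_b - .data$ref_pos),
           ref_mid = (.data$ref_pos + .data$ref_pos_b) / 2,
           pair_orientation = ifelse(.data$ref_pos_b >= .data$ref_pos,
                                     "+", "-")) %>%
    select("scaffold", "marker_a", "marker_b", "scaffold_gap", "ref_chrom",
           "ref_gap", "ref_mid", "pair_orientation")
}

#' Assign scaffolds to chromosomes by valid-pair majority
#'
#' A scaffold is assigned to the chromosome holding the most valid pairs,
#' provided that chromosome carries at least `min_support` of all its
#' valid pairs *and* strictly exceeds every other chromosome's count;
#' otherwise the scaffold goes to `"chrUn"` (including exact 50/50 ties —
#' an ambiguous winner is no winner). Position is the median `ref_mid` of
#' the assigned pairs; orientation is the majority pair orientation (tie
#' defaults to `+`, keeping assembly orientation).
#'
#' @param pairs Tibble from [pair_adjacent()].
#' @param cfg An [anchor_config()].
#' @param scaffolds Optional character vector of all scaffold ids, so that
#'   scaffolds with zero valid pairs receive a `chrUn` row.
#' @return Tibble `scaffold`, `assigned_chrom`, `n_valid_pairs`,
#'   `n_pairs_on_assigned`, `support_fraction`, `median_ref_pos`,
#'   `orientation`, `votes_plus`, `votes_minus`.
#' @export
assign_chromosome <- function(pairs, cfg = anchor_config(),
                              scaffolds = NULL) {
  if (nrow(pairs) == 0) {
    per <- tibble(scaffold = character(), n_valid_pairs = integer(),
                  assigned_chrom = character(),
                  n_pairs_on_assigned = integer(),
                  median_ref_pos = numeric(), votes_plus = integer(),
                  votes_minus = integer(), orientation = character(),
                  support_fraction = numeric())
  } else {
  per <- pairs %>%
    group_by(.data$scaffold) %>%
    dplyr::group_modify(function(df, key) {
      cnt <- sort(table(df$ref_chrom), decreasing = TRUE)
      best <- names(cnt)[1]
      ok <- cnt[1] / nrow(df) >= cfg$min_support &&
        (length(cnt) == 1 || cnt[1] > cnt[2])
      on_best <- df$ref_chrom == best
      vp <- sum(df$pair_orientation[on_best] == "+")
      vm <- sum(df$pair_orientation[on_best] == "-")
      tibble(n_valid_pairs = nrow(df),
             assigned_chrom = if (ok) best else "chrUn",
             n_pairs_on_assigned = as.integer(cnt[1]),
             median_ref_pos = median(df$ref_mid[on_best]),
             votes_plus = vp, votes_minus = vm,
             orientation = if (vp >= vm) "+" else "-")
    }) %>%
    ungroup() %>%
    mutate(support_fraction = .data$n_pairs_on_assigned / .data$n_valid_pairs)
  }
  per <- per %>%
    mutate(n_pairs_on_assigned =
             ifelse(.data$assigned_chrom == "chrUn", NA_integer_,
                    .data$n_pairs_on_assigned),
           median_ref_pos = ifelse(.data$assigned_chrom == "chrUn",
                                   NA_real_, .data$median_ref_pos))
  if (!is.null(scaffolds)) {
    missing <- setdiff(scaffolds, per$scaffold)
    if (length(missing) > 0)
      per <- bind_rows(per, tibble(
        scaffold = missing, n_valid_pairs = 0L, assigned_chrom = "chrUn",
        n_pairs_on_assigned = NA_integer_, median_ref_pos = NA_real_,
        votes_plus = 0L, votes_minus = 0L, orientation = "+",
        support_fraction = NA_real_))
  }
  per %>% arrange(.data$scaffold) %>%
    select("scaffold", "assigned_chrom", "n_valid_pairs",
           "n_pairs_on_assigned", "support_fraction", "median_ref_pos",
           "orientation", "votes_plus", "votes_minus")
}

#' Order anchored scaffolds into a pseudomolecule layout
#'
#' Per chromosome, scaffolds are sorted by their median reference position;
#' ties break by descending scaffold length, then lexicographic id.
#' Unassigned scaffolds and scaffolds shorter than `min_scaffold_len` are
#' listed as unplaced.
#'
#' @param anchors Tibble from [assign_chromosome()].
#' @param scaffold_lengths Named vector of scaffold lengths.
#' @param cfg An [anchor_config()].
#' @return A `pseudo_layout`: list with `chroms` (named list of tibbles
#'   `scaffold`, `orientation`, in order), `unplaced`, `gap_len`.
#' @export
order_scaffolds <- function(anchors, scaffold_lengths,
                            cfg = anchor_config()) {
  if (anyDuplicated(anchors$scaffold))
    abort("duplicate scaffold ids in anchors")
  anchors <- anchors %>%
    mutate(len = unname(scaffold_lengths[.data$scaffold]))
  placed <- anchors %>%
    filter(.data$assigned_chrom != "chrUn",
           .data$len >= cfg$min_scaffold_len) %>%
    arrange(.data$assigned_chrom, .data$median_ref_pos, desc(.data$len),
            .data$scaffold)
  chroms <- lapply(split(placed, placed$assigned_chrom), function(df)
    tibble(scaffold = df$scaffold, orientation = df$orientation))
  unplaced <- setdiff(anchors$scaffold, placed$scaffold)
  structure(list(chroms = chroms, unplaced = unplaced,
                 gap_len = cfg$gap_len),
            class = "pseudo_layout")
}

#' @export
print.pseudo_layout <- function(x, ...) {
  cat("<pseudo_layout> ", length(x$chroms), " chromosome(s), ",
      sum(vapply(x$chroms, nrow, integer(1))), " placed scaffold(s), ",
      length(x$unplaced), " unplaced\n", sep = "")
  invisible(x)
}

#' Build pseudomolecule sequences from a layout
#'
#' Concatenates oriented scaffolds (minus-orientation scaffolds are
#' reverse-complemented) joined by runs of exactly `gap_len` Ns. The
#' resulting length is the sum of scaffold lengths plus
#' `gap_len * (n - 1)` per chromosome.
#'
#' @param layout A `pseudo_layout` from [order_scaffolds()].
#' @param scaffolds Sequence tibble (`id`, `seq`) holding every placed
#'   scaffold.
#' @return Sequence tibble of pseudomolecules (`id`, `seq`, `length`).
#' @export
build_pseudomolecule <- function(layout, scaffolds) {
  stopifnot(inherits(layout, "pseudo_layout"))
  seqs <- setNames(scaffolds$seq, scaffolds$id)
  gap <- strrep("N", layout$gap_len)
  out <- purrr::imap(layout$chroms, function(df, chrom) {
    missing <- setdiff(df$scaffold, names(seqs))
    if (length(missing) > 0)
      abort(paste0("missing sequence for scaffold ", missing[1]))
    pieces <- purrr::map2_chr(df$scaffold, df$orientation, function(sc, o) {
      if (o == "-") reverse_complement(seqs[[sc]]) else seqs[[sc]]
    })
    paste(pieces, collapse = gap)
  })
  tibble(id = names(out), seq = unname(unlist(out)),
         length = unname(nchar(unlist(out))))
}

#' Snap a break coordinate to the nearest scaffold gap
#'
#' When a chimeric scaffold must be split, the break is recalculated to
#' the internal gap whose midpoint is nearest the proposed coordinate
#' (equidistant gaps resolve to the lower coordinate); splitting at a gap
#' removes the gap bases from both fragments.
#'
#' @param gaps Tibble of internal gap intervals (`start`, `end`, 0-based
#'   half-open) of one scaffold.
#' @param break_coord Proposed break coordinate (bases).
#' @return The chosen gap as a one-row tibble.
#' @export
snap_break_to_gap <- function(gaps, break_coord) {
  if (is.null(gaps) || nrow(gaps) == 0)
    abort("scaffold has no internal gap; split at the coordinate and warn")
  mids <- (gaps$start + gaps$end) / 2
  d <- abs(mids - break_coord)
  gaps[order(d, gaps$start), ][1, ]
}
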