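#' Read a FASTA file into a sequence tibble
#'
#' Sequences travel through the package as a tibble with one row per record
#' (columns `id`, `seq`, `length`). Input is uppercased on read and the
#' alphabet is restricted to `A`, `C`, `G`, `T`, `N`: IUPAC ambiguity codes
#' other than `N` are rejected so that every sequence is 2-bit codable for
#' the k-mer machinery.
#'
#' @param path Path to a (possibly multi-line) FASTA file.
#' @return A tibble with columns `id` (character), `seq` (character,
#'   uppercase DNA) and `length` (integer).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (file.size(path) == 0) {
    warn(paste0("empty FASTA file: ", path))
    return(tibble(id = character(), seq = character(), length = integer()))
  }
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    abort(paste0("duplicate FASTA id: ", dup[1]))
  seqs <- toupper(as.character(ss))
  check_alphabet(seqs, ids)
  tibble(id = ids, seq = unname(seqs), length = unname(nchar(seqs)))
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  ss <- Biostrings::BStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

check_alphabet <- function(seqs, ids = NULL) {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    who <- if (is.null(ids)) which(bad)[1] else ids[bad][1]
    abort(paste0("sequence ", who,
                 " contains characters outside {A,C,G,T,N}"))
  }
  invisible(TRUE)
}

#' Reverse-complement DNA sequences
#'
#' Vectorised over a character vector; `N` maps to `N`. An involution:
#' `reverse_complement(reverse_complement(x)) == x`.
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of the same length.
#' @export
reverse_complement <- function(x) {
  check_alphabet(toupper(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Split a sequence into N-free contig intervals
#'
#' Splits at runs of `N` of length at least `min_gap_len` (with the default
#' 1, every `N` is a breakpoint and the returned intervals are exactly the
#' maximal N-free runs). Coordinates are 0-based half-open.
#'
#' @param seq A single DNA sequence.
#' @param min_gap_len Minimum N-run length that acts as a breakpoint.
#' @return Tibble with columns `start`, `end` (0-based half-open) and
#'   `length`.
#' @export
split_at_n <- function(seq, min_gap_len = 1) {
  stopifnot(length(seq) == 1, nchar(seq) > 0, min_gap_len >= 1)
  gaps <- gregexpr(sprintf("N{%d,}", min_gap_len), seq)[[1]]
  if (gaps[1] == -1) {
    return(tibble(start = 0L, end = nchar(seq),
                  length = nchar(seq)))
  }
  gs <- as.integer(gaps) - 1L                       # 0-based gap starts
  ge <- gs + attr(gaps, "match.length")             # 0-based gap ends (excl)
  starts <- c(0L, ge)
  ends <- c(gs, nchar(seq))
  keep <- ends > starts
  tibble(start = starts[keep], end = ends[keep],
         length = ends[keep] - starts[keep])
}

#' Read a BED3+ file
#'
#' Columns beyond the third are kept under the supplied names (e.g. `name`,
#' `mapq`, `proper_pair`). Coordinates stay 0-based half-open.
#'
#' @param path Path to a tab-separated BED file (no header).
#' @param extra_cols Names for columns 4+ present in the file.
#' @return Tibble with `chrom`, `start`, `end` plus any extra columns.
#' @export
read_bed <- function(path, extra_cols = character()) {
  cols <- c("chrom", "start", "end", extra_cols)
  df <- readr::read_tsv(path, col_names = cols, comment = "#",
                        show_col_types = FALSE, progress = FALSE)
  as_tibble(df)
}

#' Write intervals as BED3+
#'
#' @param x Tibble with `chrom`, `start`, `end` and optional extra columns,
#'   written in order.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  ord <- c("chrom", "start", "end",
           setdiff(names(x), c("chrom", "start", "end")))
  readr::write_tsv(x[, ord], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read TE (or other feature) annotations from GFF3
#'
#' Minimal read-only GFF3 support for repeat annotations: returns 0-based
#' half-open intervals (GFF3 is 1-based inclusive; the conversion happens
#' here and only here).
#'
#' @param path Path to a GFF3 file.
#' @param feature Optional feature type filter (column 3).
#' @return Tibble with `chrom`, `start`, `end`, `strand`, `feature`.
#' @export
read_gff3 <- function(path, feature = NULL) {
  df <- readr::read_tsv(path,
                        col_names = c("chrom", "source", "feature", "start",
                                      "end", "score", "strand", "frame",
                                      "attrs"),
                        comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!is.null(feature)) df <- df[df$feature %in% feature, ]
  tibble(chrom = df$chrom, start = df$start - 1L, end = df$end,
         strand = df$strand, feature = df$feature)
}

#' Write a pseudomolecule layout as AGP v2.1
#'
#' Scaffold (`W`) rows alternate with fixed 100-N gap rows, written with
#' component type `U`, gap type `scaffold`, linkage `yes` and evidence
#' `map` — the gap length is a placeholder join, not a measured distance.
#' AGP coordinates are 1-based inclusive.
#'
#' @param layout A `pseudo_layout` (see [order_scaffolds()]).
#' @param scaffold_lengths Named vector of scaffold lengths (bases).
#' @param path Output path.
#' @return The AGP rows as a tibble, invisibly.
#' @export
write_agp <- function(layout, scaffold_lengths, path) {
  stopifnot(inherits(layout, "pseudo_layout"))
  gap_len <- layout$gap_len
  rows <- list()
  for (chrom in names(layout$chroms)) {
    placed <- layout$chroms[[chrom]]
    obj_pos <- 0L
    part <- 0L
    for (i in seq_len(nrow(placed))) {
      sc <- placed$scaffold[i]
      len <- scaffold_lengths[[sc]]
      if (is.null(len) || is.na(len))
        abort(paste0("no length for scaffold ", sc))
      if (i > 1) {
        part <- part + 1L
        rows[[length(rows) + 1]] <- tibble(
          object = chrom, object_start = obj_pos + 1, object_end = obj_pos + gap_len,
          part_number = part, component_type = "U", c1 = as.character(gap_len),
          c2 = "scaffold", c3 = "yes", c4 = "map")
        obj_pos <- obj_pos + gap_len
      }
      part <- part + 1L
      rows[[length(rows) + 1]] <- tibble(
        object = chrom, object_start = obj_pos + 1, object_end = obj_pos + len,
        part_number = part, component_type = "W", c1 = sc,
        c2 = "1", c3 = as.character(len), c4 = placed$orientation[i])
      obj_pos <- obj_pos + len
    }
  }
  agp <- bind_rows(rows)
  hdr <- "##agp-version\t2.1"
  writeLines(c(hdr, apply(agp, 1, paste, collapse = "\t")), path)
  invisible(agp)
}

#' Read an AGP v2.1 file
#'
#' @param path Path to an AGP file written by [write_agp()].
#' @return Tibble of AGP rows (1-based inclusive object coordinates).
#' @export
read_agp <- function(path) {
  readr::read_tsv(path,
                  col_names = c("object", "object_start", "object_end",
                                "part_number", "component_type",
                                "c1", "c2", "c3", "c4"),
                  comment = "#", show_col_types = FALSE, progress = FALSE)
}
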