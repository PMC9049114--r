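#' Introgression-calling configuration
#'
#' Donor-read coverage is binned in `bin_len` windows after discarding
#' alignments with mapq below `min_mapq` or (when `proper_only`) not
#' flagged as proper pairs. Candidate introgressions are maximal runs of
#' at least `min_run` consecutive blocks whose profile is shared by at
#' most `max_share` cultivars; when donor coverage is available a run is
#' called only if its mean donor depth is at least `cov_factor` times the
#' chromosome-median donor depth. The run-length and coverage-factor
#' defaults are explicit tunables — the underlying evidence (minority
#' haplotype plus elevated donor coverage) is thresholded rather than
#' delimited by eye.
#'
#' @param bin_len Coverage window length in bases (default 1 Mb).
#' @param min_mapq Minimum mapping quality (default 10).
#' @param proper_only Keep only proper-pair alignments (default TRUE).
#' @param min_run Minimum run length in bins (default 5).
#' @param cov_factor Required multiple of the chromosome-median donor
#'   depth inside a call (default 5).
#' @param max_share Profiles shared by at most this many cultivars count
#'   as minority (default 5).
#' @return An `intro_config` list.
#' @export
intro_config <- function(bin_len = 1e6, min_mapq = 10, proper_only = TRUE,
                         min_run = 5, cov_factor = 5, max_share = 5) {
  stopifnot(min_run >= 1, cov_factor > 1, bin_len > 0)
  structure(list(bin_len = as.integer(bin_len), min_mapq = min_mapq,
                 proper_only = proper_only, min_run = as.integer(min_run),
                 cov_factor = cov_factor, max_share = as.integer(max_share)),
            class = "intro_config")
}

#' Bin alignment coverage into fixed windows
#'
#' Each surviving alignment interval contributes its overlap bases to
#' every bin it intersects; bin depth is contributed bases divided by the
#' bin's true length (the trailing bin may be partial). Total contributed
#' bases are conserved exactly.
#'
#' @param intervals Tibble `chrom`, `start`, `end` with optional `mapq`
#'   and `proper_pair` columns (0-based half-open).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param cfg An [intro_config()].
#' @return Tibble `chrom`, `start`, `end`, `depth`.
#' @export
bin_coverage <- function(intervals, chrom_lengths, cfg = intro_config()) {
  stopifnot(inherits(cfg, "intro_config"))
  iv <- intervals
  if ("mapq" %in% names(iv)) iv <- filter(iv, .data$mapq >= cfg$min_mapq)
  if (cfg$proper_only && "proper_pair" %in% names(iv))
    iv <- filter(iv, .data$proper_pair)
  bl <- cfg$bin_len
  bins <- purrr::map_dfr(names(chrom_lengths), function(chrom) {
    len <- chrom_lengths[[chrom]]
    starts <- seq(0, len - 1, by = bl)
    tibble(chrom = chrom, start = starts, end = pmin(starts + bl, len))
  })
  if (nrow(iv) > 0) {
    over_end <- iv$end > chrom_lengths[iv$chrom]
    if (any(over_end, na.rm = TRUE)) {
      warn("clipping intervals extending beyond chromosome ends")
      iv$end <- pmin(iv$end, chrom_lengths[iv$chrom])
    }
    iv <- iv[iv$end > iv$start, ]
  }
  contrib <- if (nrow(iv) == 0) {
    tibble(chrom = character(), bin = integer(), bases = numeric())
  } else {
    iv %>%
      mutate(first_bin = .data$start %/% bl,
             last_bin = (.data$end - 1) %/% bl,
             n_bins = .data$last_bin - .data$first_bin + 1) %>%
      mutate(bin_seq = purrr::pmap(list(.data$first_bin, .data$last_bin),
                                   function(a, b) seq.int(a, b))) %>%
      tidyr::unnest("bin_seq") %>%
      mutate(ov_start = pmax(.data$start, .data$bin_seq * bl),
             ov_end = pmin(.data$end, (.data$bin_seq + 1) * bl),
             bases = .data$ov_end - .data$ov_start) %>%
      group_by(.data$chrom, bin = .data$bin_seq) %>%
      summarise(bases = sum(.data$bases), .groups = "drop")
  }
  bins %>%
    mutate(bin = .data$start %/% bl) %>%
    left_join(contrib, by = c("chrom", "bin")) %>%
    mutate(bases = dplyr::coalesce(.data$bases, 0),
           depth = .data$bases / (.data$end - .data$start)) %>%
    select("chrom", "start", "end", "depth")
}

#' Call candidate introgressions for one cultivar
#'
#' Scans the cultivar's block track for maximal runs of consecutive
#' blocks with minority profiles (popcount <= `max_share`) of length at
#' least `min_run`. With donor coverage bins supplied (same grid), a run
#' is emitted only when its mean donor depth reaches `cov_factor` times
#' the chromosome-median donor depth; without coverage, runs are emitted
#' flagged `coverage_evidence = FALSE`.
#'
#' @param blocks Tibble for one cultivar with `start`, `end`, `popcount`,
#'   `profile` (one chromosome, sorted, on the bin grid).
#' @param donor_bins Optional [bin_coverage()] tibble on the same grid.
#' @param cfg An [intro_config()].
#' @return Tibble `start`, `end`, `n_bins`, `profile` (dominant profile
#'   of the run), `mean_donor_depth`, `coverage_evidence`.
#' @export
call_introgressions <- function(blocks, donor_bins = NULL,
                                cfg = intro_config()) {
  stopifnot(!is.unsorted(blocks$start))
  if (!is.null(donor_bins)) {
    if (nrow(donor_bins) != nrow(blocks) ||
        any(donor_bins$start != blocks$start))
      abort("donor bins and blocks must share the bin grid")
  }
  minority <- !is.na(blocks$popcount) & blocks$popcount <= cfg$max_share
  r <- rle(minority)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1
  runs <- tibble(from = starts_i[r$values], to = ends_i[r$values]) %>%
    mutate(n_bins = .data$to - .data$from + 1) %>%
    filter(.data$n_bins >= cfg$min_run)
  if (nrow(runs) == 0)
    return(tibble(start = numeric(), end = numeric(), n_bins = integer(),
                  profile = character(), mean_donor_depth = numeric(),
                  coverage_evidence = logical()))
  med_depth <- if (!is.null(donor_bins)) median(donor_bins$depth) else NA_real_
  out <- purrr::pmap_dfr(runs, function(from, to, n_bins) {
    prof <- blocks$profile[from:to]
    dom <- names(which.max(table(factor(prof, levels = unique(prof)))))
    mean_depth <- if (!is.null(donor_bins))
      mean(donor_bins$depth[from:to]) else NA_real_
    tibble(start = blocks$start[from], end = blocks$end[to],
           n_bins = as.integer(n_bins), profile = dom,
           mean_donor_depth = mean_depth)
  })
  if (!is.null(donor_bins)) {
    thresh <- cfg$cov_factor * med_depth
    out <- out %>%
      filter(.data$mean_donor_depth > 0,
             .data$mean_donor_depth >= thresh) %>%
      mutate(coverage_evidence = TRUE)
  } else {
    out <- out %>% mutate(coverage_evidence = FALSE)
  }
  out
}
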