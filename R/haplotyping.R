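#' Haplotype painting configuration
#'
#' Parameters of coloured k-mer haplotype painting: 31-mers indexed per
#' cultivar, 1-kb query markers every 20 kb (locus mode: every 5 kb), a
#' presence ratio `e` of 0.95 (locus mode 0.97), the 15 most abundant
#' profiles as the colour palette, 1-Mb superblock merging, and the
#' shared-by-at-least-10 (grey) / cultivar-specific (black) display
#' classes.
#'
#' @param k K-mer size (default 31; must be <= 31).
#' @param marker_len Query marker length in bases (default 1000).
#' @param spacing Marker grid spacing in bases (default 20000).
#' @param e Minimum fraction of a marker's k-mers that must be present in
#'   a cultivar for the marker to be called present there (inclusive).
#' @param top_n Palette size: number of most-abundant profiles (default
#'   15).
#' @param merge_window Superblock tile length in bases (default 1e6).
#' @param grey_min_share Minimum popcount for the grey class (default 10).
#' @param black_share Popcount of the black (cultivar-specific) class
#'   (default 1).
#' @return A `haplo_config` list.
#' @export
haplo_config <- function(k = 31, marker_len = 1000, spacing = 20000,
                         e = 0.95, top_n = 15, merge_window = 1e6,
                         grey_min_share = 10, black_share = 1) {
  stopifnot(k >= 2, k <= 31, marker_len > k, spacing >= marker_len,
            e > 0, e <= 1, top_n >= 1, merge_window >= spacing)
  structure(list(k = as.integer(k), marker_len = as.integer(marker_len),
                 spacing = as.integer(spacing), e = e,
                 top_n = as.integer(top_n),
                 merge_window = as.integer(merge_window),
                 grey_min_share = as.integer(grey_min_share),
                 black_share = as.integer(black_share)),
            class = "haplo_config")
}

#' Locus-scale configuration (5-kb grid, e = 0.97)
#'
#' @param ... Overrides passed to [haplo_config()].
#' @return A `haplo_config` with `spacing = 5000` and `e = 0.97`.
#' @export
haplo_config_locus <- function(...) {
  args <- list(spacing = 5000, e = 0.97)
  override <- list(...)
  args[names(override)] <- override
  do.call(haplo_config, args)
}

#' Build a coloured canonical k-mer index over a cultivar panel
#'
#' Stores, for every canonical k-mer (lexicographic min of a k-mer and its
#' reverse complement) present in any cultivar's sequence, the bitset of
#' cultivars containing it. Only N-free windows are indexed. This
#' membership table carries the same query semantics as a coloured de
#' Bruijn graph for presence-ratio queries, without graph topology.
#'
#' @param panel Tibble with columns `cultivar` and `seq` (one or more
#'   sequences per cultivar).
#' @param cfg A [haplo_config()].
#' @return A `colored_kmer_index` (in-memory; rebuild rather than
#'   serialize).
#' @export
build_colored_index <- function(panel, cfg = haplo_config()) {
  stopifnot(inherits(cfg, "haplo_config"),
            all(c("cultivar", "seq") %in% names(panel)))
  colours <- unique(panel$cultivar)
  if (length(colours) < 2) abort("need at least two cultivars")
  if (min(nchar(panel$seq)) < cfg$k)
    abort("k exceeds the shortest sequence")
  by_col <- lapply(colours, function(cv) panel$seq[panel$cultivar == cv])
  ptr <- cpp_build_colored_index(by_col, cfg$k)
  structure(list(ptr = ptr, k = cfg$k, colours = colours,
                 n_kmers = cpp_index_size(ptr)),
            class = "colored_kmer_index")
}

#' @export
print.colored_kmer_index <- function(x, ...) {
  cat("<colored_kmer_index> k=", x$k, ", ", length(x$colours),
      " colours, ", format(x$n_kmers, big.mark = ","),
      " canonical k-mers\n", sep = "")
  invisible(x)
}

#' Extract fixed-length query markers on an even grid
#'
#' Markers of `marker_len` bases start at offsets 0, `spacing`,
#' 2·`spacing`, … and are emitted only when fully inside the chromosome.
#' Windows that are at least half N are skipped.
#'
#' @param seq A single chromosome sequence.
#' @param cfg A [haplo_config()].
#' @return Tibble `start`, `end` (0-based half-open), `seq`.
#' @export
extract_query_markers <- function(seq, cfg = haplo_config()) {
  len <- nchar(seq)
  if (len < cfg$marker_len)
    return(tibble(start = integer(), end = integer(), seq = character()))
  starts <- seq.int(0L, len - cfg$marker_len, by = cfg$spacing)
  out <- tibble(start = starts, end = starts + cfg$marker_len,
                seq = substring(seq, starts + 1, starts + cfg$marker_len))
  n_frac <- (nchar(out$seq) -
               nchar(gsub("N", "", out$seq, fixed = TRUE))) / cfg$marker_len
  out[n_frac < 0.5, ]
}

#' Query marker presence across the panel
#'
#' For each marker, counts its valid (N-free) k-mers and, per cultivar,
#' the fraction found in that cultivar's index; a cultivar's bit is set
#' when the fraction is at least `e`. Markers with no valid k-mer get an
#' empty profile (`NA`).
#'
#' @param markers Character vector of marker sequences, or the tibble from
#'   [extract_query_markers()].
#' @param index A [build_colored_index()] result.
#' @param cfg A [haplo_config()] (supplies `e`).
#' @return Tibble with `profile` (bit string over cultivars in index
#'   order), `popcount`, `n_kmers_valid`, plus any input columns.
#' @export
query_presence <- function(markers, index, cfg = haplo_config()) {
  stopifnot(inherits(index, "colored_kmer_index"))
  tab <- if (is.character(markers)) tibble(seq = markers) else markers
  res <- cpp_query_counts(tab$seq, index$ptr)
  m <- res$m
  counts <- res$counts
  present <- counts >= ceiling(cfg$e * m) & m > 0
  profile <- apply(present, 1, function(r) paste(as.integer(r), collapse = ""))
  profile[m == 0] <- NA_character_
  tab$profile <- profile
  tab$popcount <- ifelse(m == 0, NA_integer_, rowSums(present))
  tab$n_kmers_valid <- m
  tab
}

#' Minimum k-mer hit count for presence
#'
#' The count threshold implied by the presence ratio: a 1-kb N-free marker
#' at k = 31 has 970 k-mers, so e = 0.95 requires at least
#' `ceiling(0.95 * 970) = 922` of them.
#'
#' @param marker_len Marker length (bases).
#' @param k K-mer size.
#' @param e Presence ratio.
#' @return Integer count threshold.
#' @export
presence_min_count <- function(marker_len = 1000, k = 31, e = 0.95) {
  as.integer(ceiling(e * (marker_len - k + 1)))
}

#' Select the most abundant presence profiles as the palette
#'
#' Profiles are ranked by how many markers carry them (descending), ties
#' broken by ascending bit-vector value, and the `top_n` retained.
#'
#' @param profiles Character vector of profile bit strings (or a tibble
#'   with a `profile` column).
#' @param cfg A [haplo_config()].
#' @return Tibble `profile`, `n_markers`, `palette_rank`.
#' @export
top_profiles <- function(profiles, cfg = haplo_config()) {
  if (is.data.frame(profiles)) profiles <- profiles$profile
  profiles <- profiles[!is.na(profiles)]
  if (length(profiles) == 0) abort("no profiles to rank")
  tab <- tibble(profile = profiles) %>%
    count(.data$profile, name = "n_markers") %>%
    mutate(bitval = strtoi(.data$profile, base = 2)) %>%
    arrange(desc(.data$n_markers), .data$bitval) %>%
    head(cfg$top_n) %>%
    mutate(palette_rank = row_number()) %>%
    select("profile", "n_markers", "palette_rank")
  tab
}

#' Classify blocks into black / grey / coloured / white
#'
#' Precedence: popcount equal to `black_share` is black
#' (cultivar-specific); popcount at least `grey_min_share` is grey
#' (shared by nearly the whole panel); otherwise a profile in the palette
#' is coloured with its palette rank; anything else (including empty
#' profiles) is white.
#'
#' @param blocks Tibble with `profile` and `popcount` columns.
#' @param palette Tibble from [top_profiles()].
#' @param cfg A [haplo_config()].
#' @return `blocks` with `cls` and `palette_rank` columns added.
#' @export
classify_blocks <- function(blocks, palette, cfg = haplo_config()) {
  blocks %>%
    left_join(palette[, c("profile", "palette_rank")], by = "profile") %>%
    mutate(cls = dplyr::case_when(
      is.na(.data$popcount) ~ "white",
      .data$popcount == cfg$black_share ~ "black",
      .data$popcount >= cfg$grey_min_share ~ "grey",
      !is.na(.data$palette_rank) ~ "coloured",
      TRUE ~ "white"),
      palette_rank = ifelse(.data$cls == "coloured", .data$palette_rank,
                            NA_integer_))
}

#' Merge per-marker blocks into superblock tiles
#'
#' Tiles each chromosome into non-overlapping `merge_window` spans and
#' assigns each tile the modal profile of its member blocks (ties resolve
#' to the profile seen first, leftmost, in the tile). A trailing partial
#' tile uses whatever members it has.
#'
#' @param blocks Tibble with `start` and `profile` (one cultivar/chrom at
#'   a time, or grouped externally), sorted by position.
#' @param cfg A [haplo_config()].
#' @return Tibble `tile_start`, `tile_end`, `profile`, `popcount`,
#'   `n_members`.
#' @export
merge_to_superblocks <- function(blocks, cfg = haplo_config()) {
  stopifnot(!is.unsorted(blocks$start))
  blocks %>%
    mutate(tile = .data$start %/% cfg$merge_window) %>%
    group_by(.data$tile) %>%
    summarise(tile_start = .data$tile[1] * cfg$merge_window,
              tile_end = tile_start + cfg$merge_window,
              profile = {
                p <- .data$profile[!is.na(.data$profile)]
                if (length(p) == 0) NA_character_ else {
                  cnt <- table(factor(p, levels = unique(p)))
                  names(cnt)[which.max(cnt)]  # unique() keeps leftmost first
                }
              },
              n_members = n(), .groups = "drop") %>%
    mutate(popcount = ifelse(is.na(.data$profile), NA_integer_,
                             vapply(strsplit(.data$profile, ""),
                                    function(b) sum(b == "1"), numeric(1)))) %>%
    select("tile_start", "tile_end", "profile", "popcount", "n_members")
}

#' Paint a chromosome panel into haplotype blocks
#'
#' End-to-end painting of one chromosome across the panel: builds the
#' coloured index, extracts the marker grid from each cultivar, queries
#' presence profiles, selects the chromosome-wide palette, classifies the
#' per-marker (spacing-sized) blocks, and merges them into superblock
#' tiles.
#'
#' @param panel Tibble `cultivar`, `seq` (one chromosome per cultivar).
#' @param cfg A [haplo_config()].
#' @param index Optionally a pre-built [build_colored_index()].
#' @return List with `blocks` (per-marker, classified), `superblocks`
#'   (classified tiles per cultivar), `palette`, `index`.
#' @export
paint_chromosome <- function(panel, cfg = haplo_config(), index = NULL) {
  if (is.null(index)) index <- build_colored_index(panel, cfg)
  blocks <- purrr::map_dfr(seq_len(nrow(panel)), function(i) {
    mk <- extract_query_markers(panel$seq[i], cfg)
    qp <- query_presence(mk, index, cfg)
    qp$cultivar <- panel$cultivar[i]
    # each marker represents its spacing-sized bin
    qp$end <- pmin(qp$start + cfg$spacing, nchar(panel$seq[i]))
    qp
  }) %>% select("cultivar", "start", "end", "profile", "popcount",
                "n_kmers_valid")
  palette <- top_profiles(blocks$profile, cfg)
  blocks <- classify_blocks(blocks, palette, cfg)
  superblocks <- blocks %>%
    group_by(.data$cultivar) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    dplyr::group_modify(~ merge_to_superblocks(.x, cfg)) %>%
    ungroup() %>%
    classify_blocks(palette, cfg)
  list(blocks = blocks, superblocks = superblocks, palette = palette,
       index = index)
}

#' Locus-scale haplotype painting
#'
#' Localizes a region of interest from one cultivar in every panel genome
#' by mapping 1-kb probes (seed-and-extend, as for ISBP markers), taking
#' the modal hit interval and majority strand per cultivar, then paints
#' the localized regions on the locus grid (1-kb marker every 5 kb,
#' e = 0.97). Cultivars where fewer than half the probes localize
#' consistently are reported as not localized.
#'
#' @param region_seq The region sequence (>= 10 kb) from the source
#'   cultivar.
#' @param panel Tibble `cultivar`, `seq` of panel chromosomes.
#' @param cfg A [haplo_config_locus()].
#' @param map_cfg A [map_config()] for probe localization.
#' @return List with `localization` (per cultivar: `localized`, `start`,
#'   `end`, `strand`, `probe_support`) and `painting` (the
#'   [paint_chromosome()] result over the localized regions).
#' @export
locus_haplotypes <- function(region_seq, panel, cfg = haplo_config_locus(),
                             map_cfg = map_config(preset = "anchor")) {
  stopifnot(nchar(region_seq) >= 10000)
  probes <- extract_query_markers(region_seq,
                                  haplo_config(spacing = 5000,
                                               marker_len = 1000,
                                               e = cfg$e))
  probes$id <- sprintf("probe%03d", seq_len(nrow(probes)))
  loc_rows <- list()
  regions <- list()
  for (i in seq_len(nrow(panel))) {
    cv <- panel$cultivar[i]
    hits <- map_markers(probes, tibble(id = cv, seq = panel$seq[i]),
                        map_cfg)
    n_probes <- nrow(probes)
    if (nrow(hits) == 0) {
      loc_rows[[i]] <- tibble(cultivar = cv, localized = FALSE,
                              start = NA_real_, end = NA_real_,
                              strand = NA_character_, probe_support = 0)
      next
    }
    # implied region origin on the target: for minus-strand hits the
    # probe at offset p sits at L - p - marker_len from the region end
    L <- nchar(region_seq)
    ml <- 1000
    hits <- hits %>%
      left_join(tibble(id = probes$id, probe_start = probes$start),
                by = c(marker_id = "id")) %>%
      mutate(origin = ifelse(.data$strand == "+",
                             .data$target_start - .data$probe_start,
                             .data$target_start - (L - .data$probe_start - ml)))
    # modal placement: cluster implied region origins within 10 kb
    ori <- sort(hits$origin)
    cl <- cumsum(c(1, diff(ori) > 10000))
    best_cl <- as.integer(names(which.max(table(cl))))
    support <- sum(cl == best_cl) / n_probes
    if (support < 0.5) {
      loc_rows[[i]] <- tibble(cultivar = cv, localized = FALSE,
                              start = NA_real_, end = NA_real_,
                              strand = NA_character_,
                              probe_support = support)
      next
    }
    origin <- median(ori[cl == best_cl])
    strand <- names(which.max(table(hits$strand)))
    rstart <- max(0, round(origin))
    rend <- min(nchar(panel$seq[i]), rstart + nchar(region_seq))
    rseq <- substring(panel$seq[i], rstart + 1, rend)
    if (strand == "-") rseq <- reverse_complement(rseq)
    loc_rows[[i]] <- tibble(cultivar = cv, localized = TRUE,
                            start = rstart, end = rend, strand = strand,
                            probe_support = support)
    regions[[cv]] <- rseq
  }
  localization <- bind_rows(loc_rows)
  painting <- NULL
  if (length(regions) >= 2) {
    reg_panel <- tibble(cultivar = names(regions),
                        seq = unname(unlist(regions)))
    painting <- paint_chromosome(reg_panel, cfg)
  }
  list(localization = localization, painting = painting)
}
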