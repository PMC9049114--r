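#' Plot haplotype block tracks for a cultivar panel
#'
#' Draws one horizontal track per cultivar with blocks coloured by their
#' class: palette colours for the shared haplotypes, grey for
#' nearly-panel-wide blocks, black for cultivar-specific blocks, white
#' where no haplotype block was assigned.
#'
#' @param blocks Classified block tibble (per-marker blocks or
#'   superblocks) with `cultivar`, `start`, `end`/`tile_start`,
#'   `tile_end`, `cls`, `palette_rank`.
#' @return A ggplot object.
#' @export
plot_haploblocks <- function(blocks) {
  if ("tile_start" %in% names(blocks))
    blocks <- blocks %>% rename(start = "tile_start", end = "tile_end")
  blocks <- blocks %>%
    mutate(fill_key = dplyr::case_when(
      .data$cls == "coloured" ~ paste0("hap", .data$palette_rank),
      TRUE ~ .data$cls))
  ranks <- sort(unique(blocks$palette_rank[blocks$cls == "coloured"]))
  pal <- setNames(scales_hue(length(ranks)), paste0("hap", ranks))
  fills <- c(pal, black = "black", grey = "grey60", white = "white")
  ggplot2::ggplot(blocks,
                  ggplot2::aes(xmin = .data$start / 1e6,
                               xmax = .data$end / 1e6,
                               ymin = as.integer(factor(.data$cultivar)) - 0.4,
                               ymax = as.integer(factor(.data$cultivar)) + 0.4,
                               fill = .data$fill_key)) +
    ggplot2::geom_rect(colour = NA) +
    ggplot2::scale_fill_manual(values = fills, name = "haplotype") +
    ggplot2::scale_y_continuous(
      breaks = seq_along(unique(blocks$cultivar)),
      labels = levels(factor(blocks$cultivar))) +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
}

scales_hue <- function(n) {
  if (n == 0) return(character())
  grDevices::hcl(h = seq(15, 375, length.out = n + 1)[seq_len(n)],
                 c = 100, l = 65)
}

#' Plot a binned coverage track with introgression calls
#'
#' @param bins Tibble from [bin_coverage()].
#' @param calls Optional tibble from [call_introgressions()]; called
#'   spans are framed.
#' @return A ggplot object.
#' @export
plot_coverage <- function(bins, calls = NULL) {
  p <- ggplot2::ggplot(bins,
                       ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                    y = .data$depth)) +
    ggplot2::geom_step(colour = "darkorange") +
    ggplot2::labs(x = "position (Mb)", y = "donor read depth") +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls) > 0)
    p <- p + ggplot2::geom_rect(
      data = calls, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -Inf, ymax = Inf),
      colour = "red", fill = NA, linewidth = 0.4)
  p
}

#' Plot cumulative assembly length against sequence rank
#'
#' The classic Nxx curve: sequences sorted descending, cumulative length
#' against rank, with the N50 point marked.
#'
#' @param lengths Numeric vector of sequence lengths (or a tibble with a
#'   `length` column).
#' @return A ggplot object.
#' @export
plot_nxx_curve <- function(lengths) {
  if (is.data.frame(lengths)) lengths <- lengths$length
  lens <- sort(lengths, decreasing = TRUE)
  df <- tibble(rank = seq_along(lens), cum = cumsum(lens))
  st <- assembly_stats(lens)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$cum)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = st$l50, linetype = "dashed") +
    ggplot2::labs(x = "sequence rank", y = "cumulative length (bp)") +
    ggplot2::theme_minimal()
}
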