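# ggplot2 displays for the main result types. Each returns a ggplot object
# the caller can restyle.

#' Tile plot of TE family enrichment
#'
#' log2 enrichment per family (optionally across several assemblies); absent
#' families are drawn as grey tiles.
#'
#' @param enrichment Output of [te_enrichment()], optionally with an extra
#'   `assembly` column when several assemblies are combined.
#' @return A ggplot.
#' @export
plot_te_enrichment <- function(enrichment) {
  e <- enrichment
  if (!"assembly" %in% names(e)) e$assembly <- "assembly"
  ggplot2::ggplot(e, ggplot2::aes(x = .data$assembly, y = .data$family)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$log2_enrichment), colour = "white") +
    ggplot2::geom_tile(data = e[e$absent, , drop = FALSE], fill = "grey70",
                       colour = "white") +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  na.value = "grey70",
                                  name = "log2 enrichment") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Divergence landscape of selected TE families
#'
#' Per-copy percent divergence, in-locus copies contrasted with the
#' genome-wide background; tight vertical stacks inside the locus are the
#' segmental-duplication signature.
#'
#' @param repeats Repeat tibble.
#' @param locus Locus tibble (`chrom`, `start`, `end`).
#' @param families Families to show; default [select_display_families()].
#' @return A ggplot.
#' @export
plot_divergence_landscape <- function(repeats, locus,
                                      families = select_display_families(repeats, locus)) {
  lf <- locus_fields(locus)
  r <- repeats %>%
    filter(.data$family %in% families) %>%
    mutate(where = ifelse(.data$chrom == lf$chrom & .data$begin <= lf$end &
                            .data$end >= lf$start,
                          "cluster locus", "genome-wide"))
  ggplot2::ggplot(r, ggplot2::aes(x = .data$perc_div, fill = .data$where)) +
    ggplot2::geom_histogram(binwidth = 0.5, position = "identity", alpha = 0.6) +
    ggplot2::facet_wrap(~family, scales = "free_y") +
    ggplot2::labs(x = "% divergence from consensus", y = "copies",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Null distribution of a permutation overlap test
#'
#' @param x A `perm_overlap` object.
#' @param ... Unused.
#' @return A ggplot: permutation counts with the observed value marked.
#' @export
plot_perm_overlap <- function(x, ...) {
  stopifnot(inherits(x, "perm_overlap"))
  df <- tibble(perm = x$perm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$perm)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey60") +
    ggplot2::geom_vline(xintercept = x$observed, colour = "firebrick") +
    ggplot2::labs(x = "regions overlapping locus (permuted)", y = "permutations",
                  subtitle = sprintf("observed = %d, Z = %.2f, p = %.3g",
                                     x$observed, x$z, x$p_value)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_perm_overlap
#' @param object A `perm_overlap` object.
#' @export
autoplot.perm_overlap <- function(object, ...) plot_perm_overlap(object, ...)

#' Gene-block map of a cluster
#'
#' Genes along the cluster coordinate, coloured by similarity group, with
#' detected block occurrences drawn underneath.
#'
#' @param genes Tibble with `gene_id`, `start`, `end`, `strand`, `group`.
#' @param blocks Output of [detect_blocks()] (may be empty).
#' @return A ggplot.
#' @export
plot_block_map <- function(genes, blocks = NULL) {
  p <- ggplot2::ggplot(genes) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end, y = 1, yend = 1,
                   colour = factor(.data$group)),
      linewidth = 4) +
    ggplot2::labs(x = "cluster coordinate (bp)", y = NULL,
                  colour = "3' exon group") +
    ggplot2::scale_y_continuous(breaks = NULL, limits = c(0, 1.5)) +
    ggplot2::theme_minimal()
  if (!is.null(blocks) && nrow(blocks) > 0L) {
    p <- p + ggplot2::geom_segment(
      data = blocks,
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = 0.6 - 0.1 * as.integer(factor(.data$block_id)),
                   yend = 0.6 - 0.1 * as.integer(factor(.data$block_id))),
      linewidth = 2, colour = "grey40")
  }
  p
}

#' Bubble plot of peak-TE association
#'
#' @param assoc Output of [peak_te_association()], optionally with a `kzfp`
#'   column when several factors are combined.
#' @return A ggplot: bubble size is the percentage of peaks on the family,
#'   colour the permutation Z-score.
#' @export
plot_peak_te <- function(assoc) {
  a <- assoc
  if (!"kzfp" %in% names(a)) a$kzfp <- "KZFP"
  ggplot2::ggplot(a[a$display, , drop = FALSE],
                  ggplot2::aes(x = .data$kzfp, y = .data$family)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$percent_peaks, colour = .data$z)) +
    ggplot2::scale_colour_gradient(low = "lightblue", high = "darkred",
                                   name = "Z") +
    ggplot2::scale_size_area(name = "% peaks") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
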