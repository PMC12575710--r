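# Gene models as a set of plain tibbles (genes / transcripts / exons / CDS),
# read from GFF3 via rtracklayer. The simulator produces the same structure
# directly, so annotation code is agnostic to provenance.

#' Read gene models from a GFF3 file
#'
#' Imports `gene`, `mRNA`, `exon` and `CDS` features and returns them as a
#' list of tibbles linked by `gene_id`/`tx_id`. Multi-exon mRNAs are honoured;
#' exon rank is assigned in transcript (5' to 3') order. A `kzfp_class`
#' attribute on gene features, when present, is carried through.
#'
#' @param path Path to a GFF3 file.
#' @return A list of class `gene_models` with tibbles `genes` (`gene_id`,
#'   `name`, `chrom`, `start`, `end`, `strand`, `kzfp_class`), `transcripts`
#'   (`tx_id`, `gene_id`), `exons` (`tx_id`, `exon_rank`, `chrom`, `start`,
#'   `end`, `strand`) and `cds` (`tx_id`, `chrom`, `start`, `end`, `strand`).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr, stringsAsFactors = FALSE))
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  first_parent <- function(p) vapply(p, function(x) {
    if (length(x) == 0L) NA_character_ else as.character(x[[1]])
  }, character(1))

  genes <- df %>%
    filter(.data$type == "gene") %>%
    transmute(
      gene_id = .data$ID,
      name = if ("Name" %in% names(df)) as.character(.data$Name) else .data$ID,
      chrom = .data$seqnames, start = .data$start, end = .data$end,
      strand = .data$strand,
      kzfp_class = if ("kzfp_class" %in% names(df)) {
        as.character(.data$kzfp_class)
      } else {
        NA_character_
      }
    )
  transcripts <- df %>%
    filter(.data$type == "mRNA") %>%
    transmute(tx_id = .data$ID, gene_id = first_parent(.data$Parent))
  exons <- df %>%
    filter(.data$type == "exon") %>%
    transmute(tx_id = first_parent(.data$Parent), chrom = .data$seqnames,
              start = .data$start, end = .data$end, strand = .data$strand)
  cds <- df %>%
    filter(.data$type == "CDS") %>%
    transmute(tx_id = first_parent(.data$Parent), chrom = .data$seqnames,
              start = .data$start, end = .data$end, strand = .data$strand)

  # Exon rank in transcript order: ascending start on '+', descending on '-'.
  exons <- exons %>%
    group_by(.data$tx_id) %>%
    arrange(if (dplyr::first(.data$strand) == "-") dplyr::desc(.data$start) else .data$start,
            .by_group = TRUE) %>%
    mutate(exon_rank = dplyr::row_number()) %>%
    ungroup() %>%
    select("tx_id", "exon_rank", "chrom", "start", "end", "strand")

  structure(list(genes = genes, transcripts = transcripts,
                 exons = exons, cds = cds),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes, %d transcripts, %d exons\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

# Extract a 1-based inclusive genomic window as a character string.
get_seq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    abort(sprintf("chromosome '%s' not present in genome", chrom))
  }
  s <- genome[[chrom]]
  len <- if (inherits(s, "DNAString")) length(s) else nchar(s)
  if (start < 1L || end > len) {
    abort(sprintf("interval %d-%d outside chromosome '%s' (length %d)",
                  start, end, chrom, len))
  }
  as.character(Biostrings::subseq(Biostrings::DNAString(as.character(s)), start, end))
}

# Spliced transcript sequence, 5'->3' in transcript orientation.
# `exons` needs chrom/start/end/strand; all exons share chrom and strand.
spliced_seq <- function(exons, genome) {
  stopifnot(nrow(exons) >= 1L)
  ex <- arrange(exons, .data$start)
  pieces <- vapply(seq_len(nrow(ex)), function(i) {
    get_seq(genome, ex$chrom[i], ex$start[i], ex$end[i])
  }, character(1))
  seq <- paste(pieces, collapse = "")
  if (ex$strand[1] == "-") seq <- reverse_complement(seq)
  seq
}

# Map transcript coordinates (1-based along the spliced sequence) back to the
# exon rank holding each position: returns cumulative exon widths in
# transcript order.
exon_cumlen <- function(exons) {
  ex <- arrange(exons, .data$exon_rank)
  w <- ex$end - ex$start + 1L
  cumsum(w)
}
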