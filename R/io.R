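# Readers and writers for the flat-file interfaces: GFF3 (write; reading is
# delegated to rtracklayer), RepeatMasker .out, PAF, MACS2-style peak tables
# and the ground-truth TSV set. All writers are byte-deterministic.

#' Write a FASTA file (60-column wrap)
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(unlist(seqs))
  }
  Biostrings::writeXStringSet(seqs, filepath = path, width = 60L)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

gff3_attr <- function(...) {
  kv <- list(...)
  kv <- kv[!vapply(kv, is.null, logical(1))]
  paste(paste0(names(kv), "=", unlist(kv)), collapse = ";")
}

#' Write gene models to GFF3
#'
#' Emits `gene`, `mRNA`, `exon` and `CDS` features with `ID`/`Parent` links
#' and a `kzfp_class` attribute on gene features. Coordinates are 1-based
#' inclusive per the format.
#'
#' @param models A `gene_models` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  lines <- c("##gff-version 3")
  genes <- arrange(models$genes, .data$chrom, .data$start)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, paste(
      g$chrom, "kzfpscape", "gene", g$start, g$end, ".", g$strand, ".",
      gff3_attr(ID = g$gene_id, Name = g$name,
                kzfp_class = if (is.na(g$kzfp_class)) NULL else g$kzfp_class),
      sep = "\t"))
    txs <- filter(models$transcripts, .data$gene_id == g$gene_id)
    for (tx in txs$tx_id) {
      ex <- models$exons %>% filter(.data$tx_id == tx) %>% arrange(.data$start)
      cd <- models$cds %>% filter(.data$tx_id == tx) %>% arrange(.data$start)
      lines <- c(lines, paste(
        g$chrom, "kzfpscape", "mRNA", min(ex$start), max(ex$end), ".",
        g$strand, ".", gff3_attr(ID = tx, Parent = g$gene_id), sep = "\t"))
      for (j in seq_len(nrow(ex))) {
        lines <- c(lines, paste(
          g$chrom, "kzfpscape", "exon", ex$start[j], ex$end[j], ".",
          g$strand, ".", gff3_attr(ID = paste0(tx, ".e", j), Parent = tx),
          sep = "\t"))
      }
      for (j in seq_len(nrow(cd))) {
        lines <- c(lines, paste(
          g$chrom, "kzfpscape", "CDS", cd$start[j], cd$end[j], ".",
          g$strand, "0", gff3_attr(ID = paste0(tx, ".c", j), Parent = tx),
          sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a repeat-annotation table as RepeatMasker .out
#'
#' Standard 15-column layout with the 3 header lines; minus-strand rows use
#' the `C` strand code as RepeatMasker does.
#'
#' @param repeats Tibble in the shape returned by [read_repeatmasker_out()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(repeats, path) {
  hdr <- c(
    "   SW  perc perc perc  query     position in query    matching repeat       position in  repeat",
    "score  div. del. ins.  sequence  begin  end  (left)   repeat   class/family begin  end (left)  ID",
    ""
  )
  rows <- character(nrow(repeats))
  for (i in seq_len(nrow(repeats))) {
    r <- repeats[i, ]
    rows[i] <- paste(
      r$score, sprintf("%.1f", r$perc_div), sprintf("%.1f", r$perc_del),
      sprintf("%.1f", r$perc_ins), r$chrom, r$begin, r$end,
      sprintf("(%d)", r$left), if (r$strand == "-") "C" else "+",
      r$family, r$class_family, r$rep_begin, r$rep_end,
      sprintf("(%d)", r$rep_left), r$join_id,
      sep = "  ")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a RepeatMasker .out file
#'
#' Parses the standard 15-column body (3 header lines skipped), tolerating
#' the trailing `*` higher-scoring-overlap flag and mapping strand `C` to
#' `-`.
#'
#' @param path Path to a `.out` file.
#' @return A tibble with columns `score`, `perc_div`, `perc_del`, `perc_ins`,
#'   `chrom`, `begin`, `end`, `left`, `strand`, `family`, `class_family`,
#'   `rep_begin`, `rep_end`, `rep_left`, `join_id`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  body <- lines[-seq_len(min(3L, length(lines)))]
  body_idx <- which(nzchar(trimws(body)))
  empty <- tibble(score = integer(), perc_div = numeric(), perc_del = numeric(),
                  perc_ins = numeric(), chrom = character(), begin = integer(),
                  end = integer(), left = integer(), strand = character(),
                  family = character(), class_family = character(),
                  rep_begin = integer(), rep_end = integer(),
                  rep_left = integer(), join_id = integer())
  if (length(body_idx) == 0L) return(empty)
  strip_paren <- function(x) as.integer(gsub("[()]", "", x))
  rows <- lapply(body_idx, function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) == 16L && f[16] == "*") f <- f[1:15]
    if (length(f) != 15L) {
      abort(sprintf("malformed RepeatMasker row at line %d: %d fields",
                    i + 3L, length(f)))
    }
    num <- suppressWarnings(list(
      score = as.integer(f[1]), perc_div = as.numeric(f[2]),
      perc_del = as.numeric(f[3]), perc_ins = as.numeric(f[4]),
      begin = as.integer(f[6]), end = as.integer(f[7]),
      left = strip_paren(f[8])
    ))
    if (any(vapply(num, function(x) length(x) == 0L || is.na(x), logical(1)))) {
      abort(sprintf("malformed RepeatMasker row at line %d: non-numeric field",
                    i + 3L))
    }
    tibble(score = num$score, perc_div = num$perc_div, perc_del = num$perc_del,
           perc_ins = num$perc_ins, chrom = f[5], begin = num$begin,
           end = num$end, left = num$left,
           strand = if (f[9] == "C") "-" else f[9],
           family = f[10], class_family = f[11],
           rep_begin = suppressWarnings(strip_paren(f[12])),
           rep_end = suppressWarnings(strip_paren(f[13])),
           rep_left = suppressWarnings(strip_paren(f[14])),
           join_id = as.integer(f[15]))
  })
  bind_rows(rows)
}

#' Read a PAF alignment file
#'
#' Parses the 12 mandatory tab-separated columns; optional SAM-style tags are
#' ignored. Query/target coordinates keep PAF's 0-based half-open convention.
#'
#' @param path Path to a PAF file.
#' @return A tibble with columns `qname`, `qlen`, `qstart`, `qend`, `strand`,
#'   `tname`, `tlen`, `tstart`, `tend`, `matches`, `alnlen`, `mapq`.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- tibble(qname = character(), qlen = integer(), qstart = integer(),
                  qend = integer(), strand = character(), tname = character(),
                  tlen = integer(), tstart = integer(), tend = integer(),
                  matches = integer(), alnlen = integer(), mapq = integer())
  if (length(lines) == 0L) return(empty)
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L) {
      abort(sprintf("malformed PAF row at line %d: %d columns (need >= 12)",
                    i, length(f)))
    }
    tibble(qname = f[1], qlen = as.integer(f[2]), qstart = as.integer(f[3]),
           qend = as.integer(f[4]), strand = f[5], tname = f[6],
           tlen = as.integer(f[7]), tstart = as.integer(f[8]),
           tend = as.integer(f[9]), matches = as.integer(f[10]),
           alnlen = as.integer(f[11]), mapq = as.integer(f[12]))
  })
  bind_rows(rows)
}

#' Write a PAF file
#'
#' @param paf Tibble in the shape returned by [read_paf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(paf, path) {
  cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
            "tstart", "tend", "matches", "alnlen", "mapq")
  readr::write_tsv(paf[, cols], path, col_names = FALSE)
  invisible(path)
}

#' Read a MACS2-style peak table
#'
#' Tab-separated with header columns `chrom`, `start`, `end`, `summit`,
#' `fold_enrichment`, `qValue` (additional columns are kept).
#'
#' @param path Path to the peak table.
#' @return A tibble.
#' @export
read_peaks <- function(path) {
  pk <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("chrom", "start", "end", "summit", "fold_enrichment", "qValue")
  if (!all(needed %in% names(pk))) {
    abort(paste("peak table needs columns:", paste(needed, collapse = ", ")))
  }
  pk
}

#' Export peaks as BED6
#'
#' BED is 0-based half-open; the score field carries fold enrichment.
#'
#' @param peaks Peak tibble (see [read_peaks()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  bed <- peaks %>%
    transmute(chrom = .data$chrom, start = .data$start - 1L, end = .data$end,
              name = sprintf("peak%d", dplyr::row_number()),
              score = .data$fold_enrichment, strand = ".")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write a full simulation to disk
#'
#' Emits `genome.fa`, `genes.gff3`, `repeats.out`, the ground-truth TSV set
#' under `truth/`, and (when [fragment_into_contigs()] has been applied)
#' `contigs.fa` and `alignments.paf`.
#'
#' @param sim A `kzfp_sim` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "kzfp_sim"))
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_gff3(sim$models, file.path(dir, "genes.gff3"))
  write_repeatmasker_out(sim$repeats, file.path(dir, "repeats.out"))
  for (nm in names(sim$truth)) {
    readr::write_tsv(sim$truth[[nm]], file.path(dir, "truth", paste0(nm, ".tsv")))
  }
  if (!is.null(sim$contigs)) {
    write_fasta(sim$contigs, file.path(dir, "contigs.fa"))
    write_paf(sim$paf, file.path(dir, "alignments.paf"))
  }
  invisible(dir)
}

#' Read a ground-truth TSV set written by [write_simulation()]
#'
#' @param dir Simulation output directory.
#' @return A list of tibbles (`genes`, `te_copies`, `blocks`, `contigs`).
#' @export
read_ground_truth <- function(dir) {
  files <- list.files(file.path(dir, "truth"), pattern = "\\.tsv$",
                      full.names = TRUE)
  out <- lapply(files, readr::read_tsv, show_col_types = FALSE, progress = FALSE)
  names(out) <- sub("\\.tsv$", "", basename(files))
  out
}
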