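# Contig-level assembly curation from PAF alignments: chromosome assignment
# by longest alignment block, removal of contigs nested inside larger ones,
# and strand correction of minus-oriented contigs.

#' Assign a contig to a chromosome from its alignments
#'
#' Alignments to targets outside `known_chroms` are discarded. If none
#' remain the contig is unplaced; otherwise it is assigned to the chromosome
#' of its single longest alignment block (target-span bp), ties broken by
#' larger total aligned bp on the chromosome, then lexicographic name.
#'
#' @param paf PAF tibble rows for one contig (see [read_paf()]).
#' @param known_chroms Character vector of placeable chromosome names.
#' @return A one-row tibble: `chrom` (`NA` if unplaced), `longest_bp`,
#'   `total_bp`, `span_start`, `span_end` (0-based half-open merged span on
#'   the assigned chromosome), `minus_bp`, `plus_bp`.
#' @export
assign_chromosome <- function(paf, known_chroms) {
  p <- paf[paf$tname %in% known_chroms, , drop = FALSE]
  if (nrow(p) == 0L) {
    return(tibble(chrom = NA_character_, longest_bp = 0L, total_bp = 0L,
                  span_start = NA_integer_, span_end = NA_integer_,
                  minus_bp = 0L, plus_bp = 0L))
  }
  p$span <- p$tend - p$tstart
  by_chrom <- p %>%
    group_by(.data$tname) %>%
    summarise(longest = max(.data$span), total = sum(.data$span),
              .groups = "drop") %>%
    arrange(dplyr::desc(.data$longest), dplyr::desc(.data$total), .data$tname)
  chrom <- by_chrom$tname[1]
  pc <- p[p$tname == chrom, ]
  tibble(
    chrom = chrom,
    longest_bp = max(pc$span),
    total_bp = sum(pc$span),
    span_start = min(pc$tstart), span_end = max(pc$tend),
    minus_bp = sum(pc$span[pc$strand == "-"]),
    plus_bp = sum(pc$span[pc$strand == "+"])
  )
}

#' Identify nested contigs to drop on one chromosome
#'
#' Contigs are processed in decreasing order of their longest alignment; a
#' contig is dropped iff its merged reference span is fully contained in the
#' span of an already-retained contig and its longest alignment is strictly
#' smaller. Partially overlapping contigs are both retained.
#'
#' @param assignments Tibble of contigs assigned to one chromosome, with
#'   columns `contig` (or first column as id), `longest_bp`, `span_start`,
#'   `span_end`.
#' @return Character vector of contig ids to drop.
#' @export
resolve_nesting <- function(assignments) {
  a <- assignments %>%
    arrange(dplyr::desc(.data$longest_bp), .data$span_start, .data$contig)
  drop <- character(0)
  kept <- list()
  for (i in seq_len(nrow(a))) {
    s <- a$span_start[i]; e <- a$span_end[i]
    nested <- any(vapply(kept, function(k) {
      s >= k$s && e <= k$e && a$longest_bp[i] < k$longest
    }, logical(1)))
    if (nested) {
      drop <- c(drop, a$contig[i])
    } else {
      kept[[length(kept) + 1L]] <- list(s = s, e = e, longest = a$longest_bp[i])
    }
  }
  drop
}

#' Curate a contig assembly from PAF alignments
#'
#' Applies the three filtering criteria — keep only contigs aligning to
#' known chromosomes, assign multi-chromosome contigs to the chromosome with
#' the longest alignment, and remove contigs nested inside larger retained
#' ones — then flips (reverse-complements) every kept contig whose aligned
#' bp on its assigned chromosome are mostly on the minus strand. Output is
#' ordered by (chromosome, reference span start).
#'
#' @param paf Full PAF tibble (see [read_paf()]).
#' @param fasta Named character vector (or `DNAStringSet`) of contig
#'   sequences; needed for every kept contig.
#' @param known_chroms Chromosomes contigs may be assigned to.
#' @return A list of class `curated_assembly`: `report` (one row per input
#'   contig: `contig`, `verdict`, `chrom`, `flipped`, `longest_bp`,
#'   `total_bp`, `span_start`, `span_end`) and `sequences` (named character
#'   vector of curated, strand-corrected contigs in output order).
#' @export
curate_assembly <- function(paf, fasta, known_chroms) {
  if (inherits(fasta, "DNAStringSet")) {
    fasta <- setNames(as.character(fasta), names(fasta))
  }
  contigs <- unique(paf$qname)
  asg <- lapply(setNames(contigs, contigs), function(ct) {
    assign_chromosome(paf[paf$qname == ct, , drop = FALSE], known_chroms)
  }) %>%
    bind_rows(.id = "contig")

  report <- asg %>%
    mutate(verdict = ifelse(is.na(.data$chrom), "drop-unplaced", "keep"),
           flipped = !is.na(.data$chrom) & .data$minus_bp > .data$plus_bp)

  for (ch in unique(stats::na.omit(report$chrom))) {
    sub <- report %>% filter(.data$verdict == "keep", .data$chrom == ch)
    dropped <- resolve_nesting(sub)
    report$verdict[report$contig %in% dropped] <- "drop-nested"
    report$flipped[report$contig %in% dropped] <- FALSE
  }

  kept <- report %>%
    filter(.data$verdict == "keep") %>%
    arrange(.data$chrom, .data$span_start, .data$contig)
  missing <- setdiff(kept$contig, names(fasta))
  if (length(missing) > 0L) {
    abort(paste("sequence missing for kept contigs:",
                paste(missing, collapse = ", ")))
  }
  seqs <- setNames(fasta[kept$contig], kept$contig)
  flip <- kept$flipped
  if (any(flip)) seqs[flip] <- vapply(seqs[flip], reverse_complement, character(1))

  structure(list(
    report = report %>%
      select("contig", "verdict", "chrom", "flipped", "longest_bp",
             "total_bp", "span_start", "span_end"),
    sequences = seqs
  ), class = "curated_assembly")
}

#' @export
print.curated_assembly <- function(x, ...) {
  cat(sprintf("<curated_assembly> %d contigs in, %d kept (%d flipped)\n",
              nrow(x$report), sum(x$report$verdict == "keep"),
              sum(x$report$flipped)))
  invisible(x)
}

#' Write a curated assembly to disk
#'
#' @param curated A `curated_assembly` object.
#' @param dir Output directory; writes `curated.fa` and `report.tsv`.
#' @return `dir`, invisibly.
#' @export
write_curated_assembly <- function(curated, dir) {
  stopifnot(inherits(curated, "curated_assembly"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(curated$sequences, file.path(dir, "curated.fa"))
  readr::write_tsv(curated$report, file.path(dir, "report.tsv"))
  invisible(dir)
}
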