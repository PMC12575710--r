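# Rule-based KZFP transcript classification, replacing the manual curation of
# transcript models with deterministic, testable criteria:
#   coding     — intact annotated start codon and an ORF encoding both a
#                KRAB-A box and at least one C2H2 finger
#   other      — intact start, no KRAB, but a finger-bearing ORF of at least
#                100 codons (residual coding potential)
#   pseudogene — a zinc-finger array is present but the start codon or the
#                KRAB module is lost
#   non-kzfp   — no zinc fingers at all

# Scan a translation that may contain stop codons: each stop-free segment is
# scanned separately so fingers never straddle a stop.
scan_translation <- function(protein, ...) {
  if (nchar(protein) == 0L) return(scan_c2h2(""))
  segs <- str_split(protein, stringr::fixed("*"))[[1]]
  offs <- cumsum(c(0L, nchar(segs) + 1L))
  res <- purrr::map2(segs, offs[seq_along(segs)], function(s, o) {
    f <- scan_c2h2(s, ...)
    if (nrow(f) > 0L) {
      f <- mutate(f, dplyr::across(c("start", "end", "c1", "c2", "h1", "h2"), ~ .x + o))
    }
    f
  })
  bind_rows(res)
}

# One frame's worth of candidate interpretations of a transcript.
frame_candidates <- function(tx_seq, frame) {
  trans <- translate_dna(substr(tx_seq, frame + 1L, nchar(tx_seq)))
  orf <- NULL
  m_pos <- regexpr("M", trans, fixed = TRUE)
  if (m_pos != -1L) {
    rest <- substr(trans, m_pos, nchar(trans))
    stop_pos <- regexpr("*", rest, fixed = TRUE)
    orf_seq <- if (stop_pos == -1L) rest else substr(rest, 1L, stop_pos - 1L)
    orf <- list(seq = orf_seq, aa_offset = as.integer(m_pos) - 1L)
  }
  list(frame = frame, translation = trans, orf = orf)
}

#' Classify a KZFP transcript from its exon structure
#'
#' Splices the transcript from the genome, inspects its three forward reading
#' frames, and applies the coding / other / pseudogene / non-kzfp rules (see
#' the file-level notes and the package vignette). The start codon is judged
#' intact when an annotated CDS is supplied and its spliced sequence begins
#' with ATG.
#'
#' @param exons Tibble of the transcript's exons with columns `chrom`,
#'   `start`, `end`, `strand` (all one chromosome/strand).
#' @param genome Named list/`DNAStringSet` of chromosome sequences.
#' @param cds Optional tibble of CDS intervals (same columns) used for the
#'   start-codon check; `NULL` means no annotated CDS, i.e. start absent.
#' @param krab_threshold Identity threshold passed to [detect_krab()].
#' @return A list with `class`, `n_fingers`, `fingerprint` (identity key),
#'   `flag_ch`, `flag_structural`, `zf_exon_rank` (see [find_zf_exon()]),
#'   `fingers` (the finger tibble of the reported translation), and
#'   `start_intact`.
#' @export
classify_transcript <- function(exons, genome, cds = NULL, krab_threshold = 0.6) {
  tx_seq <- spliced_seq(exons, genome)

  start_intact <- FALSE
  if (!is.null(cds) && nrow(cds) > 0L) {
    cds_seq <- spliced_seq(cds, genome)
    start_intact <- toupper(substr(cds_seq, 1L, 3L)) == "ATG"
  }

  frames <- lapply(0:2, function(f) frame_candidates(tx_seq, f))

  orf_info <- lapply(frames, function(fr) {
    if (is.null(fr$orf)) return(NULL)
    fingers <- scan_c2h2(fr$orf$seq)
    krab <- detect_krab(fr$orf$seq, threshold = krab_threshold)
    list(frame = fr$frame, aa_offset = fr$orf$aa_offset, seq = fr$orf$seq,
         fingers = fingers, krab = krab$found, n_codons = nchar(fr$orf$seq))
  })
  orf_info <- orf_info[!vapply(orf_info, is.null, logical(1))]

  frame_fingers <- lapply(frames, function(fr) scan_translation(fr$translation))
  fingers_any <- any(vapply(frame_fingers, nrow, integer(1)) > 0L)

  coding_orfs <- keep(orf_info, ~ .x$krab && nrow(.x$fingers) > 0L)
  long_zf_orfs <- keep(orf_info, ~ !.x$krab && nrow(.x$fingers) > 0L && .x$n_codons >= 100L)

  if (start_intact && length(coding_orfs) > 0L) {
    best <- coding_orfs[[which.max(vapply(coding_orfs, function(o) nrow(o$fingers), integer(1)))]]
    cls <- "coding"
    fingers <- best$fingers
    nt_base <- best$frame + 3L * best$aa_offset
  } else if (fingers_any && start_intact && length(long_zf_orfs) > 0L) {
    best <- long_zf_orfs[[which.max(vapply(long_zf_orfs, function(o) nrow(o$fingers), integer(1)))]]
    cls <- "other"
    fingers <- best$fingers
    nt_base <- best$frame + 3L * best$aa_offset
  } else if (fingers_any) {
    cls <- "pseudogene"
    k <- which.max(vapply(frame_fingers, nrow, integer(1)))
    fingers <- frame_fingers[[k]]
    nt_base <- frames[[k]]$frame
  } else {
    return(list(class = "non-kzfp", n_fingers = 0L, fingerprint = "",
                flag_ch = FALSE, flag_structural = FALSE,
                zf_exon_rank = NA_integer_, fingers = scan_c2h2(""),
                start_intact = start_intact))
  }

  zf_exon_rank <- zf_exon_from_fingers(fingers, nt_base, exons)
  list(
    class = cls,
    n_fingers = nrow(fingers),
    fingerprint = fingerprint_key(fingers$fingerprint),
    flag_ch = any(fingers$flag_ch_mutation),
    flag_structural = any(fingers$flag_structural_mutation),
    zf_exon_rank = zf_exon_rank,
    fingers = fingers,
    start_intact = start_intact
  )
}

# Assign each finger (aa interval in a translation whose first residue starts
# at transcript nt `nt_base + 1`) to the exon holding the majority of its
# nucleotides; return the rank of the exon with the most fingers (ties to the
# 3'-most exon). NA when no fingers.
zf_exon_from_fingers <- function(fingers, nt_base, exons) {
  if (nrow(fingers) == 0L) return(NA_integer_)
  ends <- exon_cumlen(exons)
  starts <- c(1L, head(ends, -1L) + 1L)
  assign_one <- function(aa_start, aa_end) {
    nt_s <- nt_base + 3L * (aa_start - 1L) + 1L
    nt_e <- nt_base + 3L * aa_end
    ov <- overlap_bp(nt_s, nt_e, starts, ends)
    if (all(ov == 0L)) return(NA_integer_)
    cand <- which(ov == max(ov))
    tail(cand, 1L)
  }
  ranks <- mapply(assign_one, fingers$start, fingers$end)
  ranks <- ranks[!is.na(ranks)]
  if (length(ranks) == 0L) return(NA_integer_)
  tab <- table(ranks)
  winners <- as.integer(names(tab)[tab == max(tab)])
  max(winners)
}

#' Locate the zinc-finger-array exon of a transcript
#'
#' Returns the 3'-most exon whose translation carries at least one finger;
#' when fingers are split across exons, the exon containing the majority of
#' fingers wins. `NA` when the transcript has no fingers.
#'
#' @inheritParams classify_transcript
#' @return Integer exon rank (1 = 5'-most exon in transcript order), or `NA`.
#' @export
find_zf_exon <- function(exons, genome, cds = NULL) {
  classify_transcript(exons, genome, cds = cds)$zf_exon_rank
}

#' Annotate every gene of a gene-model set
#'
#' Runs [classify_transcript()] on every transcript and summarises to one row
#' per gene: a gene's class is the most coding-like class among its
#' transcripts (coding > other > pseudogene > non-kzfp), and the fingerprint
#' array, finger count and zinc-finger exon are taken from that best
#' transcript. The zinc-finger exon's full DNA sequence (transcript
#' orientation, including any UTR) is returned as `exon3_seq` for downstream
#' duplication analysis.
#'
#' @param models A `gene_models` object (see [read_gene_models()]).
#' @param genome Named list/`DNAStringSet` of chromosome sequences.
#' @param krab_threshold Identity threshold passed to [detect_krab()].
#' @return A tibble with one row per gene: `gene_id`, `name`, `chrom`,
#'   `start`, `end`, `strand`, `class`, `n_fingers`, `fingerprint`,
#'   `flag_ch`, `flag_structural`, `zf_exon_rank`, `exon3_seq`, `tx_id`.
#' @export
annotate_genes <- function(models, genome, krab_threshold = 0.6) {
  stopifnot(inherits(models, "gene_models"))
  class_rank <- c(coding = 1L, other = 2L, pseudogene = 3L, `non-kzfp` = 4L)

  tx_rows <- purrr::pmap(models$transcripts, function(tx_id, gene_id) {
    ex <- filter(models$exons, .data$tx_id == !!tx_id)
    cd <- filter(models$cds, .data$tx_id == !!tx_id)
    res <- classify_transcript(ex, genome, cds = if (nrow(cd)) cd else NULL,
                               krab_threshold = krab_threshold)
    exon3_seq <- NA_character_
    if (!is.na(res$zf_exon_rank)) {
      e3 <- filter(ex, .data$exon_rank == res$zf_exon_rank)
      exon3_seq <- spliced_seq(e3, genome)
    }
    tibble(
      tx_id = tx_id, gene_id = gene_id, class = res$class,
      n_fingers = res$n_fingers, fingerprint = res$fingerprint,
      flag_ch = res$flag_ch, flag_structural = res$flag_structural,
      zf_exon_rank = res$zf_exon_rank, exon3_seq = exon3_seq
    )
  })
  tx_tbl <- bind_rows(tx_rows)

  best <- tx_tbl %>%
    mutate(rank = class_rank[.data$class]) %>%
    group_by(.data$gene_id) %>%
    arrange(.data$rank, dplyr::desc(.data$n_fingers), .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup() %>%
    select(-"rank")

  models$genes %>%
    select("gene_id", "name", "chrom", "start", "end", "strand") %>%
    inner_join(best, by = "gene_id") %>%
    arrange(.data$chrom, .data$start)
}
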