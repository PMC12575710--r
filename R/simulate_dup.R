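# Segmental duplication and contig fragmentation on a simulated genome.
# Both operations keep the ground-truth registry exactly in step with the
# sequence, which is what makes downstream recovery tests meaningful.

shift_tbl <- function(tbl, x, L, cols = c("start", "end")) {
  if (nrow(tbl) == 0L) return(tbl)
  for (cl in cols) {
    tbl[[cl]] <- ifelse(tbl[[cl]] >= x, tbl[[cl]] + L, tbl[[cl]])
  }
  tbl
}

#' Apply a segmental duplication to a simulated cluster
#'
#' Copies the genomic block spanning the given KZFP genes (extended to fully
#' include any TE copy it touches) to a new, feature-free position inside the
#' cluster locus, `rounds` times. Each inserted copy is independently mutated
#' at `post_rate` substitutions per base. Genes and TE copies inside the
#' block are registered in the ground truth as duplicates with
#' `origin = "duplication"` and parent links; the cluster chromosome grows by
#' the block length per round.
#'
#' @param sim A `kzfp_sim` object.
#' @param genes Integer indices (1-based, in cluster order) or `gene_id`s of
#'   the KZFP genes forming the block.
#' @param rounds Number of copies to insert (>= 1).
#' @param post_rate Per-base substitution probability applied to each
#'   inserted copy (0 gives byte-identical copies).
#' @param invert Logical; insert copies reverse-complemented (an inverted
#'   duplication). May be length 1 or `rounds`.
#' @param flank Margin (bp) added on both sides of the gene span when
#'   delimiting the source block.
#' @param avoid Optional tibble of intervals (`start`, `end`, cluster
#'   chromosome assumed) that insertion sites must additionally stay clear
#'   of — e.g. the source spans of other blocks still to be duplicated.
#' @return The updated `kzfp_sim` object.
#' @export
apply_segmental_duplication <- function(sim, genes, rounds = 1L, post_rate = 0,
                                        invert = FALSE, flank = 100L,
                                        avoid = NULL) {
  stopifnot(inherits(sim, "kzfp_sim"), post_rate >= 0, post_rate <= 1)
  rounds <- check_scalar_count(rounds, "rounds", min = 1L)
  invert <- rep_len(invert, rounds)

  tg <- sim$truth$genes
  kz <- tg %>% filter(.data$role == "kzfp") %>% arrange(.data$start)
  block_genes <- if (is.numeric(genes)) kz$gene_id[genes] else genes
  if (any(is.na(block_genes)) || !all(block_genes %in% kz$gene_id)) {
    abort("`genes` must identify planted KZFP genes")
  }
  chrom <- kz$chrom[1]

  block_id <- sprintf("block%d", length(unique(sim$truth$blocks$block_id)) + 1L)
  brows <- tg %>% filter(.data$gene_id %in% block_genes)
  src_s <- min(brows$start) - flank
  src_e <- max(brows$end) + flank

  # Grow the source to fully include straddling TE copies.
  repeat {
    te <- sim$truth$te_copies %>%
      filter(.data$chrom == !!chrom,
             overlap_bp(.data$start, .data$end, src_s, src_e) > 0L)
    new_s <- min(c(src_s, te$start)); new_e <- max(c(src_e, te$end))
    if (new_s == src_s && new_e == src_e) break
    src_s <- new_s; src_e <- new_e
  }
  outside <- tg %>%
    filter(.data$chrom == !!chrom, !.data$gene_id %in% block_genes,
           overlap_bp(.data$start, .data$end, src_s, src_e) > 0L)
  if (any(outside$role == "anchor")) {
    abort("refused: duplication block overlaps an anchor gene")
  }
  if (nrow(outside) > 0L) {
    abort("refused: duplication block partially overlaps genes outside the block")
  }

  src_members <- (tg %>% filter(.data$gene_id %in% block_genes) %>%
                    arrange(.data$start))$gene_id
  sim$truth$blocks <- bind_rows(
    sim$truth$blocks,
    tibble(block_id = block_id, occurrence = 0L, chrom = chrom,
           start = src_s, end = src_e, strand = "+",
           member_genes = paste(src_members, collapse = ","))
  )

  for (r in seq_len(rounds)) {
    anch <- sim$truth$genes %>% filter(.data$role == "anchor") %>% arrange(.data$start)
    locus_s <- anch$end[1] + 1L
    locus_e <- anch$start[2] - 1L

    # Candidate insertion sites: feature-free cluster positions with a 50 bp
    # margin, outside the source block.
    occ <- IRanges::reduce(IRanges::IRanges(
      start = c(sim$truth$genes$start[sim$truth$genes$chrom == chrom],
                sim$truth$te_copies$start[sim$truth$te_copies$chrom == chrom],
                sim$truth$blocks$start[sim$truth$blocks$chrom == chrom],
                if (!is.null(avoid)) avoid$start else integer(0),
                src_s),
      end = c(sim$truth$genes$end[sim$truth$genes$chrom == chrom],
              sim$truth$te_copies$end[sim$truth$te_copies$chrom == chrom],
              sim$truth$blocks$end[sim$truth$blocks$chrom == chrom],
              if (!is.null(avoid)) avoid$end else integer(0),
              src_e)
    ) + 50L)
    free <- IRanges::gaps(occ, start = locus_s, end = locus_e)
    free <- free[IRanges::width(free) >= 2L]
    if (length(free) == 0L) abort("layout error: no room to insert a duplication copy")
    pick <- sample.int(length(free), 1L, prob = IRanges::width(free))
    x <- IRanges::start(free)[pick] + sample.int(IRanges::width(free)[pick], 1L) - 1L

    # --- snapshot everything in pre-insertion coordinates --------------------
    parents <- sim$truth$genes %>%
      filter(.data$gene_id %in% src_members) %>% arrange(.data$start)
    parent_tx <- paste0(src_members, ".t1")
    parent_exons <- sim$models$exons %>% filter(.data$tx_id %in% parent_tx)
    parent_cds <- sim$models$cds %>% filter(.data$tx_id %in% parent_tx)
    src_tes <- sim$truth$te_copies %>%
      filter(.data$chrom == !!chrom, .data$start >= src_s, .data$end <= src_e)

    piece <- substr(sim$genome[[chrom]], src_s, src_e)
    Lb <- nchar(piece)
    n_sub <- rbinom(1L, Lb, post_rate)
    mut <- mutate_dna(piece, n_sub)
    mut_pos <- mut$pos
    copy_seq <- if (invert[r]) reverse_complement(mut$seq) else mut$seq

    # Map pre-insertion source coordinates to coordinates inside the copy.
    src2copy <- function(s, e) {
      if (!invert[r]) {
        tibble(start = x + (s - src_s), end = x + (e - src_s))
      } else {
        tibble(start = x + (src_e - e), end = x + (src_e - s))
      }
    }
    flip_strand <- function(st) {
      if (!invert[r]) st else ifelse(st == "+", "-", "+")
    }

    # --- insert sequence and shift existing annotation -----------------------
    g <- sim$genome[[chrom]]
    sim$genome[[chrom]] <- paste0(substr(g, 1L, x - 1L), copy_seq,
                                  substr(g, x, nchar(g)))
    for (nm in c("genes", "te_copies", "blocks")) {
      idx <- sim$truth[[nm]]$chrom == chrom
      sim$truth[[nm]][idx, ] <- shift_tbl(sim$truth[[nm]][idx, ], x, Lb)
    }
    for (nm in c("genes", "exons", "cds")) {
      m <- sim$models[[nm]]
      idx <- m$chrom == chrom
      m[idx, ] <- shift_tbl(m[idx, ], x, Lb)
      sim$models[[nm]] <- m
    }

    # --- clone gene models (coordinates from the pre-insertion snapshot) -----
    for (i in seq_along(src_members)) {
      gid <- src_members[i]
      grow <- parents[parents$gene_id == gid, ]
      cc <- src2copy(grow$start, grow$end)
      new_id <- sprintf("%s_%s_r%d", gid, block_id, r)
      new_strand <- flip_strand(grow$strand)
      was_mut <- length(mut_pos) > 0L &&
        any(mut_pos >= grow$start - src_s + 1L & mut_pos <= grow$end - src_s + 1L)

      sim$truth$genes <- bind_rows(sim$truth$genes, tibble(
        gene_id = new_id, name = paste0(grow$name, "-", block_id, "r", r),
        chrom = chrom, start = cc$start, end = cc$end, strand = new_strand,
        role = "kzfp", class = grow$class, n_fingers = grow$n_fingers,
        fingerprint = grow$fingerprint, block_id = block_id,
        origin = "duplication", parent_id = gid, mutated = was_mut
      ))
      sim$models$genes <- bind_rows(sim$models$genes, tibble(
        gene_id = new_id, name = paste0(grow$name, "-", block_id, "r", r),
        chrom = chrom, start = cc$start, end = cc$end, strand = new_strand,
        kzfp_class = grow$class
      ))
      new_tx <- paste0(new_id, ".t1")
      sim$models$transcripts <- bind_rows(sim$models$transcripts,
                                          tibble(tx_id = new_tx, gene_id = new_id))
      ex <- parent_exons %>% filter(.data$tx_id == paste0(gid, ".t1"))
      exg <- src2copy(ex$start, ex$end)
      sim$models$exons <- bind_rows(sim$models$exons, tibble(
        tx_id = new_tx, exon_rank = NA_integer_, chrom = chrom,
        start = exg$start, end = exg$end, strand = flip_strand(ex$strand)
      ))
      cd <- parent_cds %>% filter(.data$tx_id == paste0(gid, ".t1"))
      cdg <- src2copy(cd$start, cd$end)
      sim$models$cds <- bind_rows(sim$models$cds, tibble(
        tx_id = new_tx, chrom = chrom, start = cdg$start, end = cdg$end,
        strand = flip_strand(cd$strand)
      ))
    }
    sim$models$exons <- sim$models$exons %>%
      group_by(.data$tx_id) %>%
      arrange(if (dplyr::first(.data$strand) == "-") dplyr::desc(.data$start) else .data$start,
              .by_group = TRUE) %>%
      mutate(exon_rank = dplyr::row_number()) %>%
      ungroup()

    # --- clone TE copies -----------------------------------------------------
    if (nrow(src_tes) > 0L) {
      max_id <- nrow(sim$truth$te_copies)
      new_tes <- purrr::pmap(src_tes, function(...) {
        te <- list(...)
        cc <- src2copy(te$start, te$end)
        new_seq <- substr(sim$genome[[chrom]], cc$start, cc$end)
        new_strand <- flip_strand(te$strand)
        oriented <- if (new_strand == "-") reverse_complement(new_seq) else new_seq
        cons <- sim$consensi[[te$family]]
        tibble(copy_id = NA_character_, family = te$family, class = te$class,
               chrom = chrom, start = cc$start, end = cc$end,
               strand = new_strand,
               perc_div = percent_divergence(oriented, cons),
               origin = "duplication", parent_copy_id = te$copy_id)
      }) %>% bind_rows()
      new_tes$copy_id <- sprintf("te%05d", max_id + seq_len(nrow(new_tes)))
      sim$truth$te_copies <- bind_rows(sim$truth$te_copies, new_tes)
    }

    sim$truth$blocks <- bind_rows(sim$truth$blocks, tibble(
      block_id = block_id, occurrence = r, chrom = chrom,
      start = x, end = x + Lb - 1L,
      strand = if (invert[r]) "-" else "+",
      member_genes = paste(sprintf("%s_%s_r%d", src_members, block_id, r),
                           collapse = ",")
    ))

    # Keep the source interval valid for the next round: it shifts right when
    # the copy was inserted before it.
    if (src_s >= x) { src_s <- src_s + Lb; src_e <- src_e + Lb }
  }

  lens <- sim_chrom_lengths(sim)
  sim$repeats <- te_to_repeats(sim$truth$te_copies, lens)
  sim$config$chrom_lengths <- lens
  sim
}

#' Fragment a simulated genome into contigs with bookkept alignments
#'
#' Splits every chromosome at random breakpoints into tiling contigs,
#' reverse-complements each with probability `flip_probability`, and adds
#' `n_nested_extras` contigs that are proper sub-intervals of existing ones.
#' Alignments are emitted from exact coordinate bookkeeping (perfect PAF
#' blocks, `matches = block length`), so the curation logic downstream is
#' exercised without aligner noise.
#'
#' @param sim A `kzfp_sim` object.
#' @param n_breakpoints,flip_probability,n_nested_extras Override the values
#'   in `sim$config$fragmentation`.
#' @return The `kzfp_sim` with added `contigs` (named character vector),
#'   `paf` (tibble of the 12 mandatory PAF columns) and a filled
#'   `truth$contigs` table.
#' @export
fragment_into_contigs <- function(sim,
                                  n_breakpoints = NULL,
                                  flip_probability = NULL,
                                  n_nested_extras = NULL) {
  stopifnot(inherits(sim, "kzfp_sim"))
  fr <- sim$config$fragmentation
  n_breakpoints <- check_scalar_count(n_breakpoints %||% fr$n_breakpoints,
                                      "n_breakpoints")
  flip_probability <- flip_probability %||% fr$flip_probability
  n_nested_extras <- check_scalar_count(n_nested_extras %||% fr$n_nested_extras,
                                        "n_nested_extras")

  lens <- sim_chrom_lengths(sim)
  chroms <- names(lens)

  # Breakpoints uniform over the genome, then split per chromosome.
  total <- sum(lens)
  breaks <- if (n_breakpoints > 0L) {
    sort(unique(sample.int(total - 1L, min(n_breakpoints, total - 1L))))
  } else integer(0)
  offs <- cumsum(c(0, unname(as.numeric(lens))))
  pieces <- list()
  for (i in seq_along(chroms)) {
    local_b <- as.integer(breaks[breaks > offs[i] & breaks < offs[i + 1L]] - offs[i])
    bounds <- c(0L, local_b, lens[[i]])
    for (j in seq_len(length(bounds) - 1L)) {
      pieces[[length(pieces) + 1L]] <- list(chrom = chroms[i],
                                            start = bounds[j] + 1L,
                                            end = bounds[j + 1L],
                                            nested_in = NA_character_)
    }
  }

  # Nested extras: proper sub-intervals of randomly chosen main contigs.
  n_main <- length(pieces)
  for (k in seq_len(n_nested_extras)) {
    cand <- which(vapply(pieces[seq_len(n_main)],
                         function(p) p$end - p$start + 1L >= 200L, logical(1)))
    if (length(cand) == 0L) abort("no contig long enough to host a nested extra")
    host_i <- cand[sample_int1(length(cand))]
    host <- pieces[[host_i]]
    w <- host$end - host$start + 1L
    a <- host$start + sample.int(w %/% 4L, 1L)
    b <- host$end - sample.int(w %/% 4L, 1L)
    pieces[[length(pieces) + 1L]] <- list(chrom = host$chrom, start = a, end = b,
                                          nested_in = sprintf("ctg%04d", host_i))
  }

  contigs <- character(0)
  truth_rows <- list()
  paf_rows <- list()
  for (i in seq_along(pieces)) {
    p <- pieces[[i]]
    id <- sprintf("ctg%04d", i)
    seq <- substr(sim$genome[[p$chrom]], p$start, p$end)
    flipped <- runif(1L) < flip_probability
    if (flipped) seq <- reverse_complement(seq)
    contigs[[id]] <- seq
    w <- p$end - p$start + 1L
    truth_rows[[i]] <- tibble(contig_id = id, chrom = p$chrom,
                              start = p$start, end = p$end,
                              strand = if (flipped) "-" else "+",
                              nested_in = p$nested_in)
    paf_rows[[i]] <- tibble(
      qname = id, qlen = w, qstart = 0L, qend = w,
      strand = if (flipped) "-" else "+",
      tname = p$chrom, tlen = unname(lens[[p$chrom]]),
      tstart = p$start - 1L, tend = p$end,
      matches = w, alnlen = w, mapq = 60L
    )
  }

  sim$contigs <- contigs
  sim$paf <- bind_rows(paf_rows)
  sim$truth$contigs <- bind_rows(truth_rows)
  sim
}
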