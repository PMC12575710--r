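# Synthetic cluster-genome simulator. A simulation is a list (class
# "kzfp_sim") carrying the genome (named character vector), the gene models,
# the repeat annotation, per-family consensus sequences and a ground-truth
# registry of every planted feature. Downstream modules consume either the
# in-memory object or the files emitted by write_simulation().

#' Configure a cluster-genome simulation
#'
#' Collects and validates all simulation parameters. The first chromosome in
#' `chrom_lengths` carries the KZFP cluster (two anchor genes flanking the
#' planted KZFP genes); remaining chromosomes are background sequence that
#' receives its share of TE copies.
#'
#' @param seed Integer seed; a fixed seed makes every emitted byte
#'   reproducible.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param n_kzfp_genes Number of KZFP genes planted in the cluster.
#' @param fingers_per_gene Length-2 integer range; each gene draws its finger
#'   count uniformly from it.
#' @param te_families Tibble with one row per TE family: `family`, `class`
#'   (one of LTR/LINE/SINE/DNA), `consensus_length` (bp), `n_copies`,
#'   `mean_divergence` (percent), `divergence_sd` (percentage points of
#'   between-copy spread in target divergence).
#' @param anchor_genes Character pair naming the flanking anchor genes.
#' @param gene_gap_range Length-2 range of inter-gene gap sizes (bp) within
#'   the cluster.
#' @param fragmentation List with `n_breakpoints`, `flip_probability`,
#'   `n_nested_extras`, used by [fragment_into_contigs()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chrCl = 200000, chrBg1 = 300000, chrBg2 = 300000),
                       n_kzfp_genes = 10L,
                       fingers_per_gene = c(3L, 8L),
                       te_families = default_te_families(),
                       anchor_genes = c("Tnfrsf8", "Miip"),
                       gene_gap_range = c(800L, 2500L),
                       fragmentation = list(n_breakpoints = 6L,
                                            flip_probability = 0.3,
                                            n_nested_extras = 2L)) {
  stopifnot(length(chrom_lengths) >= 1L, !is.null(names(chrom_lengths)),
            all(chrom_lengths > 0), length(anchor_genes) == 2L,
            length(fingers_per_gene) == 2L,
            fingers_per_gene[1] >= 1L, fingers_per_gene[2] >= fingers_per_gene[1],
            gene_gap_range[1] > 0L, gene_gap_range[2] >= gene_gap_range[1])
  n_kzfp_genes <- check_scalar_count(n_kzfp_genes, "n_kzfp_genes")
  te_families <- as_tibble(te_families)
  needed <- c("family", "class", "consensus_length", "n_copies",
              "mean_divergence", "divergence_sd")
  if (!all(needed %in% names(te_families))) {
    abort(paste("te_families needs columns:", paste(needed, collapse = ", ")))
  }
  stopifnot(all(te_families$consensus_length > 0),
            all(te_families$n_copies >= 0),
            all(te_families$mean_divergence >= 0))
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 n_kzfp_genes = n_kzfp_genes,
                 fingers_per_gene = as.integer(fingers_per_gene),
                 te_families = te_families, anchor_genes = anchor_genes,
                 gene_gap_range = as.integer(gene_gap_range),
                 fragmentation = fragmentation),
            class = "sim_config")
}

#' Default TE family panel for simulations
#'
#' Three LTR/ERV-like families plus one LINE-like family with copy numbers,
#' consensus lengths and divergence levels in the range typical of young
#' murine repeat annotations at toy scale.
#'
#' @return A tibble accepted by [sim_config()].
#' @export
default_te_families <- function() {
  tibble(
    family = c("ERVm1", "ERVm2", "ERVm3", "L1mx"),
    class = c("LTR", "LTR", "LTR", "LINE"),
    consensus_length = c(500L, 400L, 350L, 800L),
    n_copies = c(60L, 50L, 40L, 80L),
    mean_divergence = c(5, 8, 12, 15),
    divergence_sd = c(2, 2.5, 3, 4)
  )
}

# Substitute `n` random distinct positions of `seq` to a different base.
mutate_dna <- function(seq, n) {
  len <- nchar(seq)
  n <- min(n, len)
  if (n == 0L) return(list(seq = seq, n_sub = 0L, pos = integer(0)))
  pos <- sort(sample.int(len, n))
  chars <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1L)
  }
  list(seq = paste(chars, collapse = ""), n_sub = n, pos = pos)
}

# Percent mismatch between two equal-length sequences.
percent_divergence <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  100 * sum(ca != cb) / length(ca)
}

# Paint `piece` onto `seq` starting at 1-based `at` (replacement, length kept).
paint <- function(seq, at, piece) {
  substr(seq, at, at + nchar(piece) - 1L) <- piece
  seq
}

#' Build a synthetic cluster genome with ground truth
#'
#' Lays out the cluster chromosome as anchor gene, KZFP genes in index order
#' separated by random gaps, anchor gene; places each TE family's copies
#' uniformly across the genome (chromosome chosen proportionally to length,
#' position uniform among feature-free space); and realises each copy's
#' divergence by Poisson-distributed substitutions from the family consensus
#' at a per-copy target drawn from
#' `Normal(mean_divergence, divergence_sd)` truncated at zero. All
#' coordinates are 1-based inclusive.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `kzfp_sim`: `genome` (named character vector),
#'   `models` (a `gene_models` object), `repeats` (repeat-annotation tibble
#'   in the same shape as [read_repeatmasker_out()] output), `consensi`
#'   (named character vector of family consensi), `truth` (list of tibbles
#'   `genes`, `te_copies`, `blocks`, `contigs`), and `config`.
#' @export
build_cluster_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  chroms <- names(config$chrom_lengths)
  cluster_chrom <- chroms[1]
  lens <- as.integer(config$chrom_lengths)
  names(lens) <- chroms

  # --- gene construction -----------------------------------------------------
  n <- config$n_kzfp_genes
  gene_objs <- vector("list", n + 2L)
  gene_meta <- vector("list", n + 2L)

  anchor1 <- make_anchor_gene()
  anchor2 <- make_anchor_gene()
  kzfps <- lapply(seq_len(n), function(i) {
    nf <- sample(seq(config$fingers_per_gene[1], config$fingers_per_gene[2]), 1L)
    make_kzfp_gene(nf)
  })

  # --- cluster layout --------------------------------------------------------
  gap <- function() sample(seq(config$gene_gap_range[1], config$gene_gap_range[2]), 1L)
  placements <- list()
  pos <- 2000L
  add_gene <- function(obj, name, role, strand) {
    placements[[length(placements) + 1L]] <<- list(
      obj = obj, name = name, role = role, strand = strand,
      chrom = cluster_chrom, start = pos
    )
    pos <<- pos + nchar(obj$dna) + gap()
  }
  add_gene(anchor1, config$anchor_genes[1], "anchor", "+")
  for (i in seq_len(n)) {
    add_gene(kzfps[[i]], sprintf("Kzfp%03d", i), "kzfp", sample(c("+", "-"), 1L))
  }
  add_gene(anchor2, config$anchor_genes[2], "anchor", "+")
  last <- placements[[length(placements)]]
  if (last$start + nchar(last$obj$dna) + 1000L > lens[cluster_chrom]) {
    abort("layout error: planted genes exceed the cluster chromosome length")
  }

  # --- genome backbones ------------------------------------------------------
  genome <- setNames(vapply(lens, random_dna, character(1)), chroms)

  gene_rows <- list(); tx_rows <- list(); exon_rows <- list(); cds_rows <- list()
  truth_gene_rows <- list()
  occupied <- lapply(setNames(chroms, chroms), function(x) IRanges::IRanges())

  for (k in seq_along(placements)) {
    p <- placements[[k]]
    L <- nchar(p$obj$dna)
    gid <- sprintf("gene%03d", k)
    seg <- if (p$strand == "+") p$obj$dna else reverse_complement(p$obj$dna)
    genome[[p$chrom]] <- paint(genome[[p$chrom]], p$start, seg)
    gstart <- p$start; gend <- p$start + L - 1L
    occupied[[p$chrom]] <- c(occupied[[p$chrom]], IRanges::IRanges(gstart, gend))

    rel2gen <- function(tbl) {
      if (p$strand == "+") {
        tibble(start = gstart + tbl$start - 1L, end = gstart + tbl$end - 1L)
      } else {
        tibble(start = gstart + L - tbl$end, end = gstart + L - tbl$start)
      }
    }
    ex <- rel2gen(p$obj$exons)
    cd <- rel2gen(p$obj$cds)
    cls <- if (p$role == "anchor") "non-kzfp" else "coding"

    gene_rows[[k]] <- tibble(gene_id = gid, name = p$name, chrom = p$chrom,
                             start = gstart, end = gend, strand = p$strand,
                             kzfp_class = cls)
    tx_rows[[k]] <- tibble(tx_id = paste0(gid, ".t1"), gene_id = gid)
    exon_rows[[k]] <- tibble(tx_id = paste0(gid, ".t1"), chrom = p$chrom,
                             start = ex$start, end = ex$end, strand = p$strand)
    cds_rows[[k]] <- tibble(tx_id = paste0(gid, ".t1"), chrom = p$chrom,
                            start = cd$start, end = cd$end, strand = p$strand)
    truth_gene_rows[[k]] <- tibble(
      gene_id = gid, name = p$name, chrom = p$chrom, start = gstart, end = gend,
      strand = p$strand, role = p$role, class = cls,
      n_fingers = p$obj$n_fingers, fingerprint = p$obj$fingerprint_key,
      block_id = NA_character_, origin = "planted",
      parent_id = NA_character_, mutated = FALSE
    )
  }

  # --- TE placement ----------------------------------------------------------
  consensi <- setNames(
    vapply(config$te_families$consensus_length, random_dna, character(1)),
    config$te_families$family
  )
  te_rows <- list()
  copy_counter <- 0L
  for (fi in seq_len(nrow(config$te_families))) {
    fam <- config$te_families[fi, ]
    cons <- consensi[[fam$family]]
    for (ci in seq_len(fam$n_copies)) {
      copy_counter <- copy_counter + 1L
      target_div <- max(0, rnorm(1L, fam$mean_divergence, fam$divergence_sd))
      n_sub <- rpois(1L, fam$consensus_length * target_div / 100)
      mut <- mutate_dna(cons, n_sub)
      realized <- percent_divergence(mut$seq, cons)
      strand <- sample(c("+", "-"), 1L)

      placed <- FALSE
      for (try in 1:200) {
        chrom <- sample(chroms, 1L, prob = lens)
        s <- sample.int(lens[[chrom]] - fam$consensus_length - 20L, 1L) + 10L
        e <- s + fam$consensus_length - 1L
        hit <- IRanges::countOverlaps(
          IRanges::IRanges(s - 10L, e + 10L), occupied[[chrom]])
        if (hit == 0L) {
          occupied[[chrom]] <- c(occupied[[chrom]], IRanges::IRanges(s, e))
          seg <- if (strand == "+") mut$seq else reverse_complement(mut$seq)
          genome[[chrom]] <- paint(genome[[chrom]], s, seg)
          te_rows[[copy_counter]] <- tibble(
            copy_id = sprintf("te%05d", copy_counter), family = fam$family,
            class = fam$class, chrom = chrom, start = s, end = e,
            strand = strand, perc_div = realized,
            origin = "insertion", parent_copy_id = NA_character_
          )
          placed <- TRUE
          break
        }
      }
      if (!placed) abort("layout error: could not place a TE copy (genome too dense)")
    }
  }
  te_tbl <- bind_rows(te_rows)

  models <- structure(list(
    genes = bind_rows(gene_rows),
    transcripts = bind_rows(tx_rows),
    exons = bind_rows(exon_rows) %>%
      group_by(.data$tx_id) %>%
      arrange(if (dplyr::first(.data$strand) == "-") dplyr::desc(.data$start) else .data$start,
              .by_group = TRUE) %>%
      mutate(exon_rank = dplyr::row_number()) %>%
      ungroup() %>%
      select("tx_id", "exon_rank", "chrom", "start", "end", "strand"),
    cds = bind_rows(cds_rows)
  ), class = "gene_models")

  structure(list(
    genome = genome,
    models = models,
    repeats = te_to_repeats(te_tbl, lens),
    consensi = consensi,
    truth = list(genes = bind_rows(truth_gene_rows), te_copies = te_tbl,
                 blocks = tibble(block_id = character(), occurrence = integer(),
                                 chrom = character(), start = integer(),
                                 end = integer(), strand = character(),
                                 member_genes = character()),
                 contigs = tibble(contig_id = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  strand = character(), nested_in = character())),
    config = config
  ), class = "kzfp_sim")
}

# Repeat-annotation tibble (the shape read_repeatmasker_out() returns) from
# the truth TE table.
te_to_repeats <- function(te_tbl, lens) {
  if (nrow(te_tbl) == 0L) {
    return(tibble(score = integer(), perc_div = numeric(), perc_del = numeric(),
                  perc_ins = numeric(), chrom = character(), begin = integer(),
                  end = integer(), left = integer(), strand = character(),
                  family = character(), class_family = character(),
                  rep_begin = integer(), rep_end = integer(), rep_left = integer(),
                  join_id = integer()))
  }
  te_tbl %>%
    transmute(
      score = 1000L,
      perc_div = round(.data$perc_div, 1),
      perc_del = 0, perc_ins = 0,
      chrom = .data$chrom, begin = .data$start, end = .data$end,
      left = as.integer(lens[.data$chrom] - .data$end),
      strand = .data$strand,
      family = .data$family,
      class_family = .data$class,
      rep_begin = 1L, rep_end = .data$end - .data$start + 1L, rep_left = 0L,
      join_id = dplyr::row_number()
    )
}

#' @export
print.kzfp_sim <- function(x, ...) {
  cat(sprintf("<kzfp_sim> %d chromosomes (%s bp), %d genes, %d TE copies\n",
              length(x$genome),
              format(sum(nchar(x$genome)), big.mark = ","),
              nrow(x$models$genes), nrow(x$truth$te_copies)))
  invisible(x)
}

#' Chromosome lengths of a simulation
#'
#' @param sim A `kzfp_sim` object.
#' @return Named integer vector of current chromosome lengths (these grow
#'   when segmental duplications are applied).
#' @export
sim_chrom_lengths <- function(sim) {
  vapply(sim$genome, nchar, integer(1))
}
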