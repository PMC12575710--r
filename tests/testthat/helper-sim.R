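# Shared fixtures: light-weight simulation configs and tiny constructors used
# across test files. Everything is generated in code under fixed seeds.

# A reduced TE panel so simulation-heavy tests stay fast.
light_te_families <- function() {
  tibble::tibble(
    family = c("ERVt1", "L1t1"),
    class = c("LTR", "LINE"),
    consensus_length = c(400L, 600L),
    n_copies = c(14L, 12L),
    mean_divergence = c(5, 12),
    divergence_sd = c(1.5, 3)
  )
}

quick_config <- function(seed, n_genes = 6L, cluster_len = 120000L,
                         bg_len = 80000L, te_families = light_te_families()) {
  sim_config(
    seed = seed,
    chrom_lengths = c(chrCl = cluster_len, chrBg1 = bg_len),
    n_kzfp_genes = n_genes,
    te_families = te_families
  )
}

quick_sim <- function(seed, ...) {
  build_cluster_genome(quick_config(seed, ...))
}

# Annotate a simulation and return only its KZFP-cluster genes (anchors out),
# in cluster order.
annotate_kzfps <- function(sim) {
  annot <- annotate_genes(sim$models, sim$genome)
  annot[!annot$name %in% sim$config$anchor_genes, , drop = FALSE]
}

# One random canonical C-x2-C-x12-H-x3-H finger embedded in filler sequence;
# returns the protein and the expected fingerprint by the 12-mer spacer
# index rule (positions 6, 8, 9, 12), which is the independent oracle for
# histidine-side anchoring.
random_canonical_finger <- function() {
  filler <- c("A", "D", "E", "F", "G", "I", "K", "L", "M", "N", "P",
              "Q", "R", "S", "T", "V", "W", "Y")
  spacer <- sample(filler, 12L, replace = TRUE)
  prot <- paste(c(sample(filler, 5L, replace = TRUE),
                  "C", sample(filler, 2L, replace = TRUE),
                  "C", spacer,
                  "H", sample(filler, 3L, replace = TRUE), "H",
                  sample(filler, 5L, replace = TRUE)), collapse = "")
  list(protein = prot,
       oracle_fingerprint = paste(spacer[c(6L, 8L, 9L, 12L)], collapse = ""))
}

# Plant a gene object on a toy one-chromosome genome at `at`, on `strand`;
# returns list(genome, models) ready for annotate_genes()/classify.
plant_gene <- function(gene, at = 501L, strand = "+", pad = 500L,
                       name = "GeneX", kzfp_class = NA_character_) {
  L <- nchar(gene$dna)
  set.seed(4242)
  backbone <- paste(sample(c("A", "C", "G", "T"), at + L + pad, replace = TRUE),
                    collapse = "")
  seg <- if (strand == "+") gene$dna else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(gene$dna)))
  substr(backbone, at, at + L - 1L) <- seg
  rel2gen <- function(tbl) {
    if (strand == "+") {
      tibble::tibble(start = at + tbl$start - 1L, end = at + tbl$end - 1L)
    } else {
      tibble::tibble(start = at + L - tbl$end, end = at + L - tbl$start)
    }
  }
  ex <- rel2gen(gene$exons)
  cd <- rel2gen(gene$cds)
  exons <- tibble::tibble(tx_id = "g1.t1", chrom = "chrT", start = ex$start,
                          end = ex$end, strand = strand)
  exons <- exons[order(if (strand == "-") -exons$start else exons$start), ]
  exons$exon_rank <- seq_len(nrow(exons))
  models <- structure(list(
    genes = tibble::tibble(gene_id = "g1", name = name, chrom = "chrT",
                           start = at, end = at + L - 1L, strand = strand,
                           kzfp_class = kzfp_class),
    transcripts = tibble::tibble(tx_id = "g1.t1", gene_id = "g1"),
    exons = exons[, c("tx_id", "exon_rank", "chrom", "start", "end", "strand")],
    cds = tibble::tibble(tx_id = "g1.t1", chrom = "chrT", start = cd$start,
                         end = cd$end, strand = strand)
  ), class = "gene_models")
  list(genome = c(chrT = backbone), models = models)
}
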