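# End-to-end validation experiments on simulated data with known ground
# truth. These drive both the package's acceptance tests and
# scripts/acceptance.R, so the exact experimental conditions live in one
# place. Problem sizes are chosen to give stable statistics at desk scale;
# see the methods vignette for the rationale behind each design.

validate_te_panel <- function() {
  tibble(
    family = c("ERVv1", "L1v1"),
    class = c("LTR", "LINE"),
    consensus_length = c(400L, 600L),
    n_copies = c(14L, 12L),
    mean_divergence = c(5, 12),
    divergence_sd = c(1.5, 3)
  )
}

# ERV-style panel for the duplication-signature experiment. Genome-wide,
# young ERV subfamilies show a broad continuum of per-copy divergence (copies
# accumulated mutations independently since insertion), so the between-copy
# spread is set wide relative to the copy number (~0.7 copies per percentage
# point); tight same-divergence groups then only arise from duplication.
signature_te_panel <- function() {
  tibble(
    family = c("ERVs1", "ERVs2"),
    class = c("LTR", "LTR"),
    consensus_length = c(450L, 400L),
    n_copies = c(20L, 20L),
    mean_divergence = c(10, 14),
    divergence_sd = c(6, 6)
  )
}

#' Round-trip validation of the simulator and annotation
#'
#' Builds a seeded cluster genome, annotates it from scratch, and scores how
#' many planted coding genes recover their class and exact fingerprint
#' array, and whether the distinct-array repertoire equals the ground truth.
#'
#' @param seed Simulation seed.
#' @param n_genes Number of planted KZFP genes (default 8).
#' @return One-row tibble: `seed`, `n_coding`, `class_ok`, `fingerprint_ok`,
#'   `distinct_arrays_match`.
#' @export
validate_roundtrip <- function(seed, n_genes = 8L) {
  cfg <- sim_config(seed = seed,
                    chrom_lengths = c(chrCl = 120000, chrBg1 = 80000),
                    n_kzfp_genes = n_genes,
                    te_families = validate_te_panel())
  sim <- build_cluster_genome(cfg)
  annot <- annotate_genes(sim$models, sim$genome)
  truth <- sim$truth$genes
  m <- inner_join(annot, truth %>%
                    select("gene_id", truth_class = "class",
                           truth_fp = "fingerprint", "role", "mutated"),
                  by = "gene_id")
  coding <- m %>% filter(.data$role == "kzfp", !.data$mutated,
                         .data$truth_class == "coding")
  da <- distinct_arrays(annot)
  truth_da <- truth %>%
    filter(.data$class == "coding", nzchar(.data$fingerprint)) %>%
    count(array = .data$fingerprint, name = "n") %>%
    arrange(dplyr::desc(.data$n), .data$array)
  tibble(seed = seed,
         n_coding = nrow(coding),
         class_ok = sum(coding$class == coding$truth_class),
         fingerprint_ok = sum(coding$fingerprint == coding$truth_fp),
         distinct_arrays_match = identical(da$array, truth_da$array) &&
           identical(da$n, truth_da$n))
}

#' Block-recovery validation on one seeded simulation
#'
#' Plants 1-3 duplicated gene blocks of 3-7 genes (post-duplication
#' substitution rate drawn up to `max_post_rate`) in a 30-gene cluster, runs
#' the full annotation, 3'exon-distance, grouping and block-detection
#' pipeline, and matches detected block occurrences against the planted ones
#' with a +/-1-gene boundary tolerance.
#'
#' @param seed Simulation seed (also drives the block layout).
#' @param n_genes Cluster gene count (default 30).
#' @param threshold Single-linkage grouping threshold (default 0.05).
#' @param max_post_rate Upper bound of the per-copy substitution rate
#'   (default 0.02).
#' @return A tibble with one row per planted block (`seed`, `block_id`,
#'   `n_genes`, `recovered`) and attribute `n_spurious`, the number of
#'   detected blocks of >= 3 genes not explained by any planted block.
#' @export
validate_block_recovery <- function(seed, n_genes = 30L, threshold = 0.05,
                                    max_post_rate = 0.02) {
  cfg <- sim_config(seed = seed,
                    chrom_lengths = c(chrCl = 420000, chrBg1 = 60000),
                    n_kzfp_genes = n_genes,
                    te_families = validate_te_panel())
  sim <- build_cluster_genome(cfg)

  # Experiment-level draws are decoupled from the simulation stream.
  set.seed(seed + 500001L)
  n_blocks <- sample(1:3, 1L)
  window <- n_genes %/% 3L
  planted <- list()
  for (k in seq_len(n_blocks)) {
    size <- sample(3:7, 1L)
    lo <- (k - 1L) * window + 1L
    start <- lo + sample.int(window - size, 1L) - 1L
    ids <- sprintf("gene%03d", (start:(start + size - 1L)) + 1L)  # +1: anchor first
    planted[[k]] <- list(size = size, ids = ids, rate = runif(1L, 0, max_post_rate))
  }
  for (k in seq_len(n_blocks)) {
    # keep insertion sites clear of every planted block's current gene span,
    # so no copy ever lands between the genes of a block
    avoid <- purrr::map(planted, function(p) {
      g <- sim$truth$genes %>% filter(.data$gene_id %in% p$ids)
      tibble(start = min(g$start) - 200L, end = max(g$end) + 200L)
    }) %>% bind_rows()
    sim <- apply_segmental_duplication(sim, genes = planted[[k]]$ids,
                                       rounds = 1L,
                                       post_rate = planted[[k]]$rate,
                                       avoid = avoid)
  }

  annot <- annotate_genes(sim$models, sim$genome)
  kz <- annot %>% filter(!.data$name %in% cfg$anchor_genes)
  D <- suppressWarnings(exon3_distances(kz))
  kz <- kz %>% filter(.data$gene_id %in% rownames(D))
  gr <- similarity_groups(D, threshold = threshold,
                          positions = setNames(kz$start, kz$gene_id))
  genes <- inner_join(kz %>% select("gene_id", "start"), gr, by = "gene_id") %>%
    arrange(.data$start)
  detected <- detect_blocks(genes, min_block_len = 3L)

  # positional index of every gene the pipeline worked with
  pos_of <- setNames(seq_len(nrow(genes)), genes$gene_id)

  truth_occ <- sim$truth$blocks %>%
    mutate(range = purrr::map(.data$member_genes, function(mg) {
      idx <- pos_of[strsplit(mg, ",")[[1]]]
      idx <- idx[!is.na(idx)]
      if (length(idx) == 0L) c(NA_integer_, NA_integer_) else range(idx)
    }),
    lo = purrr::map_int(.data$range, 1L),
    hi = purrr::map_int(.data$range, 2L))

  matches_occ <- function(first, last, lo, hi) {
    !is.na(lo) & abs(first - lo) <= 1L & abs(last - hi) <= 1L
  }

  det_ids <- unique(detected$block_id)
  # which planted occurrences does each detected occurrence explain?
  det_match <- detected %>%
    mutate(planted_block = purrr::map2_chr(
      .data$first_gene_index, .data$last_gene_index, function(f, l) {
        hit <- truth_occ %>%
          filter(matches_occ(f, l, .data$lo, .data$hi))
        if (nrow(hit) == 0L) NA_character_ else hit$block_id[1]
      }))

  recovered <- vapply(unique(sim$truth$blocks$block_id), function(b) {
    d <- det_match %>% filter(.data$planted_block == b)
    length(unique(d$occurrence)) >= 2L && length(unique(d$block_id)) >= 1L
  }, logical(1))

  spurious <- det_match %>%
    group_by(.data$block_id) %>%
    summarise(ok = sum(!is.na(.data$planted_block)) >= 2L, .groups = "drop")

  out <- tibble(seed = seed,
                block_id = unique(sim$truth$blocks$block_id),
                n_genes = vapply(planted, function(p) p$size, integer(1)),
                recovered = unname(recovered))
  attr(out, "n_spurious") <- sum(!spurious$ok)
  out
}

#' Calibration of the permutation null on data drawn from the null
#'
#' Generates `n_datasets` region sets whose placement follows the null
#' exactly (uniform starts on one chromosome) and records the permutation
#' p-value of each against a fixed locus; under a correct null the p-values
#' are (super-)uniform. Also compares the permutation mean against the exact
#' expectation obtained by exhaustive enumeration of all starts on a small
#' instance.
#'
#' @param seed RNG seed.
#' @param n_datasets Number of null datasets (default 500).
#' @param n_regions Regions per dataset (default 2000).
#' @param n_perm Permutations per dataset (default 999; large enough that
#'   ties between the observed count and permuted counts cannot distort the
#'   small-p tail of the rank distribution).
#' @return A list: `frac_le_05` (fraction of p-values <= 0.05), `p_values`,
#'   `enum_abs_error` and `enum_se` (absolute difference between permutation
#'   mean and the enumerated expectation, and its standard error).
#' @export
validate_null_calibration <- function(seed, n_datasets = 500L,
                                      n_regions = 2000L, n_perm = 999L) {
  set.seed(seed)
  chrom_len <- c(c1 = 10000L)
  locus <- tibble(chrom = "c1", start = 4001L, end = 6000L)
  width <- 50L
  pvals <- vapply(seq_len(n_datasets), function(i) {
    starts <- sample.int(chrom_len[[1]] - width + 1L, n_regions, replace = TRUE)
    regs <- tibble(chrom = "c1", start = starts, end = starts + width - 1L)
    permutation_overlap_test(regs, locus, chrom_len, n_perm = n_perm)$p_value
  }, numeric(1))

  # exhaustive-enumeration check on a <= 200 bp instance
  small_locus <- tibble(chrom = "c1", start = 26L, end = 75L)
  regs <- tibble(chrom = "c1", start = c(1L, 1L), end = c(10L, 20L))
  exact <- sum(vapply(c(10L, 20L), function(w) {
    s <- seq_len(100L - w + 1L)
    mean(s <= 75L & (s + w - 1L) >= 26L)
  }, numeric(1)))
  pt <- permutation_overlap_test(regs, small_locus, c(c1 = 100L),
                                 n_perm = 4000L)
  list(frac_le_05 = mean(pvals <= 0.05), p_values = pvals,
       enum_abs_error = abs(pt$null_mean - exact),
       enum_se = pt$null_sd / sqrt(pt$n_perm))
}

#' Duplication-versus-insertion signature on one seeded simulation
#'
#' Duplicates a TE-bearing three-gene block twice (no post-duplication
#' mutation) and measures the resulting change in the block family's cluster
#' enrichment and copy representation, plus the in-locus versus genome-wide
#' divergence-grouping contrast.
#'
#' @param seed Simulation seed.
#' @return One-row tibble: `seed`, `family`, `enrichment_before`,
#'   `enrichment_after`, `representation_before`, `representation_after`,
#'   `contrast` (in-locus minus genome-wide grouped divergence fraction).
#' @export
validate_duplication_signature <- function(seed) {
  cfg <- sim_config(seed = seed,
                    chrom_lengths = c(chrCl = 60000, chrBg1 = 30000),
                    n_kzfp_genes = 8L,
                    te_families = signature_te_panel())
  sim <- build_cluster_genome(cfg)
  loc <- locate_cluster(sim$models$genes)
  tg <- sim$truth$genes
  kz <- tg %>% filter(.data$role == "kzfp") %>% arrange(.data$start)
  te <- sim$truth$te_copies

  # Duplicate a three-gene window in which one family is concentrated: the
  # claim under test (duplication raises cluster enrichment) presupposes the
  # block carries the family at higher density than the locus average, which
  # is how the expanded blocks look in vivo. Among such windows take the one
  # with the highest block-to-locus density ratio; fall back to the highest
  # copy count when no window clears the locus average.
  locus_w <- loc$end - loc$start + 1L
  locus_density <- function(f) {
    r <- te[te$family == f & te$chrom == loc$chrom &
              te$start <= loc$end & te$end >= loc$start, ]
    sum(pmin(r$end, loc$end) - pmax(r$start, loc$start) + 1L) / locus_w
  }
  best <- list(score = -Inf, count = 0L, i = NULL, fam = NULL)
  for (i in seq_len(nrow(kz) - 2L)) {
    span <- c(kz$start[i] - 100L, kz$end[i + 2L] + 100L)
    inside <- te$chrom == kz$chrom[1] & te$start >= span[1] & te$end <= span[2]
    if (!any(inside)) next
    for (f in unique(te$family[inside])) {
      sel <- inside & te$family == f
      block_density <- sum(te$end[sel] - te$start[sel] + 1L) /
        (span[2] - span[1] + 1L)
      score <- block_density / locus_density(f)
      cnt <- sum(sel)
      better <- (score > 1 && score > best$score) ||
        (best$score <= 1 && cnt > best$count)
      if (better) best <- list(score = score, count = cnt, i = i, fam = f)
    }
  }
  if (is.null(best$i)) {
    abort("no TE copy between cluster genes for this seed; enlarge the panel")
  }
  pick <- best$i; fam <- best$fam

  e0 <- te_enrichment(sim$repeats, loc, sim_chrom_lengths(sim), families = fam)
  r0 <- family_representation(sim$repeats, loc, families = fam)
  sim2 <- apply_segmental_duplication(sim, genes = kz$gene_id[pick:(pick + 2L)],
                                      rounds = 3L, post_rate = 0)
  loc2 <- locate_cluster(sim2$models$genes)
  e1 <- te_enrichment(sim2$repeats, loc2, sim_chrom_lengths(sim2), families = fam)
  r1 <- family_representation(sim2$repeats, loc2, families = fam)
  dc <- divergence_contrast(sim2$repeats, loc2, fam)

  tibble(seed = seed, family = fam,
         enrichment_before = ifelse(is.na(e0$log2_enrichment), -Inf,
                                    e0$log2_enrichment),
         enrichment_after = e1$log2_enrichment,
         representation_before = r0$representation,
         representation_after = r1$representation,
         contrast = dc$contrast)
}

#' Curation validation on one seeded fragmentation
#'
#' Fragments a simulated genome into contigs (with optional nested extras
#' and random strand flips), curates the contigs from the bookkept PAF, and
#' checks the drop set and the chromosome reconstruction against the truth.
#'
#' @param seed Simulation seed.
#' @param n_nested Number of planted nested contigs (default 3).
#' @return One-row tibble: `seed`, `nested_exact` (dropped set equals the
#'   planted nested extras), `reconstruction_exact` (kept contigs
#'   concatenate to every chromosome byte-for-byte).
#' @export
validate_curation <- function(seed, n_nested = 3L) {
  cfg <- sim_config(seed = seed,
                    chrom_lengths = c(chrCl = 80000, chrBg1 = 60000),
                    n_kzfp_genes = 2L,
                    te_families = validate_te_panel())
  sim <- build_cluster_genome(cfg)
  sim <- fragment_into_contigs(sim, n_breakpoints = 6L,
                               flip_probability = 0.4,
                               n_nested_extras = n_nested)
  cur <- curate_assembly(sim$paf, sim$contigs, names(sim$genome))
  tr <- sim$truth$contigs
  nested_true <- tr$contig_id[!is.na(tr$nested_in)]
  dropped <- cur$report$contig[cur$report$verdict == "drop-nested"]

  kept <- cur$report %>% filter(.data$verdict == "keep") %>%
    arrange(.data$chrom, .data$span_start)
  rebuilt <- vapply(split(kept$contig, kept$chrom), function(ids) {
    paste(cur$sequences[ids], collapse = "")
  }, character(1))
  recon <- all(vapply(names(rebuilt), function(ch) {
    identical(rebuilt[[ch]], sim$genome[[ch]])
  }, logical(1)))

  tibble(seed = seed,
         nested_exact = setequal(nested_true, dropped),
         reconstruction_exact = recon)
}
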