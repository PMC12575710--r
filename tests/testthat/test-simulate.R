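# Simulator: layout, determinism, divergence realisation, segmental
# duplication bookkeeping and contig fragmentation.

test_that("a fixed config reproduces byte-identical outputs", {
  cfg <- quick_config(42, n_genes = 3L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- fragment_into_contigs(build_cluster_genome(cfg))
  s2 <- fragment_into_contigs(build_cluster_genome(cfg))
  # in-memory fragmentation draws come after build from the seeded stream
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in c("genome.fa", "genes.gff3", "repeats.out", "contigs.fa",
              "alignments.paf", "truth/genes.tsv", "truth/te_copies.tsv",
              "truth/contigs.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("zero KZFP genes leaves only the two anchors", {
  sim <- quick_sim(5, n_genes = 0L)
  expect_equal(nrow(sim$models$genes), 2L)
  expect_setequal(sim$models$genes$name, c("Tnfrsf8", "Miip"))
})

test_that("planted feature counts match the configuration", {
  fams <- light_te_families()
  sim <- quick_sim(8, n_genes = 10L, te_families = fams)
  expect_equal(nrow(sim$models$genes), 12L)            # 10 KZFPs + 2 anchors
  expect_equal(nrow(sim$repeats), sum(fams$n_copies))
  expect_equal(nrow(sim$truth$te_copies), sum(fams$n_copies))
  # anchors placed first and last on the cluster chromosome
  cl <- sim$models$genes[order(sim$models$genes$start), ]
  expect_equal(cl$name[1], "Tnfrsf8")
  expect_equal(cl$name[nrow(cl)], "Miip")
})

test_that("realised divergence matches the configured mean within 3 s.e.", {
  fams <- tibble::tibble(family = "ERVx", class = "LTR",
                         consensus_length = 500L, n_copies = 60L,
                         mean_divergence = 5, divergence_sd = 0)
  sim <- quick_sim(13, n_genes = 0L, cluster_len = 150000L, bg_len = 150000L,
                   te_families = fams)
  div <- sim$truth$te_copies$perc_div
  # per-copy substitutions ~ Poisson(L * 0.05): sd of % div = 100*sqrt(p/L)
  se_mean <- 100 * sqrt(0.05 / 500) / sqrt(60)
  expect_lt(abs(mean(div) - 5), 3 * se_mean + 0.05)
})

test_that("a zero-rate duplication copies the block byte for byte", {
  sim <- quick_sim(31, n_genes = 6L)
  sim2 <- apply_segmental_duplication(sim, genes = 2:4, rounds = 1L, post_rate = 0)
  b <- sim2$truth$blocks
  src <- b[b$occurrence == 0L, ]
  cp <- b[b$occurrence == 1L, ]
  chrom <- src$chrom
  expect_identical(substr(sim2$genome[[chrom]], src$start, src$end),
                   substr(sim2$genome[[chrom]], cp$start, cp$end))
  # duplicated TEs inherit the parent's divergence exactly
  dups <- sim2$truth$te_copies[sim2$truth$te_copies$origin == "duplication", ]
  if (nrow(dups) > 0L) {
    parent_div <- sim2$truth$te_copies$perc_div[
      match(dups$parent_copy_id, sim2$truth$te_copies$copy_id)]
    expect_equal(dups$perc_div, parent_div)
  }
  # every duplication-origin TE has a parent
  expect_true(all(!is.na(dups$parent_copy_id)))
})

test_that("duplication truth counts and cluster growth are exact", {
  sim <- quick_sim(32, n_genes = 8L)
  len0 <- sim_chrom_lengths(sim)[["chrCl"]]
  sim2 <- apply_segmental_duplication(sim, genes = 2:5, rounds = 2L, post_rate = 0)
  tg <- sim2$truth$genes
  expect_equal(sum(tg$origin == "duplication"), 8L)    # 4 genes x 2 rounds
  blk <- sim2$truth$blocks
  w <- blk$end[blk$occurrence == 0L] - blk$start[blk$occurrence == 0L] + 1L
  expect_equal(sim_chrom_lengths(sim2)[["chrCl"]], len0 + 2L * w)
  # occurrences must not overlap
  blk <- blk[order(blk$start), ]
  expect_true(all(blk$start[-1] > blk$end[-nrow(blk)]))
})

test_that("post-duplication mutation matches the binomial expectation", {
  sim <- quick_sim(33, n_genes = 6L, cluster_len = 150000L)
  rate <- 0.02
  sim2 <- apply_segmental_duplication(sim, genes = 2:5, rounds = 1L,
                                      post_rate = rate)
  b <- sim2$truth$blocks
  src <- b[b$occurrence == 0L, ]; cp <- b[b$occurrence == 1L, ]
  s1 <- strsplit(substr(sim2$genome[[src$chrom]], src$start, src$end), "")[[1]]
  s2 <- strsplit(substr(sim2$genome[[src$chrom]], cp$start, cp$end), "")[[1]]
  L <- length(s1)
  mism <- sum(s1 != s2)
  expect_lt(abs(mism / L - rate), 4 * sqrt(rate * (1 - rate) / L))
})

test_that("a block overlapping an anchor is refused", {
  sim <- quick_sim(34, n_genes = 3L)
  expect_error(
    apply_segmental_duplication(sim, genes = 1L, flank = 50000L),
    "anchor")
})

test_that("fragmentation tiles the genome and honours flip settings", {
  sim <- quick_sim(35, n_genes = 2L)
  s0 <- fragment_into_contigs(sim, n_breakpoints = 0L, flip_probability = 0,
                              n_nested_extras = 0L)
  expect_equal(nrow(s0$paf), length(sim$genome))
  expect_true(all(s0$paf$strand == "+"))
  expect_equal(sort(s0$paf$tname), sort(names(sim$genome)))

  s1 <- fragment_into_contigs(sim, n_breakpoints = 7L, flip_probability = 1,
                              n_nested_extras = 0L)
  expect_true(all(s1$paf$strand == "-"))
  # conservation: non-nested contigs tile each chromosome without overlap
  tr <- s1$truth$contigs[is.na(s1$truth$contigs$nested_in), ]
  by_chrom <- split(tr, tr$chrom)
  for (ch in names(by_chrom)) {
    x <- by_chrom[[ch]][order(by_chrom[[ch]]$start), ]
    expect_equal(x$start[1], 1L)
    expect_equal(x$end[nrow(x)], unname(sim_chrom_lengths(sim)[ch]))
    if (nrow(x) > 1L) expect_equal(x$start[-1], x$end[-nrow(x)] + 1L)
    expect_equal(sum(x$end - x$start + 1L),
                 unname(sim_chrom_lengths(sim)[ch]))
  }
  # flipped contig sequences are the reverse complement of their segment
  flipped <- s1$truth$contigs[1, ]
  seg <- substr(sim$genome[[flipped$chrom]], flipped$start, flipped$end)
  expect_identical(
    s1$contigs[[flipped$contig_id]],
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg))))
})

test_that("nested extras are proper sub-intervals of their hosts", {
  sim <- quick_sim(36, n_genes = 2L)
  s <- fragment_into_contigs(sim, n_breakpoints = 4L, flip_probability = 0.5,
                             n_nested_extras = 3L)
  tr <- s$truth$contigs
  nested <- tr[!is.na(tr$nested_in), ]
  expect_equal(nrow(nested), 3L)
  for (i in seq_len(nrow(nested))) {
    host <- tr[tr$contig_id == nested$nested_in[i], ]
    expect_equal(host$chrom, nested$chrom[i])
    expect_gt(nested$start[i], host$start)
    expect_lt(nested$end[i], host$end)
  }
})
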