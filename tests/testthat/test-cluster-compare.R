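# Cluster locus definition, repertoire comparison, 3'exon distances,
# similarity grouping and block detection.

toy_genes <- function(a_start, a_end, b_start, b_end,
                      strands = c("+", "+")) {
  tibble::tibble(gene_id = c("gA", "gB"), name = c("Tnfrsf8", "Miip"),
                 chrom = "chr1", start = c(a_start, b_start),
                 end = c(a_end, b_end), strand = strands)
}

test_that("the locus is the open interval between the anchor bodies", {
  loc <- locate_cluster(toy_genes(100L, 200L, 1000L, 1100L))
  expect_equal(loc$start, 201L)
  expect_equal(loc$end, 999L)
  # anchor strand does not matter
  loc2 <- locate_cluster(toy_genes(100L, 200L, 1000L, 1100L, c("-", "-")))
  expect_equal(c(loc2$start, loc2$end), c(201L, 999L))
  # coordinate order of the anchors does not matter either
  loc3 <- locate_cluster(toy_genes(1000L, 1100L, 100L, 200L))
  expect_equal(c(loc3$start, loc3$end), c(201L, 999L))
})

test_that("anchor resolution failures are reported", {
  g <- toy_genes(100L, 200L, 1000L, 1100L)
  expect_error(locate_cluster(g, upstream = "Nope"), "not found")
  g2 <- dplyr::bind_rows(g, g[1, ])
  expect_error(locate_cluster(g2), "matches 2")
  g3 <- g; g3$chrom[2] <- "chr2"
  expect_error(locate_cluster(g3), "different chromosomes")
})

test_that("the synthetic locus contains exactly the planted KZFP genes", {
  sim <- quick_sim(61, n_genes = 5L)
  loc <- locate_cluster(sim$models$genes)
  tg <- sim$truth$genes
  kz <- tg[tg$role == "kzfp", ]
  expect_true(all(kz$start >= loc$start & kz$end <= loc$end))
  anch <- tg[tg$role == "anchor", ]
  expect_true(all(anch$end < loc$start | anch$start > loc$end))
})

test_that("distinct_arrays counts identity keys with copy numbers", {
  annot <- tibble::tibble(
    gene_id = paste0("g", 1:4),
    class = c("coding", "coding", "coding", "pseudogene"),
    fingerprint = c("AAAA|BBBB", "AAAA|BBBB", "CCDD", "EEEE"))
  da <- distinct_arrays(annot)
  expect_equal(nrow(da), 2L)
  expect_equal(da$n[da$array == "AAAA|BBBB"], 2L)
  da_all <- distinct_arrays(annot, coding_only = FALSE)
  expect_equal(nrow(da_all), 3L)
})

test_that("repertoire sharing partitions each assembly's distinct set", {
  a <- tibble::tibble(array = c("X", "Y", "Z"), n = c(2L, 1L, 1L))
  b <- tibble::tibble(array = c("Y", "Z", "W"), n = c(1L, 3L, 1L))
  rc <- compare_repertoires(list(A = a, B = b))
  pw <- tidy(rc)
  expect_equal(pw$shared, 2L)
  expect_equal(pw$unique_a, 1L)
  expect_equal(pw$unique_b, 1L)
  expect_equal(pw$shared + pw$unique_a, nrow(a))
  expect_equal(pw$shared + pw$unique_b, nrow(b))
  expect_equal(pw$shared_equal_copy, 1L)   # Y at equal copy number, Z not

  same <- compare_repertoires(list(A = a, B = a))
  expect_equal(tidy(same)$shared, 3L)
  expect_equal(tidy(same)$unique_a, 0L)
  disjoint <- compare_repertoires(list(
    A = a, B = tibble::tibble(array = "Q", n = 1L)))
  expect_equal(tidy(disjoint)$shared, 0L)
})

test_that("3'exon distances behave like alignment identities", {
  set.seed(71)
  base <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  mut <- kzfpscape:::mutate_dna(base, 12L)$seq   # 2% of 600
  rand <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  annot <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g4"),
                          exon3_seq = c(base, base, mut, rand))
  D <- exon3_distances(annot)
  expect_equal(unname(diag(D)), rep(0, 4))
  expect_equal(D["g1", "g2"], 0)
  expect_lt(abs(D["g1", "g3"] - 0.02), 0.012)
  expect_gt(D["g1", "g4"], 0.5)
  expect_true(isSymmetric(D))
})

test_that("genes without a zinc-finger exon are excluded with a warning", {
  annot <- tibble::tibble(gene_id = c("g1", "g2"),
                          exon3_seq = c("ACGTACGT", NA))
  expect_warning(D <- exon3_distances(annot), "g2")
  expect_equal(rownames(D), "g1")
  expect_equal(attr(D, "excluded"), "g2")
})

test_that("single-linkage grouping honours the threshold", {
  D0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(unique(similarity_groups(D0)$group), 1L)
  D1 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(D1) <- 0
  expect_equal(sort(similarity_groups(D1)$group), 1:3)
  # chaining: a-b close, b-c close, a-c far => one group under single linkage
  D2 <- matrix(c(0, .01, .2, .01, 0, .01, .2, .01, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(unique(similarity_groups(D2, threshold = 0.05)$group), 1L)
})

test_that("detect_blocks finds repeated label runs by definition", {
  g <- tibble::tibble(gene_id = paste0("g", 1:7),
                      start = (1:7) * 1000,
                      group = c(1L, 2L, 3L, 4L, 1L, 2L, 3L))
  bl <- detect_blocks(g)
  expect_equal(length(unique(bl$block_id)), 1L)
  expect_equal(nrow(bl), 2L)
  expect_equal(bl$n_genes, c(3L, 3L))
  expect_equal(bl$first_gene_index, c(1L, 5L))

  none <- detect_blocks(tibble::tibble(gene_id = paste0("g", 1:5),
                                       start = (1:5) * 10,
                                       group = 1:5))
  expect_equal(nrow(none), 0L)
})

test_that("inverted repeats are reported as reverted occurrences", {
  g <- tibble::tibble(gene_id = paste0("g", 1:8),
                      start = (1:8) * 100,
                      group = c(1L, 2L, 3L, 9L, 3L, 2L, 1L, 9L))
  bl <- detect_blocks(g)
  expect_equal(nrow(bl), 2L)
  expect_setequal(bl$orientation, c("forward", "reverted"))
})

test_that("length-2 repeats are partial candidates, not blocks", {
  g <- tibble::tibble(gene_id = paste0("g", 1:6),
                      start = (1:6) * 100,
                      group = c(1L, 2L, 7L, 8L, 1L, 2L))
  bl <- detect_blocks(g, min_block_len = 3L)
  expect_equal(nrow(bl), 0L)
  partials <- attr(bl, "partials")
  expect_equal(nrow(partials), 2L)
  expect_equal(unique(partials$n_genes), 2L)
})

test_that("block detection is invariant under coordinate translation", {
  g <- tibble::tibble(gene_id = paste0("g", 1:7),
                      start = (1:7) * 1000,
                      group = c(1L, 2L, 3L, 4L, 1L, 2L, 3L))
  b1 <- detect_blocks(g)
  g2 <- g; g2$start <- g2$start + 5e6
  b2 <- detect_blocks(g2)
  expect_equal(b2$first_gene_index, b1$first_gene_index)
  expect_equal(b2$gene_ids, b1$gene_ids)
})

test_that("a planted duplication is recovered through the full pipeline", {
  sim <- quick_sim(62, n_genes = 9L, cluster_len = 150000L)
  sim <- apply_segmental_duplication(sim, genes = 3:5, rounds = 1L,
                                     post_rate = 0.01)
  kz <- annotate_kzfps(sim)
  D <- exon3_distances(kz)
  gr <- similarity_groups(D, positions = setNames(kz$start, kz$gene_id))
  genes <- dplyr::inner_join(kz[, c("gene_id", "start")], gr, by = "gene_id")
  bl <- detect_blocks(genes)
  expect_equal(length(unique(bl$block_id)), 1L)
  expect_equal(nrow(bl), 2L)
  # the duplicated genes co-group with their parents
  tg <- sim$truth$genes
  dup <- tg[tg$origin == "duplication", ]
  for (i in seq_len(nrow(dup))) {
    gd <- gr$group[gr$gene_id == dup$gene_id[i]]
    gp <- gr$group[gr$gene_id == dup$parent_id[i]]
    if (length(gd) == 1L && length(gp) == 1L) expect_equal(gd, gp)
  }
})
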