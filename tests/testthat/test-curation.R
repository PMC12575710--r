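# Contig curation: chromosome assignment, nesting resolution, strand
# correction and full-genome recovery on simulated fragmentations.

paf_row <- function(q, t, tstart, tend, strand = "+", qlen = 1000L) {
  tibble::tibble(qname = q, qlen = qlen, qstart = 0L, qend = tend - tstart,
                 strand = strand, tname = t, tlen = 10000000L,
                 tstart = tstart, tend = tend,
                 matches = tend - tstart, alnlen = tend - tstart, mapq = 60L)
}

test_that("a contig goes to the chromosome with the longest alignment block", {
  paf <- dplyr::bind_rows(paf_row("ctg", "chr1", 0L, 5000000L),
                          paf_row("ctg", "chr2", 0L, 1000000L))
  a <- assign_chromosome(paf, c("chr1", "chr2"))
  expect_equal(a$chrom, "chr1")
  expect_equal(a$longest_bp, 5000000L)
})

test_that("contigs aligning only to unknown targets are unplaced", {
  paf <- paf_row("ctg", "scaffold_17", 0L, 100000L)
  a <- assign_chromosome(paf, c("chr1", "chr2"))
  expect_true(is.na(a$chrom))
})

test_that("ties on longest block break by total bp, then name", {
  paf <- dplyr::bind_rows(
    paf_row("ctg", "chr1", 0L, 1000L),
    paf_row("ctg", "chr2", 0L, 1000L),
    paf_row("ctg", "chr2", 5000L, 6000L))
  expect_equal(assign_chromosome(paf, c("chr1", "chr2"))$chrom, "chr2")
  paf2 <- dplyr::bind_rows(paf_row("ctg", "chr2", 0L, 1000L),
                           paf_row("ctg", "chr1", 0L, 1000L))
  expect_equal(assign_chromosome(paf2, c("chr1", "chr2"))$chrom, "chr1")
})

test_that("nested spans are dropped, partial overlaps retained", {
  asg <- tibble::tibble(contig = c("big", "small"),
                        longest_bp = c(100L, 10L),
                        span_start = c(0L, 10L), span_end = c(100L, 20L))
  expect_equal(resolve_nesting(asg), "small")
  asg2 <- tibble::tibble(contig = c("left", "right"),
                         longest_bp = c(60L, 60L),
                         span_start = c(0L, 40L), span_end = c(60L, 100L))
  expect_equal(resolve_nesting(asg2), character(0))
})

test_that("nesting resolution equals a brute-force containment oracle", {
  brute <- function(asg) {
    # a contig is nested iff contained in a retained contig with strictly
    # larger longest alignment; retained = not nested (fixed point from the
    # largest down)
    ord <- order(-asg$longest_bp, asg$span_start, asg$contig)
    a <- asg[ord, ]
    kept <- logical(nrow(a))
    for (i in seq_len(nrow(a))) {
      kept[i] <- !any(kept[seq_len(i - 1L)] &
                        a$span_start[seq_len(i - 1L)] <= a$span_start[i] &
                        a$span_end[seq_len(i - 1L)] >= a$span_end[i] &
                        a$longest_bp[seq_len(i - 1L)] > a$longest_bp[i])
    }
    sort(a$contig[!kept])
  }
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(2:30, 1)
    s <- sample.int(100000L, n)
    w <- sample.int(50000L, n)
    asg <- tibble::tibble(contig = sprintf("c%02d", seq_len(n)),
                          longest_bp = w, span_start = s, span_end = s + w)
    expect_equal(sort(resolve_nesting(asg)), brute(asg))
  }
})

test_that("minus-strand contigs are emitted reverse-complemented", {
  seqs <- c(ctgA = "ACGTACGTTT")
  paf <- paf_row("ctgA", "chr1", 100L, 110L, strand = "-", qlen = 10L)
  cur <- curate_assembly(paf, seqs, "chr1")
  expect_true(cur$report$flipped)
  expect_equal(unname(cur$sequences[["ctgA"]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString("ACGTACGTTT"))))
  # all-plus contig passes through byte-identical
  cur2 <- curate_assembly(paf_row("ctgA", "chr1", 100L, 110L), seqs, "chr1")
  expect_equal(unname(cur2$sequences[["ctgA"]]), "ACGTACGTTT")
})

test_that("planted nested extras are exactly the contigs dropped", {
  sim <- fragment_into_contigs(quick_sim(41, n_genes = 2L),
                               n_breakpoints = 5L, flip_probability = 0.3,
                               n_nested_extras = 3L)
  cur <- curate_assembly(sim$paf, sim$contigs, names(sim$genome))
  tr <- sim$truth$contigs
  expect_setequal(cur$report$contig[cur$report$verdict == "drop-nested"],
                  tr$contig_id[!is.na(tr$nested_in)])
  # every input contig appears exactly once in the report
  expect_setequal(cur$report$contig, tr$contig_id)
  expect_equal(anyDuplicated(cur$report$contig), 0L)
})

test_that("curation reconstructs each chromosome exactly", {
  sim <- fragment_into_contigs(quick_sim(42, n_genes = 2L),
                               n_breakpoints = 6L, flip_probability = 0.5,
                               n_nested_extras = 0L)
  cur <- curate_assembly(sim$paf, sim$contigs, names(sim$genome))
  kept <- cur$report[cur$report$verdict == "keep", ]
  kept <- kept[order(kept$chrom, kept$span_start), ]
  rebuilt <- vapply(split(kept$contig, kept$chrom), function(ids) {
    paste(cur$sequences[ids], collapse = "")
  }, character(1))
  for (ch in names(rebuilt)) {
    expect_identical(rebuilt[[ch]], sim$genome[[ch]])
  }
})

test_that("curating a curated assembly changes nothing", {
  sim <- fragment_into_contigs(quick_sim(43, n_genes = 2L),
                               n_breakpoints = 4L, flip_probability = 0.6,
                               n_nested_extras = 2L)
  cur <- curate_assembly(sim$paf, sim$contigs, names(sim$genome))
  kept <- cur$report[cur$report$verdict == "keep", ]
  # exact bookkeeping of the curated contigs: all plus strand by construction
  paf2 <- tibble::tibble(
    qname = kept$contig, qlen = kept$span_end - kept$span_start,
    qstart = 0L, qend = kept$span_end - kept$span_start,
    strand = "+", tname = kept$chrom, tlen = 10000000L,
    tstart = kept$span_start, tend = kept$span_end,
    matches = kept$span_end - kept$span_start,
    alnlen = kept$span_end - kept$span_start, mapq = 60L)
  cur2 <- curate_assembly(paf2, cur$sequences, names(sim$genome))
  expect_true(all(cur2$report$verdict == "keep"))
  expect_false(any(cur2$report$flipped))
  expect_identical(cur2$sequences, cur$sequences)
})

test_that("a missing sequence for a kept contig errors", {
  paf <- paf_row("ctgZ", "chr1", 0L, 1000L)
  expect_error(curate_assembly(paf, c(other = "ACGT"), "chr1"), "ctgZ")
})
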