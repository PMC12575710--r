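# TE enrichment, permutation null, representation, display filter and the
# divergence-based duplication signature.

test_that("the enrichment ratio reproduces forced arithmetic", {
  reps <- tibble::tibble(chrom = c("c1", "c2"), begin = c(100001L, 1L),
                         end = c(110000L, 90000L), family = "F", join_id = 1:2)
  locus <- tibble::tibble(chrom = "c1", start = 100001L, end = 1100000L)
  e <- te_enrichment(reps, locus, c(c1 = 5e7, c2 = 5e7))
  # 10 kb in a 1 Mb locus vs 100 kb in a 100 Mb genome: log2(10)
  expect_equal(e$log2_enrichment, log2(10), tolerance = 1e-12)

  # equal densities give zero
  reps2 <- tibble::tibble(chrom = "c1", begin = c(1L, 200001L),
                          end = c(100L, 200100L), family = "F", join_id = 1:2)
  locus2 <- tibble::tibble(chrom = "c1", start = 1L, end = 100000L)
  e2 <- te_enrichment(reps2, locus2, c(c1 = 2e5))
  expect_equal(e2$log2_enrichment, 0)
})

test_that("locus-absent families carry the absent sentinel", {
  reps <- tibble::tibble(chrom = "c2", begin = 1L, end = 100L,
                         family = "F", join_id = 1L)
  locus <- tibble::tibble(chrom = "c1", start = 1L, end = 1000L)
  e <- te_enrichment(reps, locus, c(c1 = 1e5, c2 = 1e5))
  expect_true(e$absent)
  expect_true(is.na(e$log2_enrichment))
  # family with no genome-wide bp is skipped with a warning
  expect_warning(
    e0 <- te_enrichment(reps, locus, c(c1 = 1e5, c2 = 1e5), families = "G"),
    "skipped")
  expect_equal(nrow(e0), 0L)
})

test_that("enrichment is invariant under coordinate scaling", {
  reps <- tibble::tibble(chrom = "c1", begin = c(11L, 501L), end = c(110L, 600L),
                         family = "F", join_id = 1:2)
  locus <- tibble::tibble(chrom = "c1", start = 1L, end = 300L)
  e1 <- te_enrichment(reps, locus, c(c1 = 1000L))
  reps2 <- dplyr::mutate(reps, begin = .data$begin * 2L - 1L, end = .data$end * 2L)
  locus2 <- tibble::tibble(chrom = "c1", start = 1L, end = 600L)
  e2 <- te_enrichment(reps2, locus2, c(c1 = 2000L))
  expect_equal(e2$log2_enrichment, e1$log2_enrichment, tolerance = 1e-12)
})

test_that("overlapping annotations are merged before counting bp", {
  reps <- tibble::tibble(chrom = "c1", begin = c(1L, 51L), end = c(100L, 150L),
                         family = "F", join_id = 1:2)
  locus <- tibble::tibble(chrom = "c1", start = 1L, end = 200L)
  e <- te_enrichment(reps, locus, c(c1 = 1000L))
  expect_equal(e$bp_locus, 150L)
})

test_that("maximal and degenerate permutation cases give forced p-values", {
  locus <- tibble::tibble(chrom = "c1", start = 500000L, end = 1500000L)
  regs <- tibble::tibble(chrom = "c1", start = rep(600000L, 5),
                         end = rep(600100L, 5))
  pt <- permutation_overlap_test(regs, locus, c(c1 = 1e8), n_perm = 1000,
                                 seed = 4)
  expect_equal(pt$observed, 5L)
  expect_equal(pt$p_value, 1 / 1001)

  whole <- tibble::tibble(chrom = "c1", start = 1L, end = 1e8)
  pt2 <- permutation_overlap_test(regs, whole, c(c1 = 1e8), n_perm = 200,
                                  seed = 4)
  expect_equal(pt2$p_value, 1)
  expect_true(all(pt2$perm == pt2$observed))

  expect_error(
    permutation_overlap_test(
      tibble::tibble(chrom = "c1", start = 1L, end = 200L), locus,
      c(c1 = 100L)),
    "longer than its chromosome")
})

test_that("the permutation mean matches exhaustive enumeration", {
  # 2 regions (widths 10 and 20) on a 100 bp chromosome, locus [26, 75]:
  # enumerate every legal start to get the exact expected overlap count.
  locus <- tibble::tibble(chrom = "c1", start = 26L, end = 75L)
  regs <- tibble::tibble(chrom = "c1", start = c(1L, 1L), end = c(10L, 20L))
  exact_one <- function(w) {
    starts <- seq_len(100L - w + 1L)
    mean(starts <= 75L & (starts + w - 1L) >= 26L)
  }
  exact <- exact_one(10L) + exact_one(20L)
  pt <- permutation_overlap_test(regs, locus, c(c1 = 100L), n_perm = 4000,
                                 seed = 10)
  se <- pt$null_sd / sqrt(pt$n_perm)
  expect_lt(abs(pt$null_mean - exact), 3 * se + 1e-9)
})

test_that("permutation results are reproducible under a seed", {
  locus <- tibble::tibble(chrom = "c1", start = 100L, end = 400L)
  regs <- tibble::tibble(chrom = "c1", start = c(50L, 300L), end = c(80L, 350L))
  a <- permutation_overlap_test(regs, locus, c(c1 = 1000L), n_perm = 100, seed = 7)
  b <- permutation_overlap_test(regs, locus, c(c1 = 1000L), n_perm = 100, seed = 7)
  expect_identical(a$perm, b$perm)
  expect_identical(tidy(a), tidy(b))
})

test_that("family representation counts joined copies once", {
  locus <- tibble::tibble(chrom = "c1", start = 1000L, end = 2000L)
  reps <- tibble::tibble(
    chrom = "c1",
    begin = c(1100L, 1300L, 5000L, 6000L, 7000L, 900L, 2100L),
    end   = c(1200L, 1400L, 5100L, 6100L, 7100L, 1050L, 2200L),
    family = "F",
    join_id = c(1L, 1L, 2L, 3L, 4L, 5L, 5L))
  fr <- family_representation(reps, locus)
  # join 1: two fragments inside = one copy in; joins 2-4 out; join 5
  # straddles the boundary with one fragment overlapping = one copy in
  expect_equal(fr$copies_total, 5L)
  expect_equal(fr$copies_in_locus, 2L)
  expect_equal(fr$representation, 0.4)

  all_in <- family_representation(
    tibble::tibble(chrom = "c1", begin = c(1100L, 1500L), end = c(1150L, 1600L),
                   family = "F", join_id = 1:2), locus)
  expect_equal(all_in$representation, 1)
})

test_that("display selection needs both >2% share and >10 in-locus rows", {
  locus <- tibble::tibble(chrom = "c1", start = 1L, end = 10000L)
  mk <- function(fam, n_in, n_out) {
    tibble::tibble(
      chrom = "c1",
      begin = c(seq(1L, by = 20L, length.out = n_in),
                seq(20001L, by = 20L, length.out = n_out)),
      end = c(seq(10L, by = 20L, length.out = n_in),
              seq(20010L, by = 20L, length.out = n_out)),
      family = fam,
      join_id = seq_len(n_in + n_out))
  }
  reps <- dplyr::bind_rows(
    mk("pass", 12L, 388L),    # 3% and 12 annotations -> selected
    mk("few", 8L, 258L),      # 3% but only 8 annotations -> rejected
    mk("dilute", 50L, 4950L)) # 50 annotations but 1% -> rejected
  reps$join_id <- seq_len(nrow(reps))
  expect_equal(select_display_families(reps, locus, min_fraction = 0.02,
                                       min_annotations = 10L),
               "pass")
})

test_that("duplication_signature groups near-identical divergences", {
  g <- duplication_signature(c(5.1, 5.1, 5.2, 12.3), tolerance = 0.5,
                             min_group = 3L)
  expect_equal(nrow(g), 1L)
  expect_equal(g$n, 3L)
  expect_equal(g$mean_divergence, mean(c(5.1, 5.1, 5.2)))
  expect_equal(attr(g, "grouped_fraction"), 0.75)

  spread <- duplication_signature(seq(1, 20, by = 1), tolerance = 0.5)
  expect_equal(nrow(spread), 0L)
  expect_equal(attr(spread, "grouped_fraction"), 0)
})

test_that("segmental duplication leaves a locus-specific divergence signature", {
  sim <- quick_sim(91, n_genes = 8L, cluster_len = 60000L, bg_len = 30000L)
  loc <- locate_cluster(sim$models$genes)
  # choose a gene block that spans at least 3 TE copies of one family
  tg <- sim$truth$genes
  kz <- tg[tg$role == "kzfp", ]
  kz <- kz[order(kz$start), ]
  te <- sim$truth$te_copies
  pick <- NULL
  for (i in seq_len(nrow(kz) - 2L)) {
    span <- c(kz$start[i] - 100L, kz$end[i + 2L] + 100L)
    inside <- te$chrom == kz$chrom[1] & te$start >= span[1] & te$end <= span[2]
    if (sum(inside) >= 1L) { pick <- i; fam <- te$family[inside][1]; break }
  }
  expect_false(is.null(pick))   # the fixture seed plants TEs between genes
  e0 <- te_enrichment(sim$repeats, loc, sim_chrom_lengths(sim),
                      families = fam)
  r0 <- family_representation(sim$repeats, loc, families = fam)

  sim2 <- apply_segmental_duplication(sim, genes = pick:(pick + 2L),
                                      rounds = 2L, post_rate = 0)
  loc2 <- locate_cluster(sim2$models$genes)
  e1 <- te_enrichment(sim2$repeats, loc2, sim_chrom_lengths(sim2),
                      families = fam)
  r1 <- family_representation(sim2$repeats, loc2, families = fam)
  expect_gt(r1$representation, r0$representation)
  expect_gt(e1$log2_enrichment,
            ifelse(is.na(e0$log2_enrichment), -Inf, e0$log2_enrichment))

  # the duplicated copies share one parent divergence exactly: the locus now
  # carries a zero-width group of at least 3 copies
  in_locus <- sim2$repeats$chrom == loc2$chrom &
    sim2$repeats$begin <= loc2$end & sim2$repeats$end >= loc2$start &
    sim2$repeats$family == fam
  g <- duplication_signature(sim2$repeats$perc_div[in_locus],
                             tolerance = 0.05, min_group = 3L)
  expect_gte(nrow(g), 1L)
  expect_true(any(g$max_divergence - g$min_divergence < 0.2))
})
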