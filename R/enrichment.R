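# TE enrichment and divergence statistics at a cluster locus, with a
# from-scratch permutation null: every permutation redraws each region's
# start uniformly on its own chromosome (length preserved, overlaps
# permitted) and re-counts overlaps with the locus.

locus_fields <- function(locus) {
  stopifnot(all(c("chrom", "start", "end") %in% names(locus)))
  list(chrom = locus$chrom[1], start = locus$start[1], end = locus$end[1])
}

#' TE family enrichment at a cluster locus
#'
#' The enrichment of a family is the log2 ratio of its annotation density in
#' the locus to its genome-wide density:
#' `log2((bp in locus / locus bp) / (bp genome-wide / genome bp))`. Base
#' pairs are annotated bases with overlapping annotations merged and locus
#' overlaps clipped at the boundaries. A family absent from the locus gets
#' `NA` enrichment (the "absent" sentinel); a family with no genome-wide
#' annotation is skipped with a warning.
#'
#' @param repeats Repeat tibble from [read_repeatmasker_out()] (or the
#'   simulator), using columns `chrom`, `begin`, `end`, `family`.
#' @param locus A [locate_cluster()] row (or any tibble with `chrom`,
#'   `start`, `end`).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param families Families to score; default all present.
#' @return A tibble per family: `family`, `bp_locus`, `bp_genome`,
#'   `locus_density`, `genome_density`, `log2_enrichment` (`NA` when absent
#'   from the locus), `absent` (logical).
#' @export
te_enrichment <- function(repeats, locus, chrom_lengths,
                          families = unique(repeats$family)) {
  lf <- locus_fields(locus)
  locus_bp <- lf$end - lf$start + 1L
  genome_bp <- sum(as.numeric(chrom_lengths))
  rows <- lapply(families, function(fam) {
    r <- repeats[repeats$family == fam, ]
    bp_genome <- merged_bp(r$begin, r$end)
    if (bp_genome == 0) {
      warn(sprintf("family '%s' has no genome-wide annotation; skipped", fam))
      return(NULL)
    }
    rl <- r[r$chrom == lf$chrom, ]
    clipped_s <- pmax(rl$begin, lf$start)
    clipped_e <- pmin(rl$end, lf$end)
    keep <- clipped_s <= clipped_e
    bp_locus <- merged_bp(clipped_s[keep], clipped_e[keep])
    dens_l <- bp_locus / locus_bp
    dens_g <- bp_genome / genome_bp
    tibble(family = fam, bp_locus = bp_locus, bp_genome = bp_genome,
           locus_density = dens_l, genome_density = dens_g,
           log2_enrichment = if (bp_locus == 0) NA_real_ else log2(dens_l / dens_g),
           absent = bp_locus == 0)
  })
  bind_rows(rows)
}

#' Permutation test of region overlap with a locus
#'
#' Observed statistic: the number of regions overlapping the locus by at
#' least 1 bp. Null: each permutation redraws every region's start uniformly
#' on its own chromosome with length preserved (overlaps between permuted
#' regions are allowed). The empirical p-value uses the add-one correction
#' `p = (1 + #(perm >= obs)) / (n + 1)`; the Z-score is
#' `(obs - mean_perm) / sd_perm` (0 when the null is degenerate).
#'
#' @param regions Tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @param locus Locus tibble (`chrom`, `start`, `end`).
#' @param chrom_lengths Named vector of chromosome lengths covering every
#'   region's chromosome.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional seed applied before permuting.
#' @return Object of class `perm_overlap`: list with `observed`,
#'   `null_mean`, `null_sd`, `z`, `p_value`, `n_perm`, `n_regions`, and the
#'   permutation counts in `perm`. Methods: [tidy()], [glance()],
#'   [autoplot()][plot_perm_overlap()].
#' @export
permutation_overlap_test <- function(regions, locus, chrom_lengths,
                                     n_perm = 1000L, seed = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  n_perm <- check_scalar_count(n_perm, "n_perm", min = 1L)
  if (!is.null(seed)) set.seed(seed)
  lf <- locus_fields(locus)

  w <- regions$end - regions$start + 1L
  clen <- chrom_lengths[regions$chrom]
  if (any(is.na(clen))) abort("region chromosome missing from chrom_lengths")
  if (any(w > clen)) abort("region longer than its chromosome")

  observed <- sum(regions$chrom == lf$chrom &
                    regions$start <= lf$end & regions$end >= lf$start)

  # Only regions on the locus chromosome can ever overlap it; their permuted
  # start is uniform on 1..(len - w + 1).
  on_chrom <- regions$chrom == lf$chrom
  wl <- w[on_chrom]
  n_starts <- unname(clen[on_chrom]) - wl + 1L
  perm <- integer(n_perm)
  if (length(wl) > 0L) {
    m <- length(wl)
    starts <- matrix(floor(runif(m * n_perm) * rep(n_starts, n_perm)) + 1L,
                     nrow = m)
    hits <- starts <= lf$end & (starts + wl - 1L) >= lf$start
    perm <- colSums(hits)
  }
  mu <- mean(perm)
  s <- sd(perm)
  structure(list(
    observed = observed,
    null_mean = mu, null_sd = s,
    z = if (is.na(s) || s == 0) 0 else (observed - mu) / s,
    p_value = (1 + sum(perm >= observed)) / (n_perm + 1),
    n_perm = n_perm, n_regions = nrow(regions), perm = perm
  ), class = "perm_overlap")
}

#' @export
print.perm_overlap <- function(x, ...) {
  cat(sprintf(
    "<perm_overlap> observed %d of %d regions; null %.2f +/- %.2f; Z = %.2f; p = %.4g (n = %d)\n",
    x$observed, x$n_regions, x$null_mean, x$null_sd, x$z, x$p_value, x$n_perm))
  invisible(x)
}

#' @rdname permutation_overlap_test
#' @param x A `perm_overlap` object.
#' @param ... Unused.
#' @export
tidy.perm_overlap <- function(x, ...) {
  tibble(observed = x$observed, null_mean = x$null_mean, null_sd = x$null_sd,
         z = x$z, p_value = x$p_value, n_perm = x$n_perm,
         n_regions = x$n_regions)
}

#' @rdname permutation_overlap_test
#' @export
glance.perm_overlap <- function(x, ...) tidy(x)

#' Fraction of a family's copies found in a locus
#'
#' Fragments sharing a RepeatMasker join ID count as a single copy (one
#' interrupted insertion); a copy is "in" the locus when any of its
#' fragments overlaps it by at least 1 bp.
#'
#' @param repeats Repeat tibble (columns `chrom`, `begin`, `end`, `family`,
#'   `join_id`).
#' @param locus Locus tibble.
#' @param families Families to report; default all.
#' @return Tibble `family`, `copies_total`, `copies_in_locus`,
#'   `representation` (fraction in 0..1).
#' @export
family_representation <- function(repeats, locus, families = unique(repeats$family)) {
  lf <- locus_fields(locus)
  repeats %>%
    filter(.data$family %in% families) %>%
    group_by(.data$family, .data$join_id) %>%
    summarise(in_locus = any(.data$chrom == lf$chrom &
                               .data$begin <= lf$end & .data$end >= lf$start),
              .groups = "drop") %>%
    group_by(.data$family) %>%
    summarise(copies_total = dplyr::n(),
              copies_in_locus = sum(.data$in_locus),
              representation = .data$copies_in_locus / .data$copies_total,
              .groups = "drop")
}

#' Select families for divergence-landscape display
#'
#' A family is displayed when more than `min_fraction` of its annotations
#' (joined copies) lie in the locus and it has more than `min_annotations`
#' in-locus annotation rows.
#'
#' @inheritParams family_representation
#' @param min_fraction Representation cutoff (default 0.02).
#' @param min_annotations In-locus annotation-count cutoff (default 10).
#' @return Character vector of family names.
#' @export
select_display_families <- function(repeats, locus, min_fraction = 0.02,
                                    min_annotations = 10L) {
  lf <- locus_fields(locus)
  rep_tbl <- family_representation(repeats, locus)
  ann_in <- repeats %>%
    filter(.data$chrom == lf$chrom, .data$begin <= lf$end,
           .data$end >= lf$start) %>%
    count(.data$family, name = "n_in")
  rep_tbl %>%
    left_join(ann_in, by = "family") %>%
    mutate(n_in = tidyr::replace_na(.data$n_in, 0L)) %>%
    filter(.data$representation > min_fraction,
           .data$n_in > min_annotations) %>%
    pull("family")
}

#' Group repeat copies by near-identical divergence
#'
#' Sorts divergence values and emits maximal runs in which consecutive gaps
#' are at most `tolerance` percentage points and run size is at least
#' `min_group`. Tight groups are the signature of copies that multiplied by
#' segmental duplication (they inherited one ancestor's divergence) rather
#' than by independent insertion.
#'
#' @param divergences Numeric vector of per-copy percent divergences.
#' @param tolerance Maximum gap between consecutive sorted values within a
#'   group, in percentage points (default 0.5).
#' @param min_group Minimum copies per group (default 3).
#' @return Tibble `group`, `n`, `mean_divergence`, `min_divergence`,
#'   `max_divergence`; attribute `grouped_fraction` is the fraction of
#'   input values that belong to a group.
#' @export
duplication_signature <- function(divergences, tolerance = 0.5, min_group = 3L) {
  stopifnot(all(is.finite(divergences)))
  v <- sort(divergences)
  n <- length(v)
  empty <- tibble(group = integer(), n = integer(), mean_divergence = numeric(),
                  min_divergence = numeric(), max_divergence = numeric())
  if (n == 0L) {
    attr(empty, "grouped_fraction") <- NA_real_
    return(empty)
  }
  run_id <- cumsum(c(1, diff(v) > tolerance))
  runs <- split(v, run_id)
  runs <- runs[vapply(runs, length, integer(1)) >= min_group]
  if (length(runs) == 0L) {
    attr(empty, "grouped_fraction") <- 0
    return(empty)
  }
  out <- tibble(
    group = seq_along(runs),
    n = unname(vapply(runs, length, integer(1))),
    mean_divergence = unname(vapply(runs, mean, numeric(1))),
    min_divergence = unname(vapply(runs, min, numeric(1))),
    max_divergence = unname(vapply(runs, max, numeric(1)))
  )
  attr(out, "grouped_fraction") <- sum(out$n) / n
  out
}

#' In-locus versus genome-wide divergence-grouping contrast
#'
#' Runs [duplication_signature()] on one family's in-locus copies and on all
#' of its copies genome-wide, and contrasts the grouped fractions. A
#' positive contrast means the locus concentrates near-identical-divergence
#' copies beyond the genome-wide background — the duplication signature.
#'
#' @inheritParams family_representation
#' @param family One family name.
#' @inheritParams duplication_signature
#' @return A one-row tibble: `family`, `n_locus`, `n_genome`,
#'   `grouped_fraction_locus`, `grouped_fraction_genome`, `contrast`.
#' @export
divergence_contrast <- function(repeats, locus, family, tolerance = 0.5,
                                min_group = 3L) {
  lf <- locus_fields(locus)
  r <- repeats[repeats$family == family, ]
  in_locus <- r$chrom == lf$chrom & r$begin <= lf$end & r$end >= lf$start
  gl <- duplication_signature(r$perc_div[in_locus], tolerance, min_group)
  gg <- duplication_signature(r$perc_div, tolerance, min_group)
  fl <- attr(gl, "grouped_fraction")
  fg <- attr(gg, "grouped_fraction")
  tibble(family = family, n_locus = sum(in_locus), n_genome = nrow(r),
         grouped_fraction_locus = fl %||% NA_real_,
         grouped_fraction_genome = fg %||% NA_real_,
         contrast = (fl %||% NA_real_) - (fg %||% NA_real_))
}
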