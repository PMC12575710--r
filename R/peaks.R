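# ChIP-seq peak filtering and peak-repeat association statistics.

#' Filter ChIP-seq peaks against negative controls and quality cutoffs
#'
#' Drops any peak overlapping a negative-control peak by >= 1 bp, then keeps
#' peaks with `qValue <= q_max` and fold enrichment >= `fe_primary`. If fewer
#' than `min_peaks` survive, the fold-enrichment cutoff falls back to
#' `fe_fallback` (the q-value cutoff is unchanged).
#'
#' @param peaks Peak tibble (see [read_peaks()]): `chrom`, `start`, `end`,
#'   `fold_enrichment`, `qValue`.
#' @param negative_control_peaks Peak tibble of control peaks (only `chrom`,
#'   `start`, `end` used); `NULL` for no control subtraction.
#' @param q_max Maximum q-value (default 0.01).
#' @param fe_primary,fe_fallback Primary and fallback fold-enrichment
#'   cutoffs (defaults 10 and 5).
#' @param min_peaks Minimum retained peaks before falling back (default 20).
#' @return The retained peaks, with attribute `fe_cutoff` recording the
#'   cutoff actually applied.
#' @export
filter_peaks <- function(peaks, negative_control_peaks = NULL, q_max = 0.01,
                         fe_primary = 10, fe_fallback = 5, min_peaks = 20L) {
  stopifnot(all(c("chrom", "start", "end", "fold_enrichment", "qValue") %in% names(peaks)))
  pk <- peaks
  if (!is.null(negative_control_peaks) && nrow(negative_control_peaks) > 0L) {
    ctrl <- negative_control_peaks
    hit <- vapply(seq_len(nrow(pk)), function(i) {
      any(ctrl$chrom == pk$chrom[i] & ctrl$start <= pk$end[i] &
            ctrl$end >= pk$start[i])
    }, logical(1))
    pk <- pk[!hit, , drop = FALSE]
  }
  qpass <- pk[pk$qValue <= q_max, , drop = FALSE]
  primary <- qpass[qpass$fold_enrichment >= fe_primary, , drop = FALSE]
  if (nrow(primary) >= min_peaks) {
    attr(primary, "fe_cutoff") <- fe_primary
    return(primary)
  }
  fallback <- qpass[qpass$fold_enrichment >= fe_fallback, , drop = FALSE]
  attr(fallback, "fe_cutoff") <- fe_fallback
  fallback
}

#' Peak-TE association by permutation
#'
#' For each repeat family, the observed statistic is the number of peaks
#' overlapping at least one annotation of the family (>= 1 bp). The null
#' redraws every peak's position uniformly on its own chromosome (length
#' preserved), exactly as in [permutation_overlap_test()], and recounts per
#' family. Reported per family: the percentage of peaks overlapping, the
#' permutation Z-score and the add-one-corrected empirical p-value.
#'
#' @param peaks Peak tibble (>= 1 peak) with `chrom`, `start`, `end`.
#' @param repeats Repeat tibble (`chrom`, `begin`, `end`, `family`).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional seed.
#' @param p_display Display cutoff; families at `p < p_display` are flagged
#'   in the `display` column (default 0.001, the bubble-plot convention).
#' @return Tibble per family: `family`, `observed`, `percent_peaks`,
#'   `null_mean`, `null_sd`, `z`, `p_value`, `display`.
#' @export
peak_te_association <- function(peaks, repeats, chrom_lengths, n_perm = 1000L,
                                seed = NULL, p_display = 0.001) {
  stopifnot(nrow(peaks) >= 1L)
  n_perm <- check_scalar_count(n_perm, "n_perm", min = 1L)
  if (!is.null(seed)) set.seed(seed)

  fams <- unique(repeats$family)
  chroms <- unique(peaks$chrom)
  if (any(is.na(chrom_lengths[chroms]))) {
    abort("peak chromosome missing from chrom_lengths")
  }

  # Per-chromosome, per-family repeat interval trees, built once.
  rep_by_chrom <- lapply(setNames(chroms, chroms), function(ch) {
    r <- repeats[repeats$chrom == ch, ]
    list(ir = IRanges::IRanges(r$begin, r$end), family = r$family)
  })

  count_by_family <- function(starts, widths, pk_chrom) {
    # number of peaks overlapping >= 1 record, per family
    counts <- setNames(integer(length(fams)), fams)
    for (ch in chroms) {
      sel <- pk_chrom == ch
      if (!any(sel)) next
      rb <- rep_by_chrom[[ch]]
      if (length(rb$ir) == 0L) next
      pk_ir <- IRanges::IRanges(start = starts[sel], width = widths[sel])
      ov <- IRanges::findOverlaps(pk_ir, rb$ir)
      if (length(ov) == 0L) next
      hit_fam <- rb$family[S4Vectors::subjectHits(ov)]
      qh <- S4Vectors::queryHits(ov)
      for (fam in unique(hit_fam)) {
        counts[[fam]] <- counts[[fam]] + length(unique(qh[hit_fam == fam]))
      }
    }
    counts
  }

  w <- peaks$end - peaks$start + 1L
  obs <- count_by_family(peaks$start, w, peaks$chrom)

  n_starts <- unname(chrom_lengths[peaks$chrom]) - w + 1L
  if (any(n_starts < 1L)) abort("peak longer than its chromosome")
  perm <- matrix(0L, nrow = n_perm, ncol = length(fams),
                 dimnames = list(NULL, fams))
  for (p in seq_len(n_perm)) {
    starts <- floor(runif(length(w)) * n_starts) + 1L
    perm[p, ] <- count_by_family(starts, w, peaks$chrom)[fams]
  }

  mu <- colMeans(perm)
  s <- apply(perm, 2L, sd)
  pvals <- vapply(fams, function(f) {
    (1 + sum(perm[, f] >= obs[[f]])) / (n_perm + 1)
  }, numeric(1))
  tibble(
    family = fams,
    observed = unname(as.integer(obs[fams])),
    percent_peaks = unname(100 * obs[fams] / nrow(peaks)),
    null_mean = unname(mu[fams]), null_sd = unname(s[fams]),
    z = unname(ifelse(s[fams] == 0, 0, (obs[fams] - mu[fams]) / s[fams])),
    p_value = unname(pvals[fams]),
    display = unname(pvals[fams] < p_display)
  )
}
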