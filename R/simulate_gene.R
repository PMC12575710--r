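# Synthetic KZFP (and anchor) gene construction. Genes are built at the
# protein level first — KRAB-A consensus, then a tandem array of canonical
# C-x2-C-x12-H-x3-H fingers with TGEKP-style linkers — and reverse-translated
# codon-by-codon with random synonymous choices, so unrelated genes share no
# more DNA identity than their residue skeleton forces.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
# Filler residues exclude C and H so random sequence never creates or shifts
# a finger anchor.
FILLER_AA <- setdiff(AA_ALPHABET, c("C", "H"))

codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

# Reverse-translate a residue vector with uniformly random synonymous codons.
encode_protein <- function(aa) {
  tab <- codons_by_aa()
  paste(vapply(aa, function(a) {
    cods <- tab[[a]]
    cods[sample_int1(length(cods))]
  }, character(1)), collapse = "")
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_aa <- function(n, alphabet = FILLER_AA) {
  sample(alphabet, n, replace = TRUE)
}

# One canonical 28-residue finger unit; optionally one coordinating cysteine
# is substituted to a non-C/H residue (a degenerate finger). Returns the
# residues plus the planted fingerprint (spacer positions 6, 8, 9, 12).
make_finger_unit <- function(degenerate = FALSE) {
  spacer <- random_aa(12L)
  unit <- c("C", random_aa(2L), "C", spacer, "H", random_aa(3L), "H",
            c("T", "G", "E", "K", "P"), random_aa(2L))
  if (degenerate) {
    mutate_at <- sample(c(1L, 4L), 1L)  # one of the two cysteines
    unit[mutate_at] <- sample(FILLER_AA, 1L)
  }
  list(aa = unit, fingerprint = paste(spacer[c(6L, 8L, 9L, 12L)], collapse = ""))
}

#' Generate one synthetic KZFP gene
#'
#' Builds a two-exon gene whose first exon encodes a start codon, a short
#' leader and the full KRAB-A consensus, and whose last (3') exon encodes an
#' in-frame tandem array of `n_fingers` canonical C2H2 fingers followed by a
#' stop codon and a random 3' UTR. Fingers listed in `degenerate_positions`
#' carry one cysteine-to-other-residue substitution and are therefore only
#' recoverable by the relaxed scanning pass. Randomness comes from the
#' session RNG; fix a seed for reproducible genes.
#'
#' @param n_fingers Number of fingers (>= 1).
#' @param degenerate_positions Integer indices (1-based) of fingers to
#'   degenerate; interior indices are recoverable by [scan_c2h2()]'s rescue
#'   pass, terminal ones are not (documented behaviour).
#' @param leader_len Residues between the start codon and the KRAB box.
#' @param intron_len Intron length in bp (>= 4; starts GT, ends AG).
#' @param utr3_len Length of the random 3' UTR in bp.
#' @return A list: `dna` (gene sequence, 5'->3'), `protein` (encoded
#'   protein), `exons`/`cds` (tibbles of 1-based intervals relative to the
#'   gene sequence), `fingerprint` (planted per-finger 4-mers),
#'   `fingerprint_key`, `n_fingers`.
#' @export
#' @examples
#' set.seed(1)
#' g <- make_kzfp_gene(3)
#' scan_c2h2(g$protein)$fingerprint == g$fingerprint
make_kzfp_gene <- function(n_fingers, degenerate_positions = integer(),
                           leader_len = 10L, intron_len = 200L, utr3_len = 150L) {
  n_fingers <- check_scalar_count(n_fingers, "n_fingers", min = 1L)
  stopifnot(intron_len >= 4L)
  if (length(degenerate_positions) > 0L &&
      (any(degenerate_positions < 1L) || any(degenerate_positions > n_fingers))) {
    abort("`degenerate_positions` must index fingers in 1..n_fingers")
  }

  krab <- strsplit(krab_consensus(), "")[[1]]
  exon1_aa <- c("M", random_aa(leader_len), krab, random_aa(5L))
  units <- lapply(seq_len(n_fingers), function(i) {
    make_finger_unit(degenerate = i %in% degenerate_positions)
  })
  exon2_aa <- c(random_aa(5L), unlist(lapply(units, `[[`, "aa")))

  exon1_dna <- encode_protein(exon1_aa)
  exon2_cds <- encode_protein(exon2_aa)
  stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
  exon2_dna <- paste0(exon2_cds, stop_codon, random_dna(utr3_len))
  intron <- paste0("GT", random_dna(intron_len - 4L), "AG")

  l1 <- nchar(exon1_dna)
  e2_start <- l1 + nchar(intron) + 1L
  dna <- paste0(exon1_dna, intron, exon2_dna)

  list(
    dna = dna,
    protein = paste(c(exon1_aa, exon2_aa), collapse = ""),
    exons = tibble(start = c(1L, e2_start), end = c(l1, nchar(dna))),
    cds = tibble(start = c(1L, e2_start),
                 end = c(l1, e2_start + nchar(exon2_cds) + 2L)),
    fingerprint = vapply(units, `[[`, character(1), "fingerprint"),
    fingerprint_key = fingerprint_key(vapply(units, `[[`, character(1), "fingerprint")),
    n_fingers = n_fingers
  )
}

# A plain two-exon protein-coding gene with neither KRAB nor fingers; used
# for the cluster anchor genes (Tnfrsf8/Miip stand-ins).
make_anchor_gene <- function(exon_codons = 60L, intron_len = 150L, utr3_len = 100L) {
  exon1_aa <- c("M", random_aa(exon_codons))
  exon2_aa <- random_aa(exon_codons)
  exon1_dna <- encode_protein(exon1_aa)
  exon2_cds <- encode_protein(exon2_aa)
  exon2_dna <- paste0(exon2_cds, "TAA", random_dna(utr3_len))
  intron <- paste0("GT", random_dna(intron_len - 4L), "AG")
  l1 <- nchar(exon1_dna)
  e2_start <- l1 + nchar(intron) + 1L
  dna <- paste0(exon1_dna, intron, exon2_dna)
  list(
    dna = dna,
    protein = paste(c(exon1_aa, exon2_aa), collapse = ""),
    exons = tibble(start = c(1L, e2_start), end = c(l1, nchar(dna))),
    cds = tibble(start = c(1L, e2_start),
                 end = c(l1, e2_start + nchar(exon2_cds) + 2L)),
    fingerprint = character(),
    fingerprint_key = "",
    n_fingers = 0L
  )
}
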