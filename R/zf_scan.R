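# C2H2 zinc-finger detection and fingerprint extraction.
#
# A canonical finger is matched as C x{2,4} C x{10,14} H x{3,5} H with
# leftmost-shortest (lazy) preference; a relaxed second pass over long
# unmatched gaps between canonical fingers rescues fingers carrying exactly
# one substitution of a coordinating C/H, which are flagged rather than
# silently accepted.

zf_pattern <- function(mutate_anchor = 0L) {
  anchors <- c("C", "C", "H", "H")
  if (mutate_anchor > 0L) anchors[mutate_anchor] <- "[^CH]"
  paste0(anchors[1], "(.{2,4}?)", anchors[2], "(.{10,14}?)",
         anchors[3], "(.{3,5}?)", anchors[4])
}

# First match of `pattern` in `seq` at or after `from`; NULL if none.
# Returns 1-based anchor offsets derived from the capture-group widths.
match_finger <- function(seq, pattern, from = 1L) {
  sub <- substr(seq, from, nchar(seq))
  m <- regexpr(pattern, sub, perl = TRUE)
  if (m == -1L) return(NULL)
  gw <- attr(m, "capture.length")[1, ]
  c1 <- from + as.integer(m) - 1L
  c2 <- c1 + 1L + gw[[1]]
  h1 <- c2 + 1L + gw[[2]]
  h2 <- h1 + 1L + gw[[3]]
  list(c1 = c1, c2 = c2, h1 = h1, h2 = h2)
}

scan_region_canonical <- function(seq, offset = 0L) {
  out <- list()
  pos <- 1L
  pat <- zf_pattern()
  while (pos <= nchar(seq)) {
    hit <- match_finger(seq, pat, pos)
    if (is.null(hit)) break
    out[[length(out) + 1L]] <- hit
    pos <- hit$h2 + 1L
  }
  lapply(out, function(h) lapply(h, function(x) x + offset))
}

# Relaxed scan of one gap: admit fingers with exactly one mutated C/H anchor,
# leftmost-shortest across the four single-substitution patterns.
scan_region_relaxed <- function(seq, offset = 0L) {
  pats <- lapply(1:4, zf_pattern)
  out <- list()
  pos <- 1L
  while (pos <= nchar(seq)) {
    hits <- lapply(pats, function(p) match_finger(seq, p, pos))
    hits <- hits[!vapply(hits, is.null, logical(1))]
    if (length(hits) == 0L) break
    starts <- vapply(hits, function(h) h$c1, integer(1))
    lens <- vapply(hits, function(h) h$h2 - h$c1, integer(1))
    best <- order(starts, lens)[1]
    out[[length(out) + 1L]] <- hits[[best]]
    pos <- hits[[best]]$h2 + 1L
  }
  lapply(out, function(h) lapply(h, function(x) x + offset))
}

#' Scan a protein for C2H2 zinc fingers
#'
#' Performs a left-to-right, non-overlapping scan for canonical C2H2 fingers
#' (`C-x(2,4)-C-x(10,14)-H-x(3,5)-H`, leftmost-shortest preference). A second,
#' relaxed pass over unmatched gaps of at least `min_gap` residues that are
#' flanked by canonical fingers admits fingers carrying exactly one
#' substitution of a coordinating cysteine/histidine; these are reported with
#' `flag_ch_mutation = TRUE`. `X` residues are tolerated in spacers but never
#' match a C/H anchor.
#'
#' @param protein A single amino-acid string. An empty string yields an empty
#'   result, not an error.
#' @param min_gap Minimum length of an inter-finger gap inspected by the
#'   relaxed pass (default 28, one full finger repeat unit).
#' @return A tibble with one row per finger, ordered by position:
#'   `start`/`end` (1-based inclusive span from first C to last H), anchor
#'   offsets `c1`, `c2`, `h1`, `h2`, the inter C2-H1 `spacer`, the 4-residue
#'   `fingerprint` (helix positions -1, +2, +3, +6), and logical flags
#'   `flag_ch_mutation` and `flag_structural_mutation`.
#' @seealso [extract_fingerprint()] for the fingerprint rule.
#' @export
#' @examples
#' scan_c2h2("PYACPVESCDRRFSRSDELTRHIRIHTG")  # Zif268 finger 1
scan_c2h2 <- function(protein, min_gap = 28L) {
  stopifnot(is.character(protein), length(protein) == 1L)
  empty <- tibble(
    start = integer(), end = integer(),
    c1 = integer(), c2 = integer(), h1 = integer(), h2 = integer(),
    spacer = character(), fingerprint = character(),
    flag_ch_mutation = logical(), flag_structural_mutation = logical()
  )
  if (is.na(protein) || nchar(protein) == 0L) return(empty)

  canon <- scan_region_canonical(protein)
  relaxed <- list()
  if (length(canon) >= 2L) {
    for (i in seq_len(length(canon) - 1L)) {
      gap_start <- canon[[i]]$h2 + 1L
      gap_end <- canon[[i + 1L]]$c1 - 1L
      if (gap_end - gap_start + 1L >= min_gap) {
        gap_seq <- substr(protein, gap_start, gap_end)
        relaxed <- c(relaxed, scan_region_relaxed(gap_seq, offset = gap_start - 1L))
      }
    }
  }
  flags <- c(rep(FALSE, length(canon)), rep(TRUE, length(relaxed)))
  hits <- c(canon, relaxed)
  if (length(hits) == 0L) return(empty)
  ord <- order(vapply(hits, function(h) h$c1, integer(1)))
  hits <- hits[ord]
  flags <- flags[ord]

  out <- tibble(
    c1 = vapply(hits, function(h) h$c1, integer(1)),
    c2 = vapply(hits, function(h) h$c2, integer(1)),
    h1 = vapply(hits, function(h) h$h1, integer(1)),
    h2 = vapply(hits, function(h) h$h2, integer(1)),
    flag_ch_mutation = flags
  )
  fp <- extract_fingerprint(protein, out$c1, out$c2, out$h1)
  tibble(
    start = out$c1, end = out$h2,
    c1 = out$c1, c2 = out$c2, h1 = out$h1, h2 = out$h2,
    spacer = substr(rep(protein, nrow(out)), out$c2 + 1L, out$h1 - 1L),
    fingerprint = fp$fingerprint,
    flag_ch_mutation = out$flag_ch_mutation,
    flag_structural_mutation = fp$flag_structural_mutation
  )
}

#' Extract the DNA-contacting fingerprint of a zinc finger
#'
#' Returns the residues at helix positions -1, +2, +3 and +6 of one or more
#' fingers, anchored from the first coordinating histidine: -1 is the residue
#' at `h1 - 7`, +2 at `h1 - 5`, +3 at `h1 - 4` and +6 at `h1 - 1`. On a
#' canonical 12-residue spacer this is identical to indexing the spacer at
#' positions 6, 8, 9 and 12, but the histidine-side anchoring also applies to
#' non-canonical spacer lengths. A structural flag is raised when any of the
#' conserved framework residues deviates: -12 (two residues before the first
#' cysteine) not F/Y, -3 (`h1 - 9`) not F, or +4 (`h1 - 3`) not L. Positions
#' falling outside the spacer (spacer shorter than 7) are padded with `-` and
#' flagged.
#'
#' @param protein Amino-acid string the offsets refer to.
#' @param c1,c2,h1 Integer vectors of 1-based offsets of the first cysteine,
#'   second cysteine and first histidine of each finger (as returned by
#'   [scan_c2h2()]).
#' @return A tibble with columns `fingerprint` (4-character string) and
#'   `flag_structural_mutation`.
#' @export
#' @examples
#' extract_fingerprint("PYACPVESCDRRFSRSDELTRHIRIHTG", c1 = 4, c2 = 9, h1 = 22)
extract_fingerprint <- function(protein, c1, c2, h1) {
  stopifnot(is.character(protein), length(protein) == 1L)
  n <- length(h1)
  aa_at <- function(pos, lower_ok) {
    # lower_ok: smallest legal offset per finger; outside -> '-'
    bad <- pos < 1L | pos <= lower_ok | pos > nchar(protein)
    out <- substring(protein, pos, pos)
    out[bad] <- "-"
    out
  }
  p_m1 <- aa_at(h1 - 7L, c2)
  p_p2 <- aa_at(h1 - 5L, c2)
  p_p3 <- aa_at(h1 - 4L, c2)
  p_p6 <- aa_at(h1 - 1L, c2)
  fingerprint <- paste0(p_m1, p_p2, p_p3, p_p6)
  padded <- grepl("-", fingerprint, fixed = TRUE)

  r_m3 <- aa_at(h1 - 9L, c2)
  r_p4 <- aa_at(h1 - 3L, c2)
  r_m12 <- substring(protein, pmax(c1 - 2L, 0L), pmax(c1 - 2L, 0L))
  r_m12[c1 - 2L < 1L] <- "-"
  flag <- padded | r_m3 != "F" | r_p4 != "L" | !(r_m12 %in% c("F", "Y"))
  tibble(fingerprint = fingerprint, flag_structural_mutation = flag)
}

#' Concatenate a fingerprint array into its identity key
#'
#' Two KZFPs have the same repertoire entry if and only if their ordered
#' fingerprint arrays are identical character-for-character; degeneracy flags
#' are not part of identity.
#'
#' @param fingerprints Character vector of per-finger 4-mers, 5' to 3'.
#' @return A single string, 4-mers joined with `|` (empty string for a gene
#'   without fingers).
#' @export
fingerprint_key <- function(fingerprints) {
  paste(fingerprints, collapse = "|")
}
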