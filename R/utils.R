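# Shared internal helpers: interval arithmetic on plain tibbles and a couple of
# sequence utilities used across modules.

# Overlap width of [s1,e1] with [s2,e2], 1-based inclusive; 0 when disjoint.
overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

# Total bp covered by a set of 1-based inclusive intervals, overlaps merged.
merged_bp <- function(start, end) {
  if (length(start) == 0L) return(0L)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start = start, end = end))))
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Codon-table translation; codons with any non-ACGT base give 'X'. A direct
# lookup keeps per-transcript translation cheap for frame-by-frame scanning.
translate_dna <- local({
  tab <- NULL
  function(x) {
    if (is.null(tab)) {
      tab <<- Biostrings::GENETIC_CODE
    }
    n <- nchar(x) - nchar(x) %% 3L
    if (n < 3L) return("")
    codons <- substring(toupper(x), seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- unname(tab[codons])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }
})

# Sample one integer uniformly from 1..n without sample()'s n==1 surprise.
sample_int1 <- function(n) {
  if (n <= 1L) return(1L)
  sample.int(n, 1L)
}

check_scalar_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}
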