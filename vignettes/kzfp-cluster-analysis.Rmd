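---
title: "Analysing KRAB zinc-finger gene clusters with kzfpscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing KRAB zinc-finger gene clusters with kzfpscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kzfpscape)
```

## The problem

KRAB zinc-finger proteins (KZFPs) are the largest transcription-factor family
in most mammals: an N-terminal KRAB box recruits TRIM28 to silence bound loci,
and a tandem array of C2H2 zinc fingers reads the DNA. The genes sit in dense
genomic clusters that expand rapidly by segmental duplication, apparently in a
feedback loop with the endogenous retroviruses (ERVs) they repress. Comparing
such a cluster across assemblies means answering a chain of questions, each of
which this package implements as a testable, deterministic step:

1. Which transcripts encode a KZFP, and is each gene coding, a pseudogene, or
   something in between?
2. What is each KZFP's DNA-binding *fingerprint*, and how do the repertoires
   of distinct fingerprint arrays compare across assemblies?
3. Which groups of genes duplicated together as blocks, and where are the
   copies?
4. Which transposable-element families are enriched in the cluster locus, and
   did they get there by retrotransposition or by riding along in segmental
   duplications?
5. Which TE families does each KZFP bind, from filtered ChIP-seq peaks?
6. Upstream of all of this: which contigs of a de novo assembly are placeable,
   redundant, or mis-oriented?

Because the published statistics for real genomes derive from multi-gigabase
assemblies and hand curation, validation here is *property-based*: a seeded
simulator plants genes, TE copies, duplications and contig fragmentations with
machine-readable ground truth, and the acceptance suite checks that the
pipeline recovers what was planted.

## Zinc-finger detection and the fingerprint rule

A canonical C2H2 finger is matched as `C-x(2,4)-C-x(10,14)-H-x(3,5)-H`,
scanned left to right with leftmost-shortest preference, non-overlapping. The
fingerprint is the four residues that contact DNA, at helix positions −1, +2,
+3 and +6. The helical numbering is operationalised **from the first
histidine**: −1 is the residue at `h1 − 7`, +2 at `h1 − 5`, +3 at `h1 − 4`,
and +6 at `h1 − 1`. On a canonical 12-residue spacer this is provably the same
as indexing the spacer at positions 6, 8, 9 and 12 — the test suite asserts
the equivalence on 10,000 random fingers — but the H-side anchoring also
yields a defined answer for 10-, 11-, 13- and 14-residue spacers, where a
spacer-index rule would be ambiguous. The reference point is the first finger
of Zif268, whose recognition residues are RDER:

```{r}
scan_c2h2("PYACPVESCDRRFSRSDELTRHIRIHTG")[, c("spacer", "fingerprint")]
```

Two flags accompany each finger. `flag_ch_mutation` marks fingers recovered by
a relaxed second pass that admits exactly one substitution of a coordinating
C/H; this pass only runs inside gaps of at least 28 residues flanked by
canonical fingers, so isolated pattern noise is never "rescued". The
structural flag marks deviations of the conserved framework residues (−12 not
F/Y, −3 not F, +4 not L), with −12 defined as two residues before the first
cysteine.

Fingerprint-array identity is exact ordered string identity of the
concatenated 4-mers; flags are not part of identity. This is deliberately
strict: a single residue difference separates two repertoire entries.

## KRAB detection and transcript classification

KRAB detection slides a fixed 42-residue KRAB-A consensus along the protein
and reports the best window identity; the domain is called at a default
threshold of 0.6. A profile HMM would be more sensitive on real proteomes, but
a consensus scan is dependency-free and its false-positive rate is directly
calibrated in the tests (< 1% on random length-100 proteins). The threshold is
a parameter of every function that uses it.

Classification applies the curation rules as deterministic logic. The spliced
transcript is translated in its three forward frames; in each frame the ORF
from the first ATG is examined. With `start_intact` meaning "an annotated CDS
exists and its spliced sequence begins with ATG":

* **coding** — start intact, and an ORF encodes both a KRAB and ≥ 1 finger;
* **other** — start intact, no KRAB anywhere, but a finger-bearing ORF of at
  least 100 codons (residual coding potential);
* **pseudogene** — fingers are present but the start or the KRAB is lost;
* **non-kzfp** — no fingers at all.

The 100-codon rule quantifies "minimal coding potential", which the underlying
curation practice left informal; it is exposed as the place where the
pseudogene/other boundary was a genuine design choice. Where a gene has
several transcripts, each is classified and the gene takes the most
coding-like class. The zinc-finger exon of a transcript is the exon holding
the majority of its fingers (ties to the 3'-most), computed by mapping finger
codons through the exon structure — this also works for pseudogenes with
truncated arrays.

## Cluster loci, repertoires, and duplicated blocks

A cluster locus is anchored syntenically: it runs from 1 bp downstream of the
upstream anchor gene (Tnfrsf8 in the Chr4 case) to 1 bp upstream of the
downstream anchor (Miip), exclusive of both, regardless of anchor strand or
coordinate order. Repertoire comparison is then plain set arithmetic on
identity keys, with copy numbers reported separately because shared arrays
often differ in representation between assemblies.

Block inference compares the **whole 3' exon DNA** (zinc-finger portion and
UTR alike) of all KZFP genes, coding or not — comparing coding sequence only
would make a recently duplicated gene with one truncating mutation look
unrelated to its parent. Distances are one minus the identity of a global
Needleman–Wunsch alignment (match +1, mismatch −1, gap open −4, gap extend −1;
identity = matches / alignment columns). A pairwise distance matrix replaces
the multiple-alignment-plus-tree route of interactive practice because the
block inference only consumes distances, and pairwise global alignments are
reproducible without an external aligner.

Genes are grouped by single-linkage clustering cut at 0.05 (i.e. 95% exon
identity) — the threshold is exposed because the visual grouping it
operationalises had no stated cutoff — and the positional sequence of group
labels is scanned for maximal runs of ≥ 3 labels occurring at ≥ 2
non-overlapping positions, in order or exactly reversed (inverted
duplications). Longer candidates claim their positions first; length-2 runs
are reported separately as partial-duplication candidates, not blocks,
matching the observed 3–7-gene range of real blocks.

The conservation census tiers each KZFP unit per species by the widest
sharing its presence pattern supports (species-unique → clade-shared →
mammal-shared → beyond-mammal), counting multiplicity; it is checked against a
brute-force set-membership oracle.

## TE enrichment, the permutation null, and the duplication signature

Enrichment of a family at a locus is
`log2((bp in locus / locus bp) / (bp genome-wide / genome bp))`, computed on
merged annotated bases with locus overlaps clipped; a family absent from the
locus is an explicit sentinel (`NA` + `absent`), not a zero. Copy-level
*representation* (fraction of copies in the locus, fragments joined by their
RepeatMasker join ID) is kept as a separate statistic because enrichment is
defined in base pairs while representation is defined in element counts.
Whether "copies" meant fragments or joined insertions was not stated in the
source analyses; joined copies are this package's documented choice, since
fragment counts are not reproducible across RepeatMasker runs.

The permutation null re-implements the overlap test from scratch: each of
`n` permutations (default 1000) redraws every region's start uniformly on its
own chromosome with length preserved, overlaps permitted; the empirical
p-value uses the add-one correction `(1 + k)/(n + 1)` and a Z-score is
reported alongside. Correctness is pinned two ways: the permutation mean must
match exhaustive enumeration of all starts on a ≤ 200 bp instance, and
p-values must be uniform when the data are drawn from the null itself. For the
calibration experiment the datasets use 2000 regions and 999 permutations —
with few regions or permutations the overlap count is so discrete that ties
make the add-one p-value visibly conservative, which would test the
discreteness of the statistic rather than the correctness of the null.

The duplication signature rests on divergence arithmetic: copies spawned by
segmental duplication inherit their ancestor's divergence to the family
consensus, so a locus expanded by duplication shows tight groups of
near-identical divergence values where the genome-wide picture is a continuum.
`duplication_signature()` sorts divergences and emits maximal runs with
consecutive gaps ≤ 0.5 percentage points and ≥ 3 members (both parameters
exposed — "nearly identical" had no stated number), and
`divergence_contrast()` contrasts the grouped fraction in-locus against
genome-wide. The validation experiment duplicates a TE-bearing three-gene
block three times and requires enrichment gain, representation gain and
positive contrast; it explicitly duplicates a window in which the family is
concentrated relative to the locus average, because that concentration is the
stated precondition of the claim (a block *less* TE-dense than the locus
dilutes enrichment when copied — arithmetic, not a bug).

ChIP-seq peaks are filtered by the fixed published rules: any ≥ 1 bp overlap
with a negative-control peak removes the peak; then qValue ≤ 0.01 and fold
enrichment ≥ 10, falling back to ≥ 5 when fewer than 20 peaks survive.
Peak–TE association permutes peak placements under the same null and reports
per family the percentage of peaks overlapping, Z, and p, with the
conventional p < 0.001 display cutoff. No multiple-testing correction is
applied across families, mirroring the raw-permutation-p reporting the
statistics are meant to reproduce.

## Contig curation

Curation from PAF alignments applies three criteria in order: contigs aligning
only to unknown targets are dropped; a contig aligning to several chromosomes
is assigned to the one carrying its **single longest alignment block** (the
wording is singular; summed bp is used only as a tie-break, and both are
reported as evidence); and a contig whose merged reference span is fully
contained in a retained contig's span with a smaller longest alignment is
dropped as nested — partial overlaps keep both. A kept contig is
reverse-complemented when the majority of its aligned bp on the assigned
chromosome is minus-strand; "majority" resolves the mixed-strand case the
published procedure did not need to define, and strand is recomputed only on
the assigned chromosome. Excluded chromosomes (the ChrY-style case) are a
user-supplied known-chromosome list, not hard-coded. The suite checks the
nested-drop set against a brute-force all-pairs containment oracle and
requires byte-exact chromosome reconstruction from the curated contigs.

## The simulator and what passing tests do and do not show

`build_cluster_genome()` lays out one cluster chromosome (anchor gene, KZFP
genes in index order with 0.8–2.5 kb gaps, anchor gene) plus background
chromosomes, then places TE copies uniformly (chromosome ∝ length, position
uniform among feature-free space). Synthetic KZFP genes are built at the
protein level — start codon, 10-residue leader, the 42-residue KRAB-A
consensus verbatim, then canonical 28-residue finger units — and
reverse-translated with random synonymous codons, so unrelated genes share
only their residue skeleton. Filler residues exclude C and H so random
sequence never creates or shifts a finger anchor. Per-copy TE divergence is
realised as Poisson-distributed uniform base substitutions at a per-copy
target drawn from a truncated normal; no indels, so percent divergence is
exactly the substitution fraction, matching the RepeatMasker semantics at toy
scale. Segmental duplication inserts the block sequence at a uniformly chosen
feature-free position inside the locus (never inside a gene, and never inside
a previous occurrence), with full coordinate bookkeeping; fragmentation cuts
the genome at uniform breakpoints and emits perfect PAF records from exact
bookkeeping. All coordinates in R are 1-based inclusive; emitted GFF3 and
RepeatMasker `.out` are 1-based, PAF 0-based half-open, as those formats
require.

What the simulator does **not** emulate bounds what green tests mean:
repeats are unfragmented and un-nested (the join-ID logic is exercised by
hand-built fixtures, not the generator), alignments are noise-free, there are
no indels, no transcript-abundance ambiguity, and gene structure is uniform.
Passing tests show the inference logic is correct under its stated model; they
do not show robustness to aligner noise, annotation error, or assembly
artefacts in real data.

Problem sizes in the validation experiments (8–30 genes, tens of TE copies,
chromosomes of 30–420 kb, 20 seeds for round-trip and block recovery, 10 for
the duplication signature, 500 null datasets) were chosen as the smallest
sizes at which the checked statistics are stable across seeds.

## Known limitations

* KRAB detection is consensus-identity based; divergent KRAB-B/C variants
  would need an HMM and may be missed on real proteomes.
* The classifier trusts the provided exon structure; it does not re-derive
  splice sites, and isoform arbitration by expression is replaced by
  "best class across provided transcripts".
* Block detection operates on group labels, so two planted blocks sharing a
  gene family could merge; the greedy longest-first resolution is
  deterministic but not globally optimal.
* The permutation null allows permuted regions to overlap and does not mask
  assembly gaps; on real genomes a masked null would be more conservative.
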