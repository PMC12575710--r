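# Cluster-level comparative analysis: anchor-defined locus, fingerprint
# repertoires, 3'exon distances, similarity groups and duplicated gene
# blocks.

#' Define a cluster locus from its two anchor genes
#'
#' The locus runs from 1 bp downstream of the upstream anchor's gene body to
#' 1 bp upstream of the downstream anchor's body, exclusive of both,
#' regardless of anchor strand or which anchor comes first in coordinates.
#'
#' @param genes Gene tibble with columns `name` (or `gene_id`), `chrom`,
#'   `start`, `end` — e.g. `models$genes` from [read_gene_models()].
#' @param upstream,downstream Names of the two anchor genes (matched against
#'   `name`, falling back to `gene_id`).
#' @param assembly Optional assembly label carried through.
#' @return A one-row tibble of class `cluster_locus`: `assembly`, `chrom`,
#'   `start`, `end` (1-based inclusive), `upstream`, `downstream`.
#' @export
locate_cluster <- function(genes, upstream = "Tnfrsf8", downstream = "Miip",
                           assembly = NA_character_) {
  find_anchor <- function(nm) {
    hit <- genes[genes$name %in% nm | genes$gene_id %in% nm, , drop = FALSE]
    if (nrow(hit) == 0L) abort(sprintf("anchor gene '%s' not found", nm))
    if (nrow(hit) > 1L) abort(sprintf("anchor gene '%s' matches %d genes", nm, nrow(hit)))
    hit
  }
  a <- find_anchor(upstream)
  b <- find_anchor(downstream)
  if (a$chrom != b$chrom) abort("anchor genes lie on different chromosomes")
  left <- if (a$start <= b$start) a else b
  right <- if (a$start <= b$start) b else a
  s <- left$end + 1L
  e <- right$start - 1L
  if (e < s) abort("anchor genes leave no interval between them")
  structure(tibble(assembly = assembly, chrom = a$chrom, start = s, end = e,
                   upstream = upstream, downstream = downstream),
            class = c("cluster_locus", class(tibble())))
}

#' Count distinct fingerprint arrays
#'
#' Collapses a per-gene annotation table to the repertoire of distinct
#' fingerprint arrays (exact ordered identity) with their copy numbers.
#'
#' @param annot Per-gene tibble from [annotate_genes()] (needs `fingerprint`
#'   and `class`).
#' @param coding_only Count only `class == "coding"` genes (default), as the
#'   repertoire analysis does; set `FALSE` to include pseudogene/other
#'   arrays.
#' @return A tibble `array`, `n` sorted by decreasing copy number; genes
#'   without fingers are dropped.
#' @export
distinct_arrays <- function(annot, coding_only = TRUE) {
  x <- annot
  if (coding_only) x <- filter(x, .data$class == "coding")
  x %>%
    filter(nzchar(.data$fingerprint)) %>%
    count(array = .data$fingerprint, name = "n") %>%
    arrange(dplyr::desc(.data$n), .data$array)
}

#' Compare fingerprint repertoires across assemblies
#'
#' An array is shared between two assemblies iff its identity string is
#' present in both; sharing is assessed on distinct arrays, with copy-number
#' agreement reported separately (shared arrays often differ in
#' representation between assemblies).
#'
#' @param arrays Named list of [distinct_arrays()] tibbles, one per assembly
#'   (at least two).
#' @return An object of class `repertoire_comparison`: list with
#'   `per_assembly` (assembly, n_distinct, n_copies) and `pairwise`
#'   (assembly_a, assembly_b, shared, shared_equal_copy, unique_a, unique_b).
#'   Use [tidy()] for the pairwise table.
#' @export
compare_repertoires <- function(arrays) {
  stopifnot(is.list(arrays), length(arrays) >= 2L, !is.null(names(arrays)))
  per <- purrr::imap(arrays, function(tb, nm) {
    tibble(assembly = nm, n_distinct = nrow(tb), n_copies = sum(tb$n))
  }) %>% bind_rows()

  nms <- names(arrays)
  pairs <- utils::combn(nms, 2L, simplify = FALSE)
  pw <- purrr::map(pairs, function(p) {
    a <- arrays[[p[1]]]; b <- arrays[[p[2]]]
    common <- intersect(a$array, b$array)
    eq <- sum(a$n[match(common, a$array)] == b$n[match(common, b$array)])
    tibble(assembly_a = p[1], assembly_b = p[2],
           shared = length(common), shared_equal_copy = eq,
           unique_a = nrow(a) - length(common),
           unique_b = nrow(b) - length(common))
  }) %>% bind_rows()

  structure(list(per_assembly = per, pairwise = pw, arrays = arrays),
            class = "repertoire_comparison")
}

#' @export
print.repertoire_comparison <- function(x, ...) {
  cat("<repertoire_comparison>\n")
  print(x$per_assembly)
  print(x$pairwise)
  invisible(x)
}

#' @rdname compare_repertoires
#' @param x A `repertoire_comparison` object.
#' @param ... Unused.
#' @export
tidy.repertoire_comparison <- function(x, ...) {
  x$pairwise
}

#' @rdname compare_repertoires
#' @export
glance.repertoire_comparison <- function(x, ...) {
  tibble(n_assemblies = nrow(x$per_assembly),
         total_distinct = length(unique(unlist(lapply(x$arrays, `[[`, "array")))),
         mean_shared = mean(x$pairwise$shared))
}

#' Pairwise 3'-exon distance matrix
#'
#' Distance between two genes is one minus the identity fraction of the
#' global (Needleman-Wunsch) alignment of their zinc-finger-exon DNA
#' sequences, scored with match +1, mismatch -1, gap open -4, gap extend -1;
#' identity is matches over alignment columns. Whole-exon DNA (coding
#' portion and UTR alike) is compared so that truncating point mutations do
#' not mask recent common descent.
#'
#' @param annot Per-gene tibble from [annotate_genes()] with `gene_id` and
#'   `exon3_seq`; genes with no zinc-finger exon are excluded and reported in
#'   the `excluded` attribute.
#' @return A symmetric numeric matrix (0 diagonal) with gene ids as
#'   dimnames; attribute `excluded` lists dropped gene ids.
#' @export
exon3_distances <- function(annot) {
  keep <- !is.na(annot$exon3_seq) & nzchar(annot$exon3_seq %||% "")
  excluded <- annot$gene_id[!keep]
  if (length(excluded) > 0L) {
    warn(paste("genes without a 3' zinc-finger exon excluded:",
               paste(excluded, collapse = ", ")))
  }
  x <- annot[keep, ]
  n <- nrow(x)
  D <- matrix(0, n, n, dimnames = list(x$gene_id, x$gene_id))
  if (n >= 2L) {
    submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    seqs <- Biostrings::DNAStringSet(x$exon3_seq)
    for (i in seq_len(n - 1L)) {
      aln <- Biostrings::pairwiseAlignment(
        rep(seqs[i], n - i), seqs[(i + 1L):n], type = "global",
        substitutionMatrix = submat, gapOpening = 4, gapExtension = 1)
      ident <- Biostrings::pid(aln, type = "PID1") / 100
      D[i, (i + 1L):n] <- 1 - ident
      D[(i + 1L):n, i] <- 1 - ident
    }
  }
  attr(D, "excluded") <- excluded
  D
}

#' Group genes by 3'-exon similarity
#'
#' Single-linkage agglomeration of the distance matrix cut at `threshold`;
#' genes closer than the threshold to any group member join that group.
#' Group labels are deterministic: numbered by the leftmost member's
#' coordinate when `positions` are given, else by first occurrence.
#'
#' @param distances Symmetric matrix from [exon3_distances()].
#' @param threshold Distance cut (default 0.05, i.e. 95% alignment
#'   identity).
#' @param positions Optional named numeric vector (gene id -> coordinate)
#'   used to order group labels.
#' @return A tibble `gene_id`, `group` (integer labels from 1).
#' @export
similarity_groups <- function(distances, threshold = 0.05, positions = NULL) {
  stopifnot(is.matrix(distances), nrow(distances) == ncol(distances))
  ids <- rownames(distances)
  if (nrow(distances) == 0L) return(tibble(gene_id = character(), group = integer()))
  if (nrow(distances) == 1L) return(tibble(gene_id = ids, group = 1L))
  hc <- hclust(as.dist(distances), method = "single")
  raw <- cutree(hc, h = threshold)
  key <- if (!is.null(positions)) {
    vapply(split(unname(positions[ids]), raw), min, numeric(1))
  } else {
    vapply(split(seq_along(ids), raw), min, numeric(1))
  }
  new_lab <- match(raw, as.integer(names(sort(key))))
  tibble(gene_id = ids, group = as.integer(new_lab))
}

#' Detect duplicated gene blocks from similarity groups
#'
#' Scans the positional sequence of group labels for maximal runs of at
#' least `min_block_len` labels that occur, in order or exactly reversed
#' (inverted duplication), at two or more non-overlapping positions.
#' Overlapping candidates are resolved longest-first, ties by leftmost
#' occurrence. Shorter repeated runs (length 2) are reported separately as
#' partial-duplication candidates, not blocks.
#'
#' @param genes Tibble with `gene_id`, `start` (cluster coordinate) and
#'   `group` (from [similarity_groups()]).
#' @param min_block_len Minimum number of genes per block (default 3).
#' @return A tibble, one row per block occurrence: `block_id`, `occurrence`,
#'   `orientation` (`forward`/`reverted`), `first_gene_index`,
#'   `last_gene_index`, `n_genes`, `gene_ids` (comma-separated), `start`,
#'   `end`. Attribute `partials` holds length-2 candidates in the same
#'   shape.
#' @export
detect_blocks <- function(genes, min_block_len = 3L) {
  stopifnot(all(c("gene_id", "start", "group") %in% names(genes)))
  g <- arrange(genes, .data$start)
  lab <- g$group
  n <- length(lab)

  find_occurrences <- function(key) {
    L <- length(key)
    rkey <- rev(key)
    occ <- list()
    for (j in seq_len(n - L + 1L)) {
      w <- lab[j:(j + L - 1L)]
      if (identical(w, key)) {
        occ[[length(occ) + 1L]] <- list(at = j, orientation = "forward")
      } else if (identical(w, rkey)) {
        occ[[length(occ) + 1L]] <- list(at = j, orientation = "reverted")
      }
    }
    occ
  }

  # One pass at a fixed length: candidates scanned left to right, occurrences
  # chosen greedily, positions claimed so shorter blocks never reuse them.
  collect_len <- function(L, claimed) {
    out <- list()
    seen <- character(0)
    for (i in seq_len(n - L + 1L)) {
      key <- lab[i:(i + L - 1L)]
      kstr <- paste(key, collapse = ",")
      rstr <- paste(rev(key), collapse = ",")
      if (kstr %in% seen || rstr %in% seen) next
      seen <- c(seen, kstr)
      occ <- find_occurrences(key)
      if (length(occ) < 2L) next
      chosen <- list()
      last_end <- 0L
      for (o in occ) {
        idx <- o$at:(o$at + L - 1L)
        if (o$at > last_end && !any(claimed[idx])) {
          chosen[[length(chosen) + 1L]] <- o
          last_end <- o$at + L - 1L
        }
      }
      if (length(chosen) >= 2L) {
        out[[length(out) + 1L]] <- list(key = key, L = L, occ = chosen,
                                        first = chosen[[1]]$at)
        for (o in chosen) claimed[o$at:(o$at + L - 1L)] <- TRUE
      }
    }
    list(blocks = out, claimed = claimed)
  }

  claimed <- rep(FALSE, n)
  max_len <- n %/% 2L
  found <- list()
  if (max_len >= min_block_len) {
    for (L in seq(max_len, min_block_len)) {
      res <- collect_len(L, claimed)
      claimed <- res$claimed
      found <- c(found, res$blocks)
    }
  }
  # order blocks by leftmost occurrence for stable ids
  if (length(found) > 0L) {
    found <- found[order(vapply(found, `[[`, integer(1), "first"))]
  }

  occ_tbl <- function(blocks, prefix) {
    rows <- list()
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      for (oi in seq_along(b$occ)) {
        o <- b$occ[[oi]]
        idx <- o$at:(o$at + b$L - 1L)
        rows[[length(rows) + 1L]] <- tibble(
          block_id = sprintf("%s%d", prefix, bi), occurrence = oi,
          orientation = o$orientation,
          first_gene_index = o$at, last_gene_index = o$at + b$L - 1L,
          n_genes = b$L,
          gene_ids = paste(g$gene_id[idx], collapse = ","),
          start = min(g$start[idx]), end = max(g$start[idx])
        )
      }
    }
    if (length(rows) == 0L) {
      tibble(block_id = character(), occurrence = integer(),
             orientation = character(), first_gene_index = integer(),
             last_gene_index = integer(), n_genes = integer(),
             gene_ids = character(), start = numeric(), end = numeric())
    } else {
      bind_rows(rows)
    }
  }

  partials <- list()
  if (min_block_len > 2L && n >= 4L) {
    res2 <- collect_len(2L, claimed)
    partials <- res2$blocks
    if (length(partials) > 0L) {
      partials <- partials[order(vapply(partials, `[[`, integer(1), "first"))]
    }
  }

  out <- occ_tbl(found, "B")
  attr(out, "partials") <- occ_tbl(partials, "P")
  out
}
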