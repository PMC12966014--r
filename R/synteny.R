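## Syntenic ortholog detection and fragment chaining.
##
## A homolog pair is syntenic when enough other homolog pairs sit within a
## rank window around it in both genomes (collinear flanking support).
## Syntenic fragments then consolidate adjacent pairs under the rule:
## fewer than `maxGeneGap` intervening genes (strict <) OR a physical
## distance of at most `maxBpGap` (inclusive), evaluated in both genomes.

#' SyntenicFragments: chained syntenic gene pairs
#'
#' Container produced by \code{\link{chainFragments}}.
#'
#' @slot fragments data.frame, one row per fragment (intervals in both
#'   genomes, member count, orientation).
#' @slot members data.frame of syntenic pairs with their
#'   \code{fragment_id}.
#' @export
setClass("SyntenicFragments",
  representation(fragments = "data.frame", members = "data.frame"))

setMethod("show", "SyntenicFragments", function(object) {
  cat("SyntenicFragments:", nrow(object@fragments), "fragments over",
      nrow(object@members), "syntenic pairs\n")
  if (nrow(object@fragments)) {
    or <- table(object@fragments$orientation)
    cat("  orientation:",
        paste(names(or), or, sep = "=", collapse = " "), "\n")
  }
})

#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))
#' @rdname SyntenicFragments-class
#' @param x a \code{SyntenicFragments}.
#' @export
setMethod("fragments", "SyntenicFragments", function(x) x@fragments)

#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname SyntenicFragments-class
#' @export
setMethod("members", "SyntenicFragments", function(x) x@members)

#' Detect syntenic gene pairs from homology plus gene order
#'
#' A homolog pair (a, b) is emitted when at least \code{minSupport} other
#' homolog pairs (a', b') lie within \code{flankWindow} gene ranks of a
#' and of b on the same chromosome combination. Emitted pairs are then
#' deduplicated to the best-supported pair per gene within each
#' chromosome combination (ties: higher similarity, then lexicographic
#' partner id), so a gene keeps at most one partner per chromosome pair
#' while a duplicated genome still recovers one partner per copy.
#'
#' @param annotA,annotB \code{GenomeAnnotation} objects.
#' @param homology data.frame with \code{gene_a} (in \code{annotA}),
#'   \code{gene_b} (in \code{annotB}), \code{similarity}.
#' @param flankWindow rank window for flanking support.
#' @param minSupport minimum number of supporting flanking pairs.
#' @return data.frame of syntenic pairs with positions in both genomes
#'   and a \code{support} column.
#' @export
detectSyntenicPairs <- function(annotA, annotB, homology,
                                flankWindow = 20, minSupport = 2) {
  if (!nrow(homology))
    return(.emptyPairs())
  ga <- geneTable(annotA); gb <- geneTable(annotB)
  ia <- match(homology$gene_a, ga$gene_id)
  ib <- match(homology$gene_b, gb$gene_id)
  if (anyNA(ia) || anyNA(ib))
    stop("homology references genes absent from the annotations")
  h <- data.frame(
    gene_a = homology$gene_a, gene_b = homology$gene_b,
    similarity = homology$similarity,
    chrom_a = ga$chrom[ia], rank_a = ga$rank[ia],
    start_a = ga$start[ia], end_a = ga$end[ia], strand_a = ga$strand[ia],
    chrom_b = gb$chrom[ib], rank_b = gb$rank[ib],
    start_b = gb$start[ib], end_b = gb$end[ib], strand_b = gb$strand[ib],
    stringsAsFactors = FALSE)
  grp <- paste(h$chrom_a, h$chrom_b, sep = "\r")
  parts <- split(seq_len(nrow(h)), grp)
  keep <- integer(0)
  support <- integer(nrow(h))
  for (idx in parts) {
    ra <- h$rank_a[idx]; rb <- h$rank_b[idx]
    ## support = collinear flanking homolog pairs within the window on
    ## both sides (self excluded)
    supp <- vapply(seq_along(idx), function(k)
      sum(abs(ra - ra[k]) <= flankWindow & abs(rb - rb[k]) <= flankWindow) - 1L,
      integer(1))
    support[idx] <- supp
    ok <- idx[supp >= minSupport]
    if (!length(ok)) next
    ## best-support-per-gene dedup within this chromosome combination
    o <- ok[order(-support[ok], -h$similarity[ok], h$gene_a[ok], h$gene_b[ok])]
    seenA <- character(0); seenB <- character(0)
    for (r in o) {
      if (h$gene_a[r] %in% seenA || h$gene_b[r] %in% seenB) next
      keep <- c(keep, r)
      seenA <- c(seenA, h$gene_a[r]); seenB <- c(seenB, h$gene_b[r])
    }
  }
  if (!length(keep)) return(.emptyPairs())
  out <- h[sort(keep), , drop = FALSE]
  out$support <- support[sort(keep)]
  rownames(out) <- NULL
  out
}

.emptyPairs <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             similarity = numeric(),
             chrom_a = character(), rank_a = integer(),
             start_a = numeric(), end_a = numeric(), strand_a = character(),
             chrom_b = character(), rank_b = integer(),
             start_b = numeric(), end_b = numeric(), strand_b = character(),
             support = integer(), stringsAsFactors = FALSE)
}

## gap between two gene intervals: 0 when they overlap, else bp between
## the nearest ends
.bpGap <- function(s1, e1, s2, e2) pmax(0, pmax(s1, s2) - pmin(e1, e2) - 1)

#' Chain syntenic pairs into syntenic fragments
#'
#' Within each chromosome combination, two pairs that are adjacent in the
#' gene order of either genome are consolidated into one fragment when,
#' in each required genome, they are separated by fewer than
#' \code{maxGeneGap} intervening genes (strict) or by at most
#' \code{maxBpGap} bp (inclusive; distance between the nearest ends of
#' the boundary genes). Fragments are the maximal sets closed under this
#' relation and partition the input pairs; the relation is symmetric in
#' the two genomes, so swapping them mirrors the fragments. Orientation
#' is \code{"same"}/\code{"inverted"} when at least 90\% of consecutive
#' member pairs agree in genome-B rank direction, else \code{"mixed"}.
#'
#' @param pairs data.frame from \code{\link{detectSyntenicPairs}}.
#' @param maxGeneGap intervening-gene bound (default 50, strict).
#' @param maxBpGap physical-distance bound in bp (default 300000,
#'   inclusive).
#' @param bothGenomes when \code{TRUE} (default) the gene-count/distance
#'   disjunction must hold in both genomes; \code{FALSE} applies it in
#'   genome A (the reference) only.
#' @return a \code{\link{SyntenicFragments}} object.
#' @export
chainFragments <- function(pairs, maxGeneGap = 50, maxBpGap = 300000,
                           bothGenomes = TRUE) {
  if (!nrow(pairs))
    return(new("SyntenicFragments",
               fragments = .emptyFragments(), members = pairs))
  grp <- paste(pairs$chrom_a, pairs$chrom_b, sep = "\r")
  parts <- split(seq_len(nrow(pairs)), grp)
  ## union-find over the merge relation
  parent <- seq_len(nrow(pairs))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- max(ri, rj)
  }
  linkOk <- function(i1, i2) {
    gapA <- abs(pairs$rank_a[i2] - pairs$rank_a[i1]) - 1L
    gapB <- abs(pairs$rank_b[i2] - pairs$rank_b[i1]) - 1L
    bpA <- .bpGap(pairs$start_a[i1], pairs$end_a[i1],
                  pairs$start_a[i2], pairs$end_a[i2])
    bpB <- .bpGap(pairs$start_b[i1], pairs$end_b[i1],
                  pairs$start_b[i2], pairs$end_b[i2])
    okA <- gapA < maxGeneGap | bpA <= maxBpGap
    okB <- gapB < maxGeneGap | bpB <= maxBpGap
    if (bothGenomes) okA & okB else okA
  }
  for (idx in parts) {
    n <- length(idx)
    if (n < 2) next
    ## candidate links: adjacency in either genome's gene order
    oa <- idx[order(pairs$rank_a[idx], pairs$rank_b[idx])]
    ob <- idx[order(pairs$rank_b[idx], pairs$rank_a[idx])]
    for (ord in list(oa, ob)) {
      ok <- linkOk(ord[-n], ord[-1])
      for (k in which(ok)) unite(ord[k], ord[k + 1])
    }
  }
  roots <- vapply(seq_len(nrow(pairs)), find, integer(1))
  fragId <- match(roots, unique(roots[order(pairs$chrom_a, pairs$rank_a,
                                            pairs$rank_b)]))
  members <- pairs
  members$fragment_id <- fragId
  frags <- do.call(rbind, lapply(split(seq_len(nrow(members)), fragId),
                                 function(i) .summarizeFragment(members[i, ])))
  frags <- frags[order(frags$fragment_id), , drop = FALSE]
  rownames(frags) <- NULL
  new("SyntenicFragments", fragments = frags, members = members)
}

.summarizeFragment <- function(m) {
  m <- m[order(m$rank_a), , drop = FALSE]
  ori <- if (nrow(m) < 2) "same" else {
    d <- sign(diff(m$rank_b))
    fa <- mean(d > 0)
    if (fa >= 0.9) "same" else if (mean(d < 0) >= 0.9) "inverted" else "mixed"
  }
  data.frame(fragment_id = m$fragment_id[1],
             chrom_a = m$chrom_a[1],
             rank_a_min = min(m$rank_a), rank_a_max = max(m$rank_a),
             start_a = min(m$start_a), end_a = max(m$end_a),
             chrom_b = m$chrom_b[1],
             rank_b_min = min(m$rank_b), rank_b_max = max(m$rank_b),
             start_b = min(m$start_b), end_b = max(m$end_b),
             n_pairs = nrow(m), orientation = ori,
             stringsAsFactors = FALSE)
}

.emptyFragments <- function() {
  data.frame(fragment_id = integer(), chrom_a = character(),
             rank_a_min = integer(), rank_a_max = integer(),
             start_a = numeric(), end_a = numeric(),
             chrom_b = character(), rank_b_min = integer(),
             rank_b_max = integer(), start_b = numeric(), end_b = numeric(),
             n_pairs = integer(), orientation = character(),
             stringsAsFactors = FALSE)
}

#' Swap the two genomes of a syntenic pair table
#'
#' @param pairs pair table from \code{\link{detectSyntenicPairs}}.
#' @return the same table with the A and B roles exchanged.
#' @export
swapPairGenomes <- function(pairs) {
  swap <- function(df, a, b) {
    tmp <- df[[a]]; df[[a]] <- df[[b]]; df[[b]] <- tmp; df
  }
  for (col in c("gene", "chrom", "rank", "start", "end", "strand"))
    pairs <- swap(pairs, paste0(col, "_a"), paste0(col, "_b"))
  pairs
}
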