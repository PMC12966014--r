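## Projection of ancestral genomic blocks onto descendant chromosomes via
## syntenic fragments, block copy counting, block-association comparison
## and chromosome fusion/rearrangement inference.

## which side of a pair table carries the ancestor-proxy genes (the genes
## listed in the block table)?
.ancestorSide <- function(members, gbTable) {
  inA <- mean(members$gene_a %in% gbTable$gene_id)
  inB <- mean(members$gene_b %in% gbTable$gene_id)
  if (inA < 0.5 && inB < 0.5)
    stop("neither genome of the fragments matches the block table")
  if (inB >= inA) "b" else "a"
}

#' Project ancestral genomic blocks onto a descendant genome
#'
#' Within each syntenic fragment (descendant vs ancestor proxy), member
#' genes are ordered along the descendant chromosome and labelled with
#' the genomic block of their ancestral partner; maximal runs of one
#' label become candidate projections. Candidates supported by fewer than
#' \code{minGenesPerCall} genes are dropped; adjacent projections of the
#' same label on one descendant chromosome separated by less than the
#' chaining gap (fewer than \code{maxGeneGap} genes or at most
#' \code{maxBpGap} bp) are merged. Copy indices are assigned per label by
#' chromosome then position. Genes without a block label reduce purity
#' (fraction of the fragment's genes carrying the projected label) but
#' never fail the call.
#'
#' @param frags \code{\link{SyntenicFragments}} linking the descendant to
#'   the ancestor proxy (either orientation; detected automatically).
#' @param gbTable block definition table
#'   (\code{\link{gbDefinitionTable}} or \code{\link{readGBTable}}).
#' @param minGenesPerCall minimum supporting genes per projection.
#' @param maxGeneGap,maxBpGap merge gap, defaulting to the chaining rule.
#' @return data.frame of projections: \code{block}, \code{chrom},
#'   \code{rank_start}, \code{rank_end}, \code{start}, \code{end},
#'   \code{n_genes}, \code{purity}, \code{copy_index}.
#' @export
projectGenomicBlocks <- function(frags, gbTable, minGenesPerCall = 5,
                                 maxGeneGap = 50, maxBpGap = 300000) {
  m <- members(frags)
  if (!nrow(m)) return(.emptyProjections())
  anc <- .ancestorSide(m, gbTable)
  if (anc == "a") m <- swapPairGenomes(m)   # descendant = side a
  lab <- gbTable$block[match(m$gene_b, gbTable$gene_id)]
  cand <- list()
  for (i in split(seq_len(nrow(m)), m$fragment_id)) {
    o <- i[order(m$rank_a[i])]
    r <- rle(ifelse(is.na(lab[o]), "\r", lab[o]))
    stops <- cumsum(r$lengths); starts <- stops - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] == "\r" || r$lengths[k] < minGenesPerCall) next
      run <- o[starts[k]:stops[k]]
      cand[[length(cand) + 1L]] <- data.frame(
        block = r$values[k], chrom = m$chrom_a[run[1]],
        rank_start = min(m$rank_a[run]), rank_end = max(m$rank_a[run]),
        start = min(m$start_a[run]), end = max(m$end_a[run]),
        n_genes = length(run),
        purity = length(run) / length(i),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(.emptyProjections())
  pr <- do.call(rbind, cand)
  ## merge adjacent same-label projections separated by less than the
  ## chaining gap (handles one block split over several fragments)
  merged <- list()
  for (i in split(seq_len(nrow(pr)), paste(pr$chrom, pr$block, sep = "\r"))) {
    i <- i[order(pr$start[i])]
    cur <- pr[i[1], , drop = FALSE]
    for (k in i[-1]) {
      geneGap <- pr$rank_start[k] - cur$rank_end - 1L
      bpGap <- .bpGap(cur$start, cur$end, pr$start[k], pr$end[k])
      if (geneGap < maxGeneGap || bpGap <= maxBpGap) {
        cur$rank_end <- max(cur$rank_end, pr$rank_end[k])
        cur$end <- max(cur$end, pr$end[k])
        cur$rank_start <- min(cur$rank_start, pr$rank_start[k])
        cur$start <- min(cur$start, pr$start[k])
        w <- c(cur$n_genes, pr$n_genes[k])
        cur$purity <- sum(w * c(cur$purity, pr$purity[k])) / sum(w)
        cur$n_genes <- sum(w)
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- pr[k, , drop = FALSE]
      }
    }
    merged[[length(merged) + 1L]] <- cur
  }
  out <- do.call(rbind, merged)
  out <- out[order(out$block, out$chrom, out$start), , drop = FALSE]
  out$copy_index <- stats::ave(seq_len(nrow(out)), out$block, FUN = seq_along)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.emptyProjections <- function() {
  data.frame(block = character(), chrom = character(),
             rank_start = integer(), rank_end = integer(),
             start = numeric(), end = numeric(), n_genes = integer(),
             purity = numeric(), copy_index = integer(),
             stringsAsFactors = FALSE)
}

#' Genomic-block copy numbers in one genome
#'
#' @param projections from \code{\link{projectGenomicBlocks}}.
#' @param gbTable block definition table (supplies the full label set so
#'   unprojected blocks are reported with copy number 0).
#' @return data.frame \code{block}, \code{copies}.
#' @export
gbCopyNumber <- function(projections, gbTable) {
  labels <- sort(unique(gbTable$block))
  n <- table(factor(projections$block, levels = labels))
  data.frame(block = labels, copies = as.integer(n),
             stringsAsFactors = FALSE)
}

## canonical "X|Y" key of an unordered label pair
.assocKey <- function(b1, b2)
  paste(pmin(b1, b2), pmax(b1, b2), sep = "|")

#' Genomic-block associations of a genome
#'
#' Orders the projections along each chromosome and records every
#' adjacent pair of distinct block labels as one unordered association;
#' duplicates are collapsed.
#'
#' @param projections from \code{\link{projectGenomicBlocks}}.
#' @return data.frame \code{block1}, \code{block2} (sorted within pair).
#' @export
extractGBAssociations <- function(projections) {
  keys <- character(0)
  for (i in split(seq_len(nrow(projections)), projections$chrom)) {
    b <- projections$block[i[order(projections$start[i])]]
    if (length(b) < 2) next
    adj <- cbind(b[-length(b)], b[-1])
    adj <- adj[adj[, 1] != adj[, 2], , drop = FALSE]
    if (nrow(adj)) keys <- c(keys, .assocKey(adj[, 1], adj[, 2]))
  }
  keys <- sort(unique(keys))
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(block1 = vapply(parts, `[`, "", 1),
             block2 = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Ancestral block associations implied by a block definition table
#'
#' @param gbTable block definition table.
#' @return data.frame \code{block1}, \code{block2}.
#' @export
gbTableAssociations <- function(gbTable) {
  keys <- character(0)
  ord <- gbTable[!duplicated(gbTable[, c("chromosome", "block")]), ]
  for (i in split(seq_len(nrow(ord)), ord$chromosome)) {
    b <- ord$block[i[order(ord$block_order[i])]]
    if (length(b) < 2) next
    keys <- c(keys, .assocKey(b[-length(b)], b[-1]))
  }
  keys <- sort(unique(keys))
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(block1 = vapply(parts, `[`, "", 1),
             block2 = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Fraction of ancestral block associations recovered in a descendant
#'
#' @param detected associations of the descendant
#'   (\code{\link{extractGBAssociations}}).
#' @param ancestral associations of the ancestor
#'   (\code{\link{gbTableAssociations}}).
#' @return fraction in [0, 1].
#' @export
associationRecoveryFraction <- function(detected, ancestral) {
  if (!nrow(ancestral))
    stop("ancestral association set is empty; fraction undefined")
  da <- .assocKey(detected$block1, detected$block2)
  an <- .assocKey(ancestral$block1, ancestral$block2)
  length(intersect(da, an)) / length(unique(an))
}

#' Infer chromosome inheritance, fusion and rearrangement events
#'
#' For each descendant chromosome, the ancestral chromosomes contributing
#' at least \code{minFraction} of its projected block span are its
#' contributors: one contributor is an intact inheritance, two or more a
#' fusion. A rearrangement flag is raised when the projected block order
#' deviates from the ancestral order (per contributor the block sequence
#' must be monotone in ancestral block order, and each contributor's
#' blocks must form one contiguous stretch).
#'
#' @param projections from \code{\link{projectGenomicBlocks}}.
#' @param gbTable block definition table.
#' @param minFraction minimal span fraction for a contributor.
#' @return list with \code{events} (data.frame: \code{chrom},
#'   \code{type} = intact/fusion/unassigned, \code{ancestors},
#'   \code{rearranged}) and convenience counts \code{n_intact},
#'   \code{n_fusion}.
#' @export
inferChromosomeEvents <- function(projections, gbTable, minFraction = 0.10) {
  blk <- gbTable[!duplicated(gbTable[, c("block", "chromosome")]),
                 c("block", "chromosome", "block_order")]
  rows <- list()
  for (i in split(seq_len(nrow(projections)), projections$chrom)) {
    i <- i[order(projections$start[i])]
    p <- projections[i, ]
    anc <- blk$chromosome[match(p$block, blk$block)]
    span <- p$end - p$start + 1
    contrib <- tapply(span, anc, sum)
    contrib <- contrib / sum(span)
    keep <- names(contrib)[contrib >= minFraction]
    type <- if (length(keep) == 0) "unassigned" else
      if (length(keep) == 1) "intact" else "fusion"
    ## order consistency of the contributing blocks
    sel <- anc %in% keep
    ordIdx <- blk$block_order[match(p$block, blk$block)][sel]
    ancSel <- anc[sel]
    mono <- vapply(split(ordIdx, ancSel), function(o) {
      o <- o[!duplicated(o)]
      length(o) < 2 || all(diff(o) > 0) || all(diff(o) < 0)
    }, logical(1))
    contiguous <- vapply(unique(ancSel), function(a) {
      w <- which(ancSel == a)
      all(diff(w) == 1)
    }, logical(1))
    rearranged <- !(all(mono) && all(contiguous))
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = p$chrom[1], type = type,
      ancestors = paste(sort(keep), collapse = "+"),
      rearranged = rearranged, stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, rows)
  list(events = ev,
       n_intact = sum(ev$type == "intact"),
       n_fusion = sum(ev$type == "fusion"))
}
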