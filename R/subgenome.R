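## Subgenome partitioning, gene retention and homoeolog expression
## dominance for a tetraploid.

#' Pair homoeologous chromosomes of a tetraploid
#'
#' Takes syntenic pairs computed within the tetraploid (self-synteny via
#' paralog homology) and matches chromosomes greedily by the number of
#' shared syntenic pairs (heaviest edge first), a maximum-weight matching
#' in the regime where homoeolog links dominate.
#'
#' @param selfPairs syntenic pair table within one genome
#'   (\code{\link{detectSyntenicPairs}} of an annotation against itself);
#'   same-chromosome pairs are ignored.
#' @param annot the tetraploid \code{GenomeAnnotation} (supplies the full
#'   chromosome set).
#' @return data.frame \code{chrom1}, \code{chrom2}, \code{weight}.
#' @export
pairHomoeologousChromosomes <- function(selfPairs, annot) {
  chroms <- chromosomes(annot)
  if (length(chroms) %% 2L != 0L)
    stop("odd chromosome count (", length(chroms),
         "); cannot pair: ", paste(chroms, collapse = ", "))
  sp <- selfPairs[selfPairs$chrom_a != selfPairs$chrom_b, , drop = FALSE]
  key <- .assocKey(sp$chrom_a, sp$chrom_b)
  w <- sort(table(key), decreasing = TRUE)
  used <- character(0)
  rows <- list()
  for (k in names(w)) {
    cc <- strsplit(k, "|", fixed = TRUE)[[1]]
    if (any(cc %in% used)) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom1 = cc[1], chrom2 = cc[2], weight = as.integer(w[[k]]),
      stringsAsFactors = FALSE)
    used <- c(used, cc)
  }
  un <- setdiff(chroms, used)
  if (length(un))
    stop("unmatched chromosomes (no homoeolog synteny): ",
         paste(un, collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign subgenomes by gene density
#'
#' Within each homoeologous chromosome pair, the chromosome with the
#' higher gene density (genes per Mb) is assigned to subgenome A (DsA)
#' and its partner to DsB. Equal densities are broken by chromosome name
#' order with a warning. When \code{linkageGroups} (two chromosome sets
#' that are known to travel together, e.g. from cross-pair synteny) are
#' supplied, per-pair assignments conflicting with the group majority are
#' overridden (reported via \code{message}).
#'
#' @param pairing from \code{\link{pairHomoeologousChromosomes}}.
#' @param annot the tetraploid \code{GenomeAnnotation}.
#' @param linkageGroups optional list of two character vectors of
#'   chromosome names.
#' @return data.frame \code{chrom}, \code{subgenome}, \code{density},
#'   \code{pair_id}.
#' @export
assignSubgenomesByDensity <- function(pairing, annot, linkageGroups = NULL) {
  gt <- geneTable(annot)
  len <- chromosomeLengths(annot)
  dens <- table(factor(gt$chrom, levels = names(len))) / (len / 1e6)
  rows <- list()
  for (i in seq_len(nrow(pairing))) {
    c1 <- pairing$chrom1[i]; c2 <- pairing$chrom2[i]
    d1 <- dens[[c1]]; d2 <- dens[[c2]]
    if (d1 == d2) {
      warning("equal gene density for ", c1, " and ", c2,
              "; tie broken by chromosome name order")
      first <- min(c1, c2) == c1
    } else first <- d1 > d2
    rows[[i]] <- data.frame(
      chrom = c(c1, c2),
      subgenome = if (first) c("DsA", "DsB") else c("DsB", "DsA"),
      density = c(d1, d2), pair_id = i, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(linkageGroups)) {
    stopifnot(length(linkageGroups) == 2)
    for (g in seq_along(linkageGroups)) {
      grp <- linkageGroups[[g]]
      lab <- out$subgenome[match(grp, out$chrom)]
      maj <- if (mean(lab == "DsA", na.rm = TRUE) >= 0.5) "DsA" else "DsB"
      conflict <- grp[!is.na(lab) & lab != maj]
      if (length(conflict)) {
        message("linkage-group majority overrides density assignment for: ",
                paste(conflict, collapse = ", "))
        ## flip the whole pair to keep one chromosome per subgenome
        for (ch in conflict) {
          pid <- out$pair_id[out$chrom == ch]
          sel <- out$pair_id == pid
          out$subgenome[sel] <- ifelse(out$subgenome[sel] == "DsA",
                                       "DsB", "DsA")
        }
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Windowed and global gene-retention ratio against the ancestor
#'
#' An ancestral gene counts as retained when it has at least one syntenic
#' partner in the pair table. Fractions are computed in sliding windows
#' of ancestral gene ranks per ancestral chromosome, plus globally.
#'
#' @param ancestor ancestral \code{GenomeAnnotation}.
#' @param pairs syntenic pair table linking a descendant (sub)genome to
#'   the ancestor (either orientation; ancestor side detected by gene
#'   ids).
#' @param window window size in ancestral genes.
#' @param step window step.
#' @return list with \code{global} (fraction) and \code{windows}
#'   (data.frame \code{chrom}, \code{rank_start}, \code{rank_end},
#'   \code{fraction}).
#' @export
retentionRatio <- function(ancestor, pairs, window = 100, step = 50) {
  stopifnot(window >= 1, step >= 1)
  gt <- geneTable(ancestor)
  partner <- unique(c(pairs$gene_a, pairs$gene_b))
  retained <- gt$gene_id %in% partner
  rows <- list()
  for (i in split(seq_len(nrow(gt)), gt$chrom)) {
    i <- i[order(gt$rank[i])]
    n <- length(i)
    w <- min(window, n)
    if (w < window)
      message("window larger than chromosome ", gt$chrom[i[1]],
              "; using one whole-chromosome window")
    starts <- seq(1L, max(1L, n - w + 1L), by = step)
    for (s in starts) {
      sel <- i[s:(s + w - 1L)]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = gt$chrom[i[1]], rank_start = gt$rank[sel[1]],
        rank_end = gt$rank[sel[length(sel)]],
        fraction = mean(retained[sel]), stringsAsFactors = FALSE)
    }
  }
  list(global = mean(retained), windows = do.call(rbind, rows))
}

#' Per-subgenome retention against the ancestor
#'
#' @param ancestor ancestral annotation.
#' @param pairs syntenic pair table tetraploid-vs-ancestor.
#' @param partition from \code{\link{assignSubgenomesByDensity}}.
#' @inheritParams retentionRatio
#' @return named list of \code{\link{retentionRatio}} results, one per
#'   subgenome.
#' @export
subgenomeRetention <- function(ancestor, pairs, partition,
                               window = 100, step = 50) {
  ## which side of the pair table is the descendant?
  descSide <- if (mean(pairs$chrom_a %in% partition$chrom) >
                  mean(pairs$chrom_b %in% partition$chrom)) "a" else "b"
  chromCol <- paste0("chrom_", descSide)
  out <- list()
  for (sg in c("DsA", "DsB")) {
    chr <- partition$chrom[partition$subgenome == sg]
    out[[sg]] <- retentionRatio(ancestor,
                                pairs[pairs[[chromCol]] %in% chr, ,
                                      drop = FALSE],
                                window = window, step = step)
  }
  out
}

#' Homoeolog gene pairs of a duplicated genome
#'
#' Ground-truth pairing from the simulator's family labels: families with
#' exactly one gene in each subgenome yield one pair (gene in subgenome A
#' first).
#'
#' @param annot tetraploid \code{GenomeAnnotation} with \code{subgenome}
#'   truth labels.
#' @return data.frame \code{gene_a}, \code{gene_b}.
#' @export
homoeologPairs <- function(annot) {
  gt <- geneTable(annot)
  gt <- gt[!is.na(gt$subgenome), ]
  a <- gt[gt$subgenome == "A", ]; b <- gt[gt$subgenome == "B", ]
  m <- merge(a[, c("family", "gene_id")], b[, c("family", "gene_id")],
             by = "family", suffixes = c("_a", "_b"))
  m <- m[stats::ave(seq_len(nrow(m)), m$family, FUN = length) == 1, ]
  data.frame(gene_a = m$gene_id_a, gene_b = m$gene_id_b,
             stringsAsFactors = FALSE)
}

#' Homoeolog expression dominance counts
#'
#' For each homoeolog pair the TPM values of the selected samples are
#' averaged per gene and the linear fold ratio
#' \code{(tpmA + pseudocount) / (tpmB + pseudocount)} is computed with
#' the DsA copy in the numerator. At each threshold f the pair counts as
#' A-dominant when the ratio exceeds f and B-dominant when its inverse
#' does (strict inequalities, so f = 1 already excludes exactly balanced
#' pairs). A two-sided binomial sign test (null probability 0.5 over the
#' dominant pairs) probes for subgenome bias at each threshold.
#'
#' @param annot tetraploid annotation (maps genes to chromosomes).
#' @param pairs homoeolog gene pairs (\code{gene_a}, \code{gene_b}), e.g.
#'   \code{\link{homoeologPairs}} or syntenic pairs between paired
#'   chromosomes.
#' @param partition subgenome partition
#'   (\code{\link{assignSubgenomesByDensity}}).
#' @param expr \code{SummarizedExperiment} with a \code{tpm} assay, or a
#'   TPM matrix.
#' @param samples optional sample ids to use (e.g. one tissue); default
#'   all. Replicates are averaged before the ratio.
#' @param thresholds fold thresholds (default 1..8).
#' @param pseudocount TPM pseudocount stabilizing near-zero ratios.
#' @param log2Mode when \code{TRUE}, thresholds are interpreted on the
#'   |log2 ratio| scale instead of the linear ratio.
#' @return data.frame \code{threshold}, \code{n_a_dominant},
#'   \code{n_b_dominant}, \code{p_value}; attribute \code{"skipped"}
#'   counts pairs absent from the matrix.
#' @export
expressionDominance <- function(annot, pairs, partition, expr,
                                samples = NULL, thresholds = 1:8,
                                pseudocount = 0.1, log2Mode = FALSE) {
  m <- if (is(expr, "SummarizedExperiment"))
    SummarizedExperiment::assay(expr, "tpm") else expr
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  gt <- geneTable(annot)
  sg <- partition$subgenome[match(gt$chrom[match(pairs$gene_a, gt$gene_id)],
                                  partition$chrom)]
  ## orient every pair DsA-first
  flip <- !is.na(sg) & sg == "DsB"
  a <- ifelse(flip, pairs$gene_b, pairs$gene_a)
  b <- ifelse(flip, pairs$gene_a, pairs$gene_b)
  ## self-synteny tables list each pair in both orientations; keep one
  dup <- duplicated(paste(a, b, sep = "\r"))
  a <- a[!dup]; b <- b[!dup]
  present <- a %in% rownames(m) & b %in% rownames(m)
  skipped <- sum(!present)
  a <- a[present]; b <- b[present]
  ea <- rowMeans(m[a, , drop = FALSE])
  eb <- rowMeans(m[b, , drop = FALSE])
  fold <- (ea + pseudocount) / (eb + pseudocount)
  stat <- if (log2Mode) abs(log2(fold)) else NULL
  rows <- lapply(thresholds, function(f) {
    if (log2Mode) {
      adom <- stat > f & fold > 1; bdom <- stat > f & fold < 1
    } else {
      adom <- fold > f; bdom <- 1 / fold > f
    }
    na <- sum(adom); nb <- sum(bdom)
    p <- if (na + nb == 0) 1 else binom.test(na, na + nb)$p.value
    data.frame(threshold = f, n_a_dominant = na, n_b_dominant = nb,
               p_value = p)
  })
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}
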