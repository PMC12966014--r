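## Forward simulator of karyotype evolution.
##
## Gene coordinates live on a uniform slot grid: gene in slot k occupies
## [(k-1)*spacing + 1, (k-1)*spacing + geneLength]. The grid makes both
## halves of the fragment-chaining rule (intervening gene count and bp
## distance) exercisable: gene loss leaves empty slots, so bp gaps grow
## while rank gaps close up.

#' Bundled ancestral block-to-chromosome layout
#'
#' Returns the bundled layout of 22 genomic-block labels (letters drawn
#' from A..X; N and P are unused because the adjacent classical blocks M+N
#' and O+P are merged) over the 8 ancestral chromosomes ACK1..ACK8. This
#' is a synthetic stand-in layout for simulation: downstream quantities
#' (copy numbers, association recovery, fusion inference) depend only on
#' block membership and order, not on which letter sits where.
#'
#' @return data.frame with columns \code{block}, \code{chromosome},
#'   \code{order}.
#' @export
ackBlockLayout <- function() {
  path <- system.file("extdata", "ack_block_layout.tsv",
                      package = "KaryoTrace", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

## internal gene table <-> GenomeAnnotation, carrying the slot grid
.grid <- function(annot) {
  md <- metadata(genes(annot))
  list(spacing = md$spacing_bp %||% 10000, geneLen = md$gene_length_bp %||% 2000)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.dfToAnnot <- function(df, genomeId, spacing, geneLen) {
  df$start <- (df$slot - 1L) * spacing + 1
  df$end <- df$start + geneLen - 1
  sl <- vapply(split(df$slot, df$chrom), function(s) (max(s) + 1) * spacing,
               numeric(1))
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
  gr$gene_id <- df$gene_id
  gr$family <- df$family
  gr$gb_label <- df$gb_label
  gr$subgenome <- df$subgenome
  gr$slot <- df$slot
  seqlevels(gr) <- names(sl)
  seqlengths(gr) <- sl
  gr <- computeRanks(gr)
  metadata(gr)$spacing_bp <- spacing
  metadata(gr)$gene_length_bp <- geneLen
  new("GenomeAnnotation", genomeId = genomeId, genes = gr)
}

.annotToDf <- function(annot) {
  g <- genes(annot)
  data.frame(gene_id = g$gene_id, chrom = as.character(seqnames(g)),
             strand = as.character(strand(g)), rank = g$rank,
             family = g$family,
             gb_label = if (is.null(g$gb_label)) NA_character_ else g$gb_label,
             subgenome = if (is.null(g$subgenome)) NA_character_ else g$subgenome,
             slot = if (is.null(g$slot)) g$rank + 1L else g$slot,
             stringsAsFactors = FALSE)
}

#' Build an ancestral karyotype with labelled genomic blocks
#'
#' Creates an 8-chromosome ancestor whose genes are partitioned into
#' contiguous genomic blocks following the bundled block-to-chromosome
#' layout (\code{\link{ackBlockLayout}}). Every gene carries its block
#' label (\code{gb_label}) and founds its own gene family (its orthologs
#' and paralogs in descendant genomes inherit the family label).
#'
#' @param nBlocks number of blocks (default 22; more than 26 exceeds the
#'   single-letter label space and is an error). When fewer than 22,
#'   the first rows of the layout are used and chromosomes left without
#'   blocks are dropped.
#' @param genesPerBlock genes per block.
#' @param spacingBp bp per gene slot on the uniform coordinate grid.
#' @param geneLengthBp gene length in bp (must be < \code{spacingBp}).
#' @return a \code{\link{GenomeAnnotation}} named \code{"ancestor"}.
#' @examples
#' anc <- buildAncestralKaryotype(genesPerBlock = 10)
#' anc
#' @export
buildAncestralKaryotype <- function(nBlocks = 22, genesPerBlock = 50,
                                    spacingBp = 10000, geneLengthBp = 2000) {
  stopifnot(nBlocks >= 1, genesPerBlock >= 1, geneLengthBp < spacingBp)
  if (nBlocks > 26)
    stop("nBlocks > 26 exceeds the A..Z block label space")
  layout <- ackBlockLayout()
  if (nBlocks > nrow(layout)) {
    extra <- setdiff(LETTERS, layout$block)[seq_len(nBlocks - nrow(layout))]
    layout <- rbind(layout, data.frame(block = extra, chromosome = "ACK8",
                                       order = max(layout$order) + seq_along(extra)))
  }
  layout <- layout[seq_len(nBlocks), ]
  dfs <- lapply(seq_len(nrow(layout)), function(i) {
    b <- layout$block[i]
    ids <- sprintf("ANC_%s%03d", b, seq_len(genesPerBlock))
    data.frame(gene_id = ids, chrom = layout$chromosome[i], strand = "+",
               family = ids, gb_label = b, subgenome = NA_character_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, dfs)
  ## running slot index within each chromosome, in layout order
  df$slot <- stats::ave(seq_len(nrow(df)), df$chrom, FUN = seq_along)
  .dfToAnnot(df, "ancestor", spacingBp, geneLengthBp)
}

#' Derive the genomic-block definition table of an annotation
#'
#' Uses the per-gene block labels (ground truth for simulated genomes; for
#' real data the table would be read with \code{\link{readGBTable}}).
#'
#' @param annot a \code{GenomeAnnotation} whose genes carry \code{gb_label}.
#' @return data.frame with columns \code{block}, \code{chromosome},
#'   \code{gene_id}, \code{block_order} (order of the block along its
#'   chromosome).
#' @export
gbDefinitionTable <- function(annot) {
  df <- geneTable(annot)
  df <- df[!is.na(df$gb_label), ]
  df <- df[order(df$chrom, df$rank), ]
  first <- !duplicated(df[, c("chrom", "gb_label")])
  ord <- stats::ave(as.integer(first), df$chrom, FUN = cumsum)
  data.frame(block = df$gb_label, chromosome = df$chrom,
             gene_id = df$gene_id, block_order = ord,
             stringsAsFactors = FALSE)
}

#' Apply an evolution scenario to a genome
#'
#' Events are applied in order; each event draws from an independent RNG
#' stream derived from the scenario seed and the event index, so appending
#' events never perturbs earlier ones. Fusion concatenates chromosome B
#' after chromosome A (new chromosome named \code{"A-B"}); inversion
#' reverses gene order (and strand) over a gene-rank span; whole-genome
#' duplication doubles every chromosome into \code{_A}/\code{_B} copies
#' with subgenome labels; gene loss drops each gene independently, leaving
#' a physical gap on the coordinate grid. Block labels and family labels
#' are inherited unchanged.
#'
#' @param genome a \code{GenomeAnnotation} (typically from
#'   \code{\link{buildAncestralKaryotype}}).
#' @param scenario an \code{\link{EvolutionScenario}}.
#' @param genomeId name of the descendant genome; also prefixes descendant
#'   gene ids so they never collide with ancestral ids.
#' @return a \code{GenomeAnnotation} with truth columns (\code{gb_label},
#'   \code{subgenome}, \code{family}) filled in.
#' @examples
#' anc <- buildAncestralKaryotype(genesPerBlock = 10)
#' sc <- EvolutionScenario(list(fusionEvent("ACK6", "ACK8")), seed = 1)
#' dip <- applyScenario(anc, sc, genomeId = "diploid")
#' length(chromosomes(dip))  # 7
#' @export
applyScenario <- function(genome, scenario, genomeId = "descendant") {
  stopifnot(is(genome, "GenomeAnnotation"), is(scenario, "EvolutionScenario"))
  grid <- .grid(genome)
  df <- .annotToDf(genome)
  df$family <- df$gene_id          # descendants share the ancestral family
  df$gene_id <- paste0(genomeId, "_", df$gene_id)
  for (i in seq_along(scenario@events)) {
    e <- scenario@events[[i]]
    set.seed((scenario@seed + 104729L * i) %% .Machine$integer.max)
    df <- switch(e$type,
      fusion = .evFusion(df, e),
      inversion = .evInversion(df, e),
      translocation = .evTranslocation(df, e),
      wgd = .evWGD(df),
      gene_loss = .evGeneLoss(df, e),
      expression_bias = df,        # consumed by simulateExpression()
      stop("unknown event type: ", e$type))
    df <- .reRank(df)
  }
  ann <- .dfToAnnot(df, genomeId, grid$spacing, grid$geneLen)
  md <- metadata(ann@genes)
  md$scenario_seed <- scenario@seed
  bias <- Filter(function(e) e$type == "expression_bias", scenario@events)
  if (length(bias)) md$expression_bias <- bias[[length(bias)]]
  metadata(ann@genes) <- md
  ann
}

.reRank <- function(df) {
  df <- df[order(df$chrom, df$slot), ]
  df$rank <- stats::ave(seq_len(nrow(df)), df$chrom, FUN = seq_along) - 1L
  rownames(df) <- NULL
  df
}

.checkChrom <- function(df, chrom) {
  if (!chrom %in% df$chrom)
    stop("event references unknown chromosome: ", chrom)
}

.evFusion <- function(df, e) {
  .checkChrom(df, e$chromA); .checkChrom(df, e$chromB)
  newName <- paste(e$chromA, e$chromB, sep = "-")
  offset <- max(df$slot[df$chrom == e$chromA]) + 1L
  bi <- df$chrom == e$chromB
  df$slot[bi] <- df$slot[bi] + offset
  df$chrom[df$chrom == e$chromA | bi] <- newName
  df
}

.evInversion <- function(df, e) {
  .checkChrom(df, e$chrom)
  ci <- which(df$chrom == e$chrom)
  ci <- ci[order(df$rank[ci])]
  n <- length(ci)
  span <- e$span
  if (is.null(span)) {
    len <- max(2L, round(n * runif(1, 0.1, 0.3)))
    s <- sample.int(n - len + 1L, 1L) - 1L
    span <- c(s, s + len - 1L)
  }
  sel <- ci[df$rank[ci] >= span[1] & df$rank[ci] <= span[2]]
  if (length(sel) > 1L) {
    df$slot[sel] <- rev(df$slot[sel])
    df$strand[sel] <- ifelse(df$strand[sel] == "+", "-", "+")
  }
  df
}

.evTranslocation <- function(df, e) {
  .checkChrom(df, e$srcChrom); .checkChrom(df, e$destChrom)
  sel <- which(df$chrom == e$srcChrom &
               df$rank >= e$srcSpan[1] & df$rank <= e$srcSpan[2])
  sel <- sel[order(df$rank[sel])]
  if (!length(sel)) return(df)
  off <- max(df$slot[df$chrom == e$destChrom]) + 1L
  df$slot[sel] <- off + seq_along(sel) - 1L
  df$chrom[sel] <- e$destChrom
  df
}

.evWGD <- function(df) {
  a <- df; b <- df
  a$subgenome <- "A"; b$subgenome <- "B"
  a$chrom <- paste0(a$chrom, "_A"); b$chrom <- paste0(b$chrom, "_B")
  a$gene_id <- paste0(a$gene_id, "_A"); b$gene_id <- paste0(b$gene_id, "_B")
  rbind(a, b)
}

.evGeneLoss <- function(df, e) {
  keep <- runif(nrow(df)) >= e$rate
  df[keep, , drop = FALSE]
}

#' Convenience scenarios mirroring the studied karyotype history
#'
#' \code{diploidScenario()} fuses two ancestral chromosomes and then
#' rearranges the fused chromosome with one inversion spanning a random
#' 10--30\% of it (the default modelling of "fused and subsequently
#' rearranged"); \code{tetraploidScenario()} additionally applies a
#' whole-genome duplication and optional per-gene loss and expression
#' bias.
#'
#' @param fuse length-2 character vector of ancestral chromosomes to fuse.
#' @param invSpan optional explicit gene-rank span for the inversion on
#'   the fused chromosome.
#' @param seed scenario seed.
#' @return an \code{\link{EvolutionScenario}}.
#' @export
diploidScenario <- function(fuse = c("ACK6", "ACK8"), invSpan = NULL, seed = 1) {
  EvolutionScenario(list(
    fusionEvent(fuse[1], fuse[2]),
    inversionEvent(paste(fuse[1], fuse[2], sep = "-"), span = invSpan)
  ), seed = seed)
}

#' @rdname diploidScenario
#' @param lossRate per-gene loss probability applied after duplication
#'   (independently per subgenome copy); 0 disables.
#' @param biasMean,biasSd parameters of the homoeolog log2 expression
#'   ratio used later by \code{\link{simulateExpression}}.
#' @export
tetraploidScenario <- function(fuse = c("ACK6", "ACK8"), invSpan = NULL,
                               lossRate = 0, biasMean = 0, biasSd = 0.5,
                               seed = 1) {
  ev <- list(
    fusionEvent(fuse[1], fuse[2]),
    inversionEvent(paste(fuse[1], fuse[2], sep = "-"), span = invSpan),
    wgdEvent())
  if (lossRate > 0) ev <- c(ev, list(geneLossEvent(lossRate)))
  ev <- c(ev, list(expressionBiasEvent(biasMean, biasSd)))
  EvolutionScenario(ev, seed = seed)
}

#' Homology table between two annotations from shared family labels
#'
#' Emulates an all-vs-all protein homology search result for simulated
#' genomes: genes sharing a family label (i.e. descending from the same
#' ancestral gene) form a homolog pair. Self-pairs (identical gene id) are
#' excluded, so applying it to one genome against itself yields paralog /
#' homoeolog pairs.
#'
#' @param annotA,annotB \code{GenomeAnnotation} objects.
#' @param similarity constant percent identity to report, or \code{NULL}
#'   to draw uniformly from \code{simRange} (seeded by caller).
#' @param simRange range for drawn similarities.
#' @return data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{similarity}.
#' @export
makeHomologyTable <- function(annotA, annotB, similarity = 95,
                              simRange = c(92, 100)) {
  a <- geneTable(annotA)[, c("gene_id", "family")]
  b <- geneTable(annotB)[, c("gene_id", "family")]
  m <- merge(a, b, by = "family", suffixes = c("_a", "_b"))
  m <- m[m$gene_id_a != m$gene_id_b, ]
  sim <- if (is.null(similarity))
    runif(nrow(m), simRange[1], simRange[2]) else rep(similarity, nrow(m))
  out <- data.frame(gene_a = m$gene_id_a, gene_b = m$gene_id_b,
                    similarity = sim, stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}
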