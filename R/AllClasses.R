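#' @import methods
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges start end
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame
#' @importFrom GenomeInfoDb seqnames seqlengths seqlengths<- seqlevels
#'   seqlevels<-
#' @importFrom BiocGenerics strand
NULL

#' GenomeAnnotation: gene models of one genome
#'
#' A thin S4 wrapper around a \link[GenomicRanges]{GRanges} of gene models.
#' The ranges are 1-based closed (the Bioconductor convention); required
#' metadata columns are \code{gene_id}, \code{rank} (0-based ordinal of the
#' gene along its chromosome, ordered by start, ties broken by gene id) and
#' \code{family} (label shared between orthologs/paralogs descended from the
#' same ancestral gene). Optional truth columns written by the simulator:
#' \code{gb_label} (ancestral genomic-block label) and \code{subgenome}
#' (\code{"A"}/\code{"B"} after whole-genome duplication).
#'
#' @slot genomeId single string naming the genome.
#' @slot genes \code{GRanges} of gene models with the columns above and
#'   \code{seqlengths} set for every chromosome.
#' @export
setClass("GenomeAnnotation",
  representation(genomeId = "character", genes = "GRanges"))

setValidity("GenomeAnnotation", function(object) {
  msg <- character()
  g <- object@genes
  if (length(object@genomeId) != 1L || is.na(object@genomeId))
    msg <- c(msg, "genomeId must be a single string")
  need <- c("gene_id", "rank", "family")
  miss <- setdiff(need, colnames(mcols(g)))
  if (length(miss))
    msg <- c(msg, paste("missing gene columns:", paste(miss, collapse = ", ")))
  if (!length(msg) && length(g)) {
    if (anyDuplicated(g$gene_id))
      msg <- c(msg, "duplicate gene ids")
    sl <- seqlengths(g)
    if (any(is.na(sl)))
      msg <- c(msg, "all chromosomes need a length")
    else if (any(end(g) > sl[as.character(seqnames(g))]))
      msg <- c(msg, "gene interval exceeds chromosome length")
    ok <- vapply(split(g$rank, as.character(seqnames(g))), function(r)
      setequal(r, seq_along(r) - 1L), logical(1))
    if (!all(ok))
      msg <- c(msg, "ranks on each chromosome must be a permutation of 0..n-1")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname GenomeAnnotation-class
#' @param genomeId genome name.
#' @param genes a \code{GRanges} (or data.frame with columns \code{gene_id},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand}, \code{family},
#'   and optionally \code{gb_label}, \code{subgenome}).
#' @param seqlengths named chromosome lengths in bp; inferred from the
#'   maximal gene end (plus a small margin) when omitted.
#' @return a \code{GenomeAnnotation}.
#' @export
GenomeAnnotation <- function(genomeId, genes, seqlengths = NULL) {
  if (is.data.frame(genes)) {
    gr <- GRanges(genes$chrom, IRanges(genes$start, genes$end),
                  strand = if ("strand" %in% names(genes)) genes$strand else "+")
    for (col in c("gene_id", "family", "gb_label", "subgenome"))
      if (col %in% names(genes)) mcols(gr)[[col]] <- genes[[col]]
    genes <- gr
  }
  if (is.null(seqlengths)) {
    bychr <- vapply(split(end(genes), as.character(seqnames(genes))), max,
                    numeric(1))
    seqlengths <- bychr + 10000
  }
  seqlevels(genes) <- names(seqlengths)
  seqlengths(genes) <- seqlengths
  genes <- computeRanks(genes)
  new("GenomeAnnotation", genomeId = genomeId, genes = genes)
}

## rank = 0-based position by start along each chromosome, ties by gene id;
## also reorders the ranges chromosome-by-chromosome in rank order
computeRanks <- function(gr) {
  o <- order(as.character(seqnames(gr)), start(gr), gr$gene_id)
  gr <- gr[o]
  rk <- unlist(lapply(split(seq_along(gr), as.character(seqnames(gr))),
                      function(i) seq_along(i) - 1L), use.names = FALSE)
  ## split() orders by factor level; rebuild in that order
  idx <- unlist(split(seq_along(gr), as.character(seqnames(gr))),
                use.names = FALSE)
  gr$rank <- NA_integer_
  gr$rank[idx] <- rk
  gr
}

#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname GenomeAnnotation-class
#' @param x a \code{GenomeAnnotation}.
#' @export
setMethod("genomeId", "GenomeAnnotation", function(x) x@genomeId)

#' @export
setGeneric("genes", function(x, ...) standardGeneric("genes"))
#' @rdname GenomeAnnotation-class
#' @param ... unused.
#' @export
setMethod("genes", "GenomeAnnotation", function(x, ...) x@genes)

#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))

#' Gene models as a plain data.frame
#'
#' @param x a \code{GenomeAnnotation}.
#' @return data.frame with one row per gene: \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{rank}, \code{family},
#'   \code{gb_label}, \code{subgenome}.
#' @export
setMethod("geneTable", "GenomeAnnotation", function(x) {
  g <- x@genes
  df <- data.frame(
    gene_id = g$gene_id,
    chrom = as.character(seqnames(g)),
    start = start(g), end = end(g),
    strand = as.character(strand(g)),
    rank = g$rank,
    family = g$family,
    stringsAsFactors = FALSE)
  df$gb_label <- if ("gb_label" %in% colnames(mcols(g))) g$gb_label else NA
  df$subgenome <- if ("subgenome" %in% colnames(mcols(g))) g$subgenome else NA
  df
})

#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))
#' @rdname GenomeAnnotation-class
#' @export
setMethod("chromosomes", "GenomeAnnotation",
          function(x) seqlevels(x@genes))

#' @export
setGeneric("chromosomeLengths", function(x) standardGeneric("chromosomeLengths"))
#' @rdname GenomeAnnotation-class
#' @export
setMethod("chromosomeLengths", "GenomeAnnotation",
          function(x) seqlengths(x@genes))

setMethod("length", "GenomeAnnotation", function(x) length(x@genes))

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation '", object@genomeId, "': ",
      length(object@genes), " genes on ",
      length(seqlevels(object@genes)), " chromosomes\n", sep = "")
  tab <- table(as.character(seqnames(object@genes)))
  cat("  genes/chromosome: ",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n", sep = "")
  if ("gb_label" %in% colnames(mcols(object@genes)))
    cat("  genomic-block labels: ",
        length(unique(stats::na.omit(object@genes$gb_label))), "\n", sep = "")
})

#' EvolutionScenario: an ordered list of karyotype events
#'
#' Events are applied in list order by \code{\link{applyScenario}}. Build
#' events with the constructors \code{\link{fusionEvent}},
#' \code{\link{inversionEvent}}, \code{\link{translocationEvent}},
#' \code{\link{wgdEvent}}, \code{\link{geneLossEvent}} and
#' \code{\link{expressionBiasEvent}}.
#'
#' @slot events list of event objects.
#' @slot seed integer root seed; each event draws from its own stream
#'   derived deterministically from the root seed and the event index, so
#'   appending an event never perturbs earlier events.
#' @export
setClass("EvolutionScenario",
  representation(events = "list", seed = "integer"))

setValidity("EvolutionScenario", function(object) {
  msg <- character()
  types <- vapply(object@events, function(e) e$type, character(1))
  if (sum(types == "wgd") > 1L)
    msg <- c(msg, "at most one whole-genome duplication per scenario")
  for (e in object@events[types == "gene_loss"])
    if (e$rate < 0 || e$rate >= 1)
      msg <- c(msg, "gene_loss rate must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname EvolutionScenario-class
#' @param events list of events.
#' @param seed integer root seed.
#' @export
EvolutionScenario <- function(events = list(), seed = 1L)
  new("EvolutionScenario", events = events, seed = as.integer(seed))

setMethod("show", "EvolutionScenario", function(object) {
  cat("EvolutionScenario with", length(object@events),
      "events (seed", object@seed, "):\n")
  for (e in object@events) {
    par <- e[setdiff(names(e), "type")]
    cat("  -", e$type,
        if (length(par)) paste0("(", paste(names(par), unlist(lapply(par, paste, collapse = ",")),
                                           sep = "=", collapse = ", "), ")"),
        "\n")
  }
})

#' Scenario event constructors
#'
#' @param chromA,chromB chromosomes to fuse (B is appended after A).
#' @return an event object for \code{\link{EvolutionScenario}}.
#' @export
fusionEvent <- function(chromA, chromB)
  list(type = "fusion", chromA = chromA, chromB = chromB)

#' @rdname fusionEvent
#' @param chrom chromosome carrying the inversion.
#' @param span numeric length-2 vector of gene ranks (0-based, inclusive)
#'   delimiting the inverted segment, or \code{NULL} to draw a random span
#'   covering 10--30\% of the chromosome.
#' @export
inversionEvent <- function(chrom, span = NULL)
  list(type = "inversion", chrom = chrom, span = span)

#' @rdname fusionEvent
#' @param srcChrom,srcSpan source chromosome and gene-rank span to move.
#' @param destChrom chromosome receiving the segment (appended at its end).
#' @export
translocationEvent <- function(srcChrom, srcSpan, destChrom)
  list(type = "translocation", srcChrom = srcChrom, srcSpan = srcSpan,
       destChrom = destChrom)

#' @rdname fusionEvent
#' @export
wgdEvent <- function() list(type = "wgd")

#' @rdname fusionEvent
#' @param rate per-gene loss probability (applied independently per gene,
#'   hence independently per subgenome after duplication).
#' @export
geneLossEvent <- function(rate) list(type = "gene_loss", rate = rate)

#' @rdname fusionEvent
#' @param mean,sd mean and sd of the per-homoeolog-pair log2 expression
#'   ratio drawn by \code{\link{simulateExpression}}.
#' @export
expressionBiasEvent <- function(mean = 0, sd = 0.5)
  list(type = "expression_bias", mean = mean, sd = sd)
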