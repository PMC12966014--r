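## Readers/writers for the standard formats the pipeline touches.
## Everything downstream consumes GenomeAnnotation / data.frame /
## SummarizedExperiment objects built here; no raw-file parsing elsewhere.
## GFF3 (1-based closed) and BED (0-based half-open) conversion is
## delegated to rtracklayer, which maps both onto the in-memory GRanges
## convention (1-based closed).

#' Read gene models from GFF3 or BED
#'
#' GFF3 features that are not typed \code{gene} (or \code{mRNA} when no
#' \code{gene} features exist) are skipped with a warning. Gene ids come
#' from the \code{ID}/\code{Name} attribute (GFF3) or the name field
#' (BED); a \code{family} attribute is carried through when present.
#' Chromosome lengths are taken from \code{##sequence-region} directives
#' when available, otherwise inferred from the maximal gene end.
#'
#' @param path input file.
#' @param format \code{"gff3"} or \code{"bed"} (default guessed from the
#'   file extension).
#' @param genomeId genome name (default: file base name).
#' @return a \code{\link{GenomeAnnotation}}.
#' @export
readAnnotation <- function(path, format = c("auto", "gff3", "bed"),
                           genomeId = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  if (is.null(genomeId))
    genomeId <- sub("\\.[^.]+$", "", basename(path))
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  if (format == "gff3") {
    types <- as.character(gr$type)
    keep <- types == "gene"
    if (!any(keep)) keep <- types == "mRNA"
    if (any(!keep))
      warning(sum(!keep), " features without gene/mRNA typing skipped")
    gr <- gr[keep]
    ids <- gr$ID
    if (is.null(ids) || anyNA(ids)) ids <- gr$Name
    gr$gene_id <- as.character(ids)
  } else {
    gr$gene_id <- if (!is.null(gr$name)) as.character(gr$name) else
      sprintf("gene%05d", seq_along(gr))
  }
  if (anyDuplicated(gr$gene_id))
    stop("duplicate gene ids in ", path)
  fam <- if ("family" %in% colnames(mcols(gr))) as.character(gr$family) else
    gr$gene_id
  gbl <- if ("gb_label" %in% colnames(mcols(gr))) as.character(gr$gb_label) else
    NA_character_
  sgn <- if ("subgenome" %in% colnames(mcols(gr))) as.character(gr$subgenome) else
    NA_character_
  out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                 strand = strand(gr))
  out$gene_id <- gr$gene_id
  out$family <- fam
  out$gb_label <- gbl
  out$subgenome <- sgn
  sl <- seqlengths(gr)
  if (all(is.na(sl)))
    sl <- vapply(split(end(out), as.character(seqnames(out))), max,
                 numeric(1)) + 10000
  GenomeAnnotation(genomeId, out, seqlengths = sl[!is.na(sl)])
}

#' Write gene models to GFF3 or BED
#'
#' @param annot a \code{GenomeAnnotation}.
#' @param path output file.
#' @param format \code{"gff3"} (keeps \code{family}/\code{gb_label}/
#'   \code{subgenome} attributes) or \code{"bed"} (coordinates, strand and
#'   gene id only).
#' @return \code{path}, invisibly.
#' @export
writeAnnotation <- function(annot, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  g <- genes(annot)
  if (format == "gff3") {
    out <- g
    mcols(out) <- NULL
    out$source <- "KaryoTrace"
    out$type <- "gene"
    out$ID <- g$gene_id
    out$family <- g$family
    if (!is.null(g$gb_label) && !all(is.na(g$gb_label)))
      out$gb_label <- g$gb_label
    if (!is.null(g$subgenome) && !all(is.na(g$subgenome)))
      out$subgenome <- g$subgenome
    rtracklayer::export(out, path, format = "gff3")
  } else {
    out <- g
    mcols(out) <- NULL
    out$name <- g$gene_id
    out$score <- 0L
    rtracklayer::export(out, path, format = "bed")
  }
  invisible(path)
}

.readTsv <- function(path) read.delim(path, stringsAsFactors = FALSE,
                                      check.names = FALSE)

.requireCols <- function(df, cols, what, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " table ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
}

#' Read a homology table (TSV: gene_a, gene_b, similarity)
#'
#' @param path TSV file with a header.
#' @return validated data.frame.
#' @export
readHomologyTable <- function(path) {
  df <- .readTsv(path)
  .requireCols(df, c("gene_a", "gene_b", "similarity"), "homology", path)
  bad <- which(!is.finite(df$similarity) | df$similarity < 0 |
               df$similarity > 100)
  if (length(bad))
    stop("similarity out of [0,100] at line(s) ",
         paste(head(bad + 1L, 5), collapse = ", "), " of ", path)
  df
}

#' Read / write a genomic-block definition table
#'
#' TSV columns: \code{block}, \code{chromosome}, \code{gene_id},
#' \code{block_order}.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readGBTable <- function(path) {
  df <- .readTsv(path)
  .requireCols(df, c("block", "chromosome", "gene_id", "block_order"),
               "genomic-block", path)
  onechr <- tapply(df$chromosome, df$block, function(x) length(unique(x)))
  if (any(onechr > 1))
    stop("block on more than one ancestral chromosome: ",
         paste(names(onechr)[onechr > 1], collapse = ", "))
  df
}

#' @rdname readGBTable
#' @param gbTable table as returned by \code{\link{gbDefinitionTable}}.
#' @export
writeGBTable <- function(gbTable, path) {
  write.table(gbTable, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix (TSV: gene_id + one column per sample)
#'
#' @param path TSV file.
#' @param metadata optional TSV of sample metadata with a
#'   \code{sample_id} column matching the expression columns.
#' @return \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{"tpm"}.
#' @export
readExpressionMatrix <- function(path, metadata = NULL) {
  df <- .readTsv(path)
  .requireCols(df, "gene_id", "expression", path)
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  if (any(!is.finite(m)) || any(m < 0))
    stop("expression values must be finite and non-negative in ", path)
  cd <- if (!is.null(metadata)) {
    md <- .readTsv(metadata)
    .requireCols(md, "sample_id", "sample metadata", metadata)
    md <- md[match(colnames(m), md$sample_id), , drop = FALSE]
    S4Vectors::DataFrame(md, row.names = colnames(m))
  } else S4Vectors::DataFrame(row.names = colnames(m))
  SummarizedExperiment::SummarizedExperiment(assays = list(tpm = m),
                                             colData = cd)
}

#' @rdname readExpressionMatrix
#' @param se \code{SummarizedExperiment} with a \code{tpm} assay.
#' @export
writeExpressionMatrix <- function(se, path) {
  m <- SummarizedExperiment::assay(se, "tpm")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a metabolite content table (TSV: compound + samples)
#'
#' @param path TSV file.
#' @return numeric matrix compounds x samples.
#' @export
readMetaboliteTable <- function(path) {
  df <- .readTsv(path)
  .requireCols(df, "compound", "metabolite", path)
  m <- as.matrix(df[, setdiff(names(df), "compound"), drop = FALSE])
  rownames(m) <- df$compound
  if (any(!is.finite(m)) || any(m < 0))
    stop("metabolite contents must be finite and non-negative in ", path)
  m
}

#' @rdname readMetaboliteTable
#' @param m compounds x samples matrix.
#' @export
writeMetaboliteTable <- function(m, path) {
  df <- data.frame(compound = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (or XStringSet) of sequences.
#' @param path output file.
#' @param type \code{"dna"} or \code{"aa"}.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(seqs, path, type = c("dna", "aa")) {
  type <- match.arg(type)
  if (is.character(seqs))
    seqs <- if (type == "dna") Biostrings::DNAStringSet(seqs) else
      Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @param type \code{"dna"} or \code{"aa"}.
#' @return named character vector.
#' @export
readFasta <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  x <- if (type == "dna") Biostrings::readDNAStringSet(path) else
    Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}
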