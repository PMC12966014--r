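## Glycosyltransferase candidate screening: anchored PSPG-motif scan,
## expression-metabolite correlation, metabolite fold-change statistics.

## PSPG anchor residues at 1-based positions within the 44-residue motif
.PSPG_ANCHORS <- c(`1` = "W", `4` = "Q", `19` = "H", `24` = "S", `27` = "E")

#' Scan proteins for the PSPG motif by its anchor residues
#'
#' Slides a 44-residue window over each protein and scores the five
#' conserved anchor positions of the plant secondary product
#' glycosyltransferase box (W at motif position 1, Q at 4, H at 19, S at
#' 24, E at 27). Windows matching at least \code{minAnchorMatches}
#' anchors are reported; overlapping hits are collapsed to the
#' best-scoring window per protein (ties: leftmost). Proteins shorter
#' than 44 residues yield no hit.
#'
#' @param proteins named character vector (or \code{AAStringSet}) of
#'   protein sequences.
#' @param minAnchorMatches minimum anchors matched (of 5).
#' @return data.frame: \code{protein_id}, \code{motif_start} (1-based),
#'   \code{window} (the 44-mer), \code{n_anchor_matches},
#'   \code{anchor_score} (matches / 5).
#' @export
scanPSPG <- function(proteins, minAnchorMatches = 4) {
  if (!is.character(proteins)) proteins <- setNames(as.character(proteins),
                                                    names(proteins))
  offs <- as.integer(names(.PSPG_ANCHORS)) - 1L
  rows <- list()
  for (id in names(proteins)) {
    s <- strsplit(proteins[[id]], "")[[1]]
    L <- length(s)
    if (L < 44L) { message("protein ", id, " shorter than 44 aa; skipped")
                   next }
    starts <- seq_len(L - 43L)
    score <- rowSums(vapply(seq_along(offs), function(k)
      s[starts + offs[k]] == .PSPG_ANCHORS[[k]], logical(length(starts))))
    hit <- which(score >= minAnchorMatches)
    if (!length(hit)) next
    ## collapse overlapping windows to the best-scoring one
    hit <- hit[order(-score[hit], hit)]
    kept <- integer(0)
    for (h in hit)
      if (!length(kept) || all(abs(h - kept) >= 44L)) kept <- c(kept, h)
    for (h in sort(kept))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = id, motif_start = h,
        window = paste(s[h:(h + 43L)], collapse = ""),
        n_anchor_matches = as.integer(score[h]),
        anchor_score = score[h] / 5,
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(protein_id = character(), motif_start = integer(),
                      window = character(), n_anchor_matches = integer(),
                      anchor_score = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation screen of expression against a metabolite total
#'
#' For each candidate gene the Pearson correlation between its expression
#' across samples and the target metabolite total is computed; the
#' two-sided probability comes from the exact t transform
#' \code{t = r sqrt((n-2)/(1-r^2))} with n-2 degrees of freedom. A gene
#' passes under \code{r > rMin} and \code{p < pMax} (the positive
#' correlation screen). Genes with constant expression have undefined r
#' and are flagged, not dropped.
#'
#' @param expr \code{SummarizedExperiment} with a \code{tpm} assay, or a
#'   genes x samples matrix.
#' @param metaboliteTotal named numeric vector (per-sample totals, names
#'   = sample ids); must cover exactly the expression samples.
#' @param candidates gene ids to screen (default: all genes).
#' @param rMin,pMax screen thresholds.
#' @return data.frame \code{gene_id}, \code{r}, \code{p_value},
#'   \code{pass}.
#' @export
correlationScreen <- function(expr, metaboliteTotal, candidates = NULL,
                              rMin = 0.75, pMax = 1e-05) {
  m <- if (is(expr, "SummarizedExperiment"))
    SummarizedExperiment::assay(expr, "tpm") else expr
  if (is.null(names(metaboliteTotal)) ||
      !setequal(names(metaboliteTotal), colnames(m)))
    stop("metabolite samples do not match expression samples")
  y <- metaboliteTotal[colnames(m)]
  n <- length(y)
  if (n < 3) stop("need at least 3 samples for a correlation probability")
  if (is.null(candidates)) candidates <- rownames(m)
  miss <- setdiff(candidates, rownames(m))
  if (length(miss))
    stop("candidate gene(s) absent from the expression matrix: ",
         paste(head(miss, 5), collapse = ", "))
  rows <- lapply(candidates, function(g) {
    x <- m[g, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(gene_id = g, r = NA_real_, p_value = NA_real_,
                        pass = FALSE, stringsAsFactors = FALSE))
    r <- cor(x, y)
    p <- if (abs(r) >= 1) 0 else {
      t <- r * sqrt((n - 2) / (1 - r^2))
      2 * pt(-abs(t), df = n - 2)
    }
    data.frame(gene_id = g, r = r, p_value = p,
               pass = (r > rMin) && (p < pMax), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## nearest integer, halves away from zero (so 177.5 -> 178, not banker's)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Metabolite fold-change statistics and the differential filter
#'
#' Per compound: group means, the fold ratio mean(group1)/mean(group2),
#' its nearest-integer rounding (halves away from zero), and the
#' differential flag under the one-fourth rule (differential when the
#' ratio exceeds \code{differentialRatio} or falls below its inverse). A
#' zero denominator yields an infinite-fold sentinel with the flag set.
#'
#' @param metab compounds x samples matrix
#'   (\code{\link{readMetaboliteTable}} or
#'   \code{\link{simulateMetabolites}}).
#' @param group1,group2 sample id vectors.
#' @param differentialRatio flag threshold (default 4, the one-fourth
#'   rule).
#' @return data.frame \code{compound}, \code{mean_group1},
#'   \code{mean_group2}, \code{fold}, \code{fold_rounded},
#'   \code{differential}.
#' @examples
#' m <- matrix(c(454.84, 6.88), 1, 2,
#'             dimnames = list("Q3G", c("tetra", "dip")))
#' metaboliteFolds(m, "tetra", "dip")  # fold 66.11, rounded 66
#' @export
metaboliteFolds <- function(metab, group1, group2, differentialRatio = 4.0) {
  stopifnot(length(group1) >= 1, length(group2) >= 1)
  bad <- setdiff(c(group1, group2), colnames(metab))
  if (length(bad)) stop("unknown sample(s): ", paste(bad, collapse = ", "))
  m1 <- rowMeans(metab[, group1, drop = FALSE])
  m2 <- rowMeans(metab[, group2, drop = FALSE])
  fold <- ifelse(m2 == 0, ifelse(m1 == 0, NaN, Inf), m1 / m2)
  data.frame(compound = rownames(metab),
             mean_group1 = m1, mean_group2 = m2, fold = fold,
             fold_rounded = ifelse(is.finite(fold), .roundHalfAway(fold), NA),
             differential = is.finite(fold) &
               (fold > differentialRatio | fold < 1 / differentialRatio) |
               is.infinite(fold),
             row.names = NULL, stringsAsFactors = FALSE)
}
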