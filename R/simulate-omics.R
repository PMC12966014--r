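## Simulated expression / metabolite / sequence panels with ground truth.

#' Default sample design for simulated omics panels
#'
#' @param tissues tissues profiled.
#' @param replicates biological replicates per tissue.
#' @param genotype genotype label attached to every sample.
#' @return data.frame with columns \code{sample_id}, \code{genotype},
#'   \code{tissue}, \code{replicate}.
#' @export
sampleDesign <- function(tissues = c("root", "leaf", "silique"),
                         replicates = 3, genotype = "sim") {
  df <- expand.grid(replicate = seq_len(replicates), tissue = tissues,
                    stringsAsFactors = FALSE)
  data.frame(sample_id = paste(genotype, df$tissue, df$replicate, sep = "_"),
             genotype = genotype, tissue = df$tissue,
             replicate = df$replicate, stringsAsFactors = FALSE)
}

#' Simulate a metabolite content table
#'
#' Generates a compound-by-sample table (mg/kg) containing the quercetin
#' aglycone and its glucosides plus unrelated decoy compounds. Glucoside
#' contents vary log-normally across samples around compound-specific
#' means, which gives the across-sample variation the correlation screen
#' needs.
#'
#' @param design sample design (\code{\link{sampleDesign}}).
#' @param glucosides named numeric of mean contents for the target
#'   compounds.
#' @param nDecoys number of unrelated compounds.
#' @param sdlog log-sd of across-sample variation.
#' @param seed integer seed.
#' @return numeric matrix compounds x samples with a \code{class}
#'   attribute-free plain layout; row names are compound names.
#' @export
simulateMetabolites <- function(design,
                                glucosides = c(Q3G = 450, Q7G = 175,
                                               `Q3,7G` = 125, quercetin = 2.8),
                                nDecoys = 20, sdlog = 0.6, seed = 1) {
  set.seed(seed)
  compounds <- c(names(glucosides), sprintf("decoy%02d", seq_len(nDecoys)))
  means <- c(glucosides, rlnorm(nDecoys, log(20), 1))
  n <- nrow(design)
  ## shared sample-level factor for the glucosides (they co-vary: one
  ## biosynthetic pathway), independent noise for decoys
  shared <- rlnorm(n, 0, sdlog)
  m <- matrix(0, length(compounds), n,
              dimnames = list(compounds, design$sample_id))
  for (i in seq_along(compounds)) {
    if (i <= length(glucosides)) {
      m[i, ] <- means[i] * shared * rlnorm(n, 0, 0.15)
    } else {
      m[i, ] <- means[i] * rlnorm(n, 0, sdlog)
    }
  }
  m
}

#' Simulate a TPM expression matrix
#'
#' Per gene family a log-normal baseline and tissue effect are drawn; for
#' duplicated genomes each homoeolog pair additionally draws a log2
#' expression ratio from \code{N(biasMean, biasSd)} (the subgenome
#' expression-bias model: mean 0 means no subgenome dominance). Planted
#' genes override this with an affine function of a metabolite total plus
#' Gaussian noise, which is the ground truth the correlation screen must
#' recover.
#'
#' @param genome \code{GenomeAnnotation}; if its scenario carried an
#'   \code{expressionBiasEvent}, those parameters are the defaults.
#' @param design sample design data.frame (\code{\link{sampleDesign}}).
#' @param biasMean,biasSd homoeolog log2-ratio distribution.
#' @param noiseSd log2-scale per-sample multiplicative noise sd.
#' @param planted data.frame with columns \code{gene_id}, \code{compound}
#'   (a metabolite name or \code{"+"}-joined sum such as
#'   \code{"Q3G+Q7G"}), \code{slope}, \code{intercept}, \code{noise_sd};
#'   requires \code{metabolites}.
#' @param metabolites compound-by-sample matrix aligned with
#'   \code{design}.
#' @param seed integer seed.
#' @return \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{"tpm"} and the design as column data.
#' @export
simulateExpression <- function(genome, design = sampleDesign(),
                               biasMean = NULL, biasSd = NULL,
                               noiseSd = 0.25, planted = NULL,
                               metabolites = NULL, seed = 1) {
  stopifnot(nrow(design) >= 2)
  md <- metadata(genes(genome))
  bias <- md$expression_bias
  if (is.null(biasMean)) biasMean <- if (is.null(bias)) 0 else bias$mean
  if (is.null(biasSd)) biasSd <- if (is.null(bias)) 0.5 else bias$sd
  set.seed(seed)
  gt <- geneTable(genome)
  n <- nrow(gt); ns <- nrow(design)
  base <- rlnorm(length(unique(gt$family)), log(20), 1)
  names(base) <- unique(gt$family)
  tisEff <- matrix(rlnorm(length(base) * length(unique(design$tissue)), 0, 0.4),
                   length(base),
                   dimnames = list(names(base), unique(design$tissue)))
  eps <- rnorm(length(base), biasMean, biasSd)   # log2 A/B ratio per family
  names(eps) <- names(base)
  half <- ifelse(is.na(gt$subgenome), 0,
                 ifelse(gt$subgenome == "A", +0.5, -0.5))
  mu <- base[gt$family] * 2^(half * eps[gt$family])
  tpm <- matrix(0, n, ns, dimnames = list(gt$gene_id, design$sample_id))
  for (j in seq_len(ns))
    tpm[, j] <- mu * tisEff[gt$family, design$tissue[j]] *
      2^rnorm(n, 0, noiseSd)
  if (!is.null(planted) && nrow(planted)) {
    if (is.null(metabolites))
      stop("planted genes need a metabolite table")
    miss <- setdiff(planted$gene_id, gt$gene_id)
    if (length(miss))
      stop("planted gene not in genome: ", paste(miss, collapse = ", "))
    for (k in seq_len(nrow(planted))) {
      comp <- strsplit(planted$compound[k], "+", fixed = TRUE)[[1]]
      bad <- setdiff(comp, rownames(metabolites))
      if (length(bad)) stop("unknown metabolite: ", paste(bad, collapse = ", "))
      target <- colSums(metabolites[comp, design$sample_id, drop = FALSE])
      ic <- if ("intercept" %in% names(planted)) planted$intercept[k] else 0
      val <- ic + planted$slope[k] * target +
        rnorm(ns, 0, planted$noise_sd[k])
      tpm[planted$gene_id[k], ] <- pmax(val, 0)
    }
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = tpm),
    colData = S4Vectors::DataFrame(design, row.names = design$sample_id))
}

## ---- codon divergence ----------------------------------------------------

## codon prefixes whose third position is fully fourfold-degenerate and
## whose first/second positions admit no synonymous single change
.FOURFOLD <- c("GC", "GG", "GT", "TC", "CC", "AC")
.STOPS <- c("TAA", "TAG", "TGA")

#' Simulate paralog codon alignments with known synonymous divergence
#'
#' Each pair starts from one random coding sequence built from codons with
#' fourfold-degenerate third positions; the two copies then diverge under
#' a Jukes-Cantor process applied to third (synonymous) positions at total
#' branch length \code{trueKs} and to first/second (nonsynonymous)
#' positions at \code{trueKa}. Mutations creating an in-frame stop codon
#' are redrawn. The expected Jukes-Cantor-corrected synonymous distance
#' equals \code{trueKs}, which is the ground truth for estimator-recovery
#' tests.
#'
#' @param nPairs number of paralog pairs.
#' @param codons codons per sequence.
#' @param trueKs true synonymous divergence (substitutions per synonymous
#'   site, both branches combined).
#' @param trueKa true nonsynonymous divergence (default a fifth of
#'   \code{trueKs}, i.e. purifying selection).
#' @param seed integer seed.
#' @return list with \code{a}, \code{b} (character vectors of aligned
#'   sequences), \code{pair_id}, and \code{true_ks}.
#' @export
simulateCodonDivergence <- function(nPairs, codons, trueKs,
                                    trueKa = trueKs / 5, seed = 1) {
  stopifnot(nPairs >= 1, codons >= 1, trueKs >= 0, trueKa >= 0)
  pDiff <- function(t) 0.75 * (1 - exp(-4 / 3 * t))
  if (!is.finite(trueKs) || !is.finite(trueKa))
    stop("divergence implies per-site difference probability >= 3/4 (saturation)")
  ps <- pDiff(trueKs); pn <- pDiff(trueKa)
  set.seed(seed)
  nt <- c("A", "C", "G", "T")
  jcMutate <- function(col, p) {
    hit <- runif(length(col)) < p
    if (any(hit)) {
      cur <- match(col[hit], nt)
      off <- sample.int(3, sum(hit), replace = TRUE)
      col[hit] <- nt[((cur - 1L + off) %% 4L) + 1L]
    }
    col
  }
  a <- character(nPairs); b <- character(nPairs)
  for (p in seq_len(nPairs)) {
    pre <- sample(.FOURFOLD, codons, replace = TRUE)
    c1 <- substr(pre, 1, 1); c2 <- substr(pre, 2, 2)
    c3 <- sample(nt, codons, replace = TRUE)
    ## total divergence on one branch is equivalent under JC to splitting
    ## it over the two branches; copy b carries it all
    r1 <- jcMutate(c1, pn); r2 <- jcMutate(c2, pn); r3 <- jcMutate(c3, ps)
    cod <- paste0(r1, r2, r3)
    bad <- which(cod %in% .STOPS)
    while (length(bad)) {     # redraw mutations of codons that became stops
      r1[bad] <- jcMutate(c1[bad], pn)
      r2[bad] <- jcMutate(c2[bad], pn)
      r3[bad] <- jcMutate(c3[bad], ps)
      cod[bad] <- paste0(r1[bad], r2[bad], r3[bad])
      bad <- bad[cod[bad] %in% .STOPS]
    }
    a[p] <- paste0(paste0(c1, c2, c3), collapse = "")
    b[p] <- paste0(cod, collapse = "")
  }
  list(a = a, b = b, pair_id = sprintf("pair%05d", seq_len(nPairs)),
       true_ks = trueKs)
}

#' Simulate a protein set with planted PSPG motifs
#'
#' Random amino-acid sequences; \code{motifIds} additionally receive a
#' 44-residue window carrying the five conserved PSPG anchor residues
#' (W at motif position 1, Q at 4, H at 19, S at 24, E at 27) near the
#' C-terminus, mimicking family-1 glycosyltransferases.
#'
#' @param ids protein ids (one sequence each).
#' @param motifIds subset of \code{ids} to receive the motif.
#' @param length protein length in residues.
#' @param seed integer seed.
#' @return named character vector of protein sequences.
#' @export
simulateProteins <- function(ids, motifIds = character(), length = 450,
                             seed = 1) {
  set.seed(seed)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- vapply(ids, function(id)
    paste(sample(aas, length, replace = TRUE), collapse = ""), character(1))
  anchors <- c(`1` = "W", `4` = "Q", `19` = "H", `24` = "S", `27` = "E")
  for (id in motifIds) {
    s <- strsplit(seqs[[id]], "")[[1]]
    at <- length - 60L           # motif near the C-terminus
    for (k in seq_along(anchors))
      s[at + as.integer(names(anchors)[k]) - 1L] <- anchors[k]
    seqs[[id]] <- paste(s, collapse = "")
  }
  seqs
}
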