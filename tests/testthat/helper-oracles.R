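## Independent oracles and compact fixture builders shared by the tests.

## ---- fixture builders ----------------------------------------------------

## annotation from a compact layout: list(chrom = c(gene ids in order));
## uniform 10 kb spacing, 2 kb genes
makeAnnot <- function(genomeId, layout, spacing = 10000, geneLen = 2000,
                      families = NULL) {
  rows <- list()
  for (ch in names(layout)) {
    ids <- layout[[ch]]
    rows[[ch]] <- data.frame(
      gene_id = ids, chrom = ch,
      start = (seq_along(ids) - 1) * spacing + 1,
      end = (seq_along(ids) - 1) * spacing + geneLen,
      strand = "+",
      family = if (is.null(families)) ids else families[ids],
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  GenomeAnnotation(genomeId, df)
}

## one syntenic-pair row with explicit positions (for chaining tests)
pairRow <- function(geneA, geneB, rankA, rankB, startA, startB,
                    chromA = "c1", chromB = "k1", geneLen = 2000) {
  data.frame(gene_a = geneA, gene_b = geneB, similarity = 95,
             chrom_a = chromA, rank_a = rankA,
             start_a = startA, end_a = startA + geneLen - 1, strand_a = "+",
             chrom_b = chromB, rank_b = rankB,
             start_b = startB, end_b = startB + geneLen - 1, strand_b = "+",
             support = 5L, stringsAsFactors = FALSE)
}

## random syntenic-pair table on a single chromosome combination
randomPairTable <- function(n, maxRank = 200, spacing = NULL) {
  ra <- sort(sample.int(maxRank, n)) - 1L
  rb <- sample.int(maxRank, n) - 1L
  spA <- if (is.null(spacing)) sample(c(3000, 10000, 120000), 1) else spacing
  spB <- sample(c(3000, 10000, 120000), 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    pairRow(paste0("a", i), paste0("b", i), ra[i], rb[i],
            ra[i] * spA + 1, rb[i] * spB + 1)))
}

## ---- chaining oracle: transitive closure of the merge relation -----------

## boolean-matrix transitive closure over the consecutive-pair merge
## relation; returns a canonical partition (list of sorted gene_a sets)
oracleChainPartition <- function(pairs, maxGeneGap = 50, maxBpGap = 300000,
                                 bothGenomes = TRUE) {
  n <- nrow(pairs)
  rel <- diag(TRUE, n)
  grp <- paste(pairs$chrom_a, pairs$chrom_b)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2) next
    ## candidate edges: adjacency in the gene order of either genome
    orders <- list(idx[order(pairs$rank_a[idx], pairs$rank_b[idx])],
                   idx[order(pairs$rank_b[idx], pairs$rank_a[idx])])
    for (o in orders) for (k in seq_len(length(o) - 1)) {
      i <- o[k]; j <- o[k + 1]
      gapIn <- function(side) {
        r <- paste0("rank_", side); s <- paste0("start_", side)
        e <- paste0("end_", side)
        genes <- abs(pairs[[r]][j] - pairs[[r]][i]) - 1
        bp <- max(0, max(pairs[[s]][i], pairs[[s]][j]) -
                     min(pairs[[e]][i], pairs[[e]][j]) - 1)
        genes < maxGeneGap || bp <= maxBpGap
      }
      ok <- if (bothGenomes) gapIn("a") && gapIn("b") else gapIn("a")
      if (ok) { rel[i, j] <- TRUE; rel[j, i] <- TRUE }
    }
  }
  repeat {
    nxt <- (rel %*% rel) > 0
    if (identical(nxt, rel > 0)) break
    rel <- nxt
  }
  comp <- unique(apply(rel, 1, function(r) paste(sort(pairs$gene_a[r]),
                                                 collapse = ",")))
  unname(sort(comp))
}

canonicalPartition <- function(members, col = "gene_a") {
  unname(sort(vapply(split(members[[col]], members$fragment_id),
                     function(g) paste(sort(g), collapse = ","),
                     character(1))))
}

## ---- NG86 oracle: exhaustive pathway enumeration -------------------------

.GC <- Biostrings::GENETIC_CODE

## depth-first enumeration of stop-free mutational pathways between two
## codons; returns the equal-weight mean c(syn, nonsyn) step counts
oracleCodonDiffs <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  walk <- function(cur, skipStops) {
    d <- which(cur != b)
    if (!length(d)) return(list(c(0, 0)))
    out <- list()
    for (p in d) {
      nxt <- cur; nxt[p] <- b[p]
      if (skipStops && .GC[[paste(nxt, collapse = "")]] == "*") next
      step <- if (.GC[[paste(cur, collapse = "")]] ==
                  .GC[[paste(nxt, collapse = "")]]) c(1, 0) else c(0, 1)
      for (rest in walk(nxt, skipStops))
        out[[length(out) + 1L]] <- step + rest
    }
    out
  }
  paths <- walk(a, TRUE)
  if (!length(paths)) paths <- walk(a, FALSE)
  colMeans(do.call(rbind, paths))
}

## per-sequence synonymous site count straight from the genetic code
oracleSynSites <- function(seq) {
  nt <- c("A", "C", "G", "T")
  cods <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  sum(vapply(cods, function(cd) {
    ch <- strsplit(cd, "")[[1]]
    s <- 0
    for (pos in 1:3) for (n in setdiff(nt, ch[pos])) {
      alt <- ch; alt[pos] <- n
      if (.GC[[paste(alt, collapse = "")]] == .GC[[cd]]) s <- s + 1 / 3
    }
    s
  }, numeric(1)))
}

oracleNG86 <- function(seqA, seqB) {
  ca <- substring(seqA, seq(1, nchar(seqA), 3), seq(3, nchar(seqA), 3))
  cb <- substring(seqB, seq(1, nchar(seqB), 3), seq(3, nchar(seqB), 3))
  diffs <- colSums(do.call(rbind, lapply(seq_along(ca), function(i)
    oracleCodonDiffs(ca[i], cb[i]))))
  S <- (oracleSynSites(seqA) + oracleSynSites(seqB)) / 2
  list(S = S, N = 3 * length(ca) - S, Sd = diffs[1], Nd = diffs[2])
}

## random stop-free codon sequence
randomCodons <- function(n) {
  nt <- c("A", "C", "G", "T")
  cods <- character(n)
  for (i in seq_len(n)) {
    repeat {
      cd <- paste(sample(nt, 3, replace = TRUE), collapse = "")
      if (.GC[[cd]] != "*") { cods[i] <- cd; break }
    }
  }
  paste(cods, collapse = "")
}

## mutate a stop-free sequence keeping it stop-free
mutateCodons <- function(seq, p) {
  nt <- c("A", "C", "G", "T")
  cods <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  for (i in seq_along(cods)) {
    repeat {
      ch <- strsplit(cods[i], "")[[1]]
      for (pos in 1:3)
        if (runif(1) < p) ch[pos] <- sample(setdiff(nt, ch[pos]), 1)
      cd <- paste(ch, collapse = "")
      if (.GC[[cd]] != "*") { cods[i] <- cd; break }
    }
  }
  paste(cods, collapse = "")
}
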