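## Nei-Gojobori (1986) synonymous/nonsynonymous rate estimation and
## Ks-distribution peak detection.
##
## Site counting: for each codon position the synonymous fraction is the
## share of the three possible nucleotide changes that preserve the amino
## acid (changes to stop codons count as nonsynonymous); site counts are
## averaged over the two sequences. Differences: per codon pair all
## minimal mutational pathways are enumerated and weighted equally,
## pathways through stop codons excluded (when every pathway crosses a
## stop, all pathways are used). Multiple hits are corrected with
## Jukes-Cantor: K = -3/4 log(1 - 4/3 p).

.ngEnv <- new.env(parent = emptyenv())

.ngTables <- function() {
  if (!is.null(.ngEnv$syn)) return(invisible(.ngEnv))
  nt <- c("A", "C", "G", "T")
  ## index layout: first base slowest (matches .codonIndex)
  codons <- apply(expand.grid(p3 = nt, p2 = nt, p1 = nt)[, 3:1], 1, paste0,
                  collapse = "")
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[codons]
  syn <- numeric(64)
  for (i in seq_len(64)) {
    if (aa[i] == "*") { syn[i] <- NA; next }
    ch <- strsplit(codons[i], "")[[1]]
    s <- 0
    for (pos in 1:3) for (n in setdiff(nt, ch[pos])) {
      alt <- ch; alt[pos] <- n
      altc <- paste(alt, collapse = "")
      if (gc[[altc]] == aa[i]) s <- s + 1 / 3
    }
    syn[i] <- s
  }
  names(syn) <- codons
  sd <- matrix(0, 64, 64, dimnames = list(codons, codons))
  nd <- sd
  for (i in seq_len(64)) for (j in seq_len(64)) {
    if (i == j || aa[i] == "*" || aa[j] == "*") next
    d <- .pathwayDiffs(codons[i], codons[j], gc)
    sd[i, j] <- d[1]; nd[i, j] <- d[2]
  }
  .ngEnv$codons <- codons
  .ngEnv$syn <- syn
  .ngEnv$nonsyn <- ifelse(is.na(syn), NA, 3 - syn)
  .ngEnv$sd <- sd
  .ngEnv$nd <- nd
  invisible(.ngEnv)
}

## equal-weight average (syn, nonsyn) difference counts over minimal
## mutational pathways between two codons; stop-crossing pathways dropped
.pathwayDiffs <- function(c1, c2, gc) {
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  perms <- .permutations(pos)
  res <- matrix(NA_real_, length(perms), 2)
  for (k in seq_along(perms)) {
    cur <- a; s <- 0; n <- 0; valid <- TRUE
    for (p in perms[[k]]) {
      nxt <- cur; nxt[p] <- b[p]
      aa1 <- gc[[paste(cur, collapse = "")]]
      aa2 <- gc[[paste(nxt, collapse = "")]]
      if (aa2 == "*") { valid <- FALSE; break }
      if (aa1 == aa2) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (valid) res[k, ] <- c(s, n)
  }
  ok <- !is.na(res[, 1])
  if (!any(ok)) {      # every pathway crosses a stop: count steps to stops
    res <- matrix(NA_real_, length(perms), 2)
    for (k in seq_along(perms)) {
      cur <- a; s <- 0; n <- 0
      for (p in perms[[k]]) {
        nxt <- cur; nxt[p] <- b[p]
        aa1 <- gc[[paste(cur, collapse = "")]]
        aa2 <- gc[[paste(nxt, collapse = "")]]
        if (aa1 == aa2) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      res[k, ] <- c(s, n)
    }
    ok <- rep(TRUE, nrow(res))
  }
  colMeans(res[ok, , drop = FALSE])
}

.permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in .permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

.codonIndex <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  code <- match(v, c("A", "C", "G", "T"))
  n <- length(v) / 3
  i1 <- code[seq(1, by = 3, length.out = n)]
  i2 <- code[seq(2, by = 3, length.out = n)]
  i3 <- code[seq(3, by = 3, length.out = n)]
  (i1 - 1L) * 16L + (i2 - 1L) * 4L + i3
}

.jc <- function(p) {
  if (p >= 0.75) stop("proportion of differences >= 3/4: ",
                      "Jukes-Cantor correction saturated")
  -0.75 * log(1 - 4 / 3 * p)
}

#' Nei-Gojobori (1986) Ka/Ks for one aligned codon pair
#'
#' @param seqA,seqB aligned coding sequences (equal length, multiple of
#'   3, ACGT only; \code{-} gaps allowed, gapped codons are dropped
#'   pairwise; no in-frame stop codons).
#' @return one-row data.frame: \code{S}, \code{N} (synonymous /
#'   nonsynonymous sites), \code{Sd}, \code{Nd} (differences), \code{ps},
#'   \code{pn}, \code{Ks}, \code{Ka}.
#' @examples
#' ng86Pairwise("TTTGCT", "TTCGCT")  # one synonymous difference
#' @export
ng86Pairwise <- function(seqA, seqB) {
  .ngTables()
  seqA <- toupper(seqA); seqB <- toupper(seqB)
  if (nchar(seqA) != nchar(seqB)) stop("sequences differ in length")
  if (nchar(seqA) == 0 || nchar(seqA) %% 3 != 0)
    stop("alignment length must be a positive multiple of 3")
  if (grepl("[^ACGT-]", seqA) || grepl("[^ACGT-]", seqB))
    stop("only A, C, G, T (and - gaps) are accepted")
  ## drop codons with a gap in either sequence
  ca <- substring(seqA, seq(1, nchar(seqA), 3), seq(3, nchar(seqA), 3))
  cb <- substring(seqB, seq(1, nchar(seqB), 3), seq(3, nchar(seqB), 3))
  keep <- !grepl("-", ca) & !grepl("-", cb)
  if (!any(keep)) stop("no ungapped codon columns")
  ia <- .codonIndex(paste(ca[keep], collapse = ""))
  ib <- .codonIndex(paste(cb[keep], collapse = ""))
  if (any(.ngEnv$codons[ia] %in% .STOPS) || any(.ngEnv$codons[ib] %in% .STOPS))
    stop("in-frame stop codon in alignment")
  S <- (sum(.ngEnv$syn[ia]) + sum(.ngEnv$syn[ib])) / 2
  N <- (sum(.ngEnv$nonsyn[ia]) + sum(.ngEnv$nonsyn[ib])) / 2
  Sd <- sum(.ngEnv$sd[cbind(ia, ib)])
  Nd <- sum(.ngEnv$nd[cbind(ia, ib)])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  data.frame(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
             Ks = .jc(ps), Ka = .jc(pn))
}

#' Batch NG86 over many codon alignments
#'
#' Saturated pairs (proportion of synonymous differences >= 3/4) get
#' \code{NA} estimates instead of an error; a single warning reports how
#' many.
#'
#' @param seqsA,seqsB character vectors of aligned sequences (pairs taken
#'   elementwise).
#' @param ids pair identifiers.
#' @return data.frame, one row per pair, columns as
#'   \code{\link{ng86Pairwise}} plus \code{pair_id}.
#' @export
ng86Batch <- function(seqsA, seqsB, ids = NULL) {
  stopifnot(length(seqsA) == length(seqsB))
  if (is.null(ids)) ids <- sprintf("pair%05d", seq_along(seqsA))
  nsat <- 0L
  rows <- lapply(seq_along(seqsA), function(i) {
    r <- tryCatch(ng86Pairwise(seqsA[i], seqsB[i]), error = function(e) {
      if (grepl("saturated", conditionMessage(e))) {
        nsat <<- nsat + 1L
        data.frame(S = NA, N = NA, Sd = NA, Nd = NA, ps = NA, pn = NA,
                   Ks = NA_real_, Ka = NA_real_)
      } else stop(e)
    })
    r
  })
  out <- cbind(data.frame(pair_id = ids, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  if (nsat > 0) warning(nsat, " saturated pair(s) set to NA")
  out
}

#' Locate peaks in a Ks distribution
#'
#' Gaussian kernel density on a fixed grid; the main peak is the grid
#' argmax and secondary peaks are local maxima at least 0.1 Ks away from
#' any higher reported peak and at least 10\% of the maximal density.
#'
#' @param ks numeric vector of Ks estimates (NAs dropped).
#' @param from,to,by evaluation grid (default 0..3 step 0.005).
#' @param bandwidth \code{"silverman"} (the Silverman rule-of-thumb,
#'   \code{\link[stats]{bw.nrd0}}) or a fixed numeric bandwidth.
#' @param ksMaxFilter drop estimates above this before density estimation
#'   (removes saturated tails).
#' @param minPeakSep,minPeakFrac secondary-peak reporting thresholds.
#' @return list: \code{peak} (main peak location), \code{peaks}
#'   (data.frame \code{location}, \code{density}), \code{bandwidth},
#'   \code{n}, \code{density} (data.frame \code{ks}, \code{density}).
#' @export
ksDistributionPeak <- function(ks, from = 0, to = 3, by = 0.005,
                               bandwidth = "silverman", ksMaxFilter = 3.0,
                               minPeakSep = 0.1, minPeakFrac = 0.1) {
  x <- ks[is.finite(ks) & ks >= 0 & ks <= ksMaxFilter]
  if (length(x) < 10)
    stop("fewer than 10 finite Ks estimates after filtering")
  bw <- if (is.numeric(bandwidth)) bandwidth else bw.nrd0(x)
  ngrid <- round((to - from) / by) + 1L
  d <- density(x, bw = bw, from = from, to = to, n = ngrid)
  main <- which.max(d$y)
  locmax <- which(diff(sign(diff(d$y))) == -2) + 1L
  locmax <- union(main, locmax)
  locmax <- locmax[order(-d$y[locmax])]
  acc <- integer(0)
  for (i in locmax) {
    if (d$y[i] < minPeakFrac * d$y[main]) next
    if (length(acc) && min(abs(d$x[i] - d$x[acc])) < minPeakSep) next
    acc <- c(acc, i)
  }
  list(peak = d$x[main],
       peaks = data.frame(location = d$x[acc], density = d$y[acc]),
       bandwidth = bw, n = length(x),
       density = data.frame(ks = d$x, density = d$y))
}
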