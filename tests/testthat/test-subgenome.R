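## shared fixture: a small tetraploid plus its self-synteny pairs
makeTet <- function(genesPerBlock = 10, lossRate = 0, seed = 3) {
  anc <- buildAncestralKaryotype(genesPerBlock = genesPerBlock)
  tet <- applyScenario(anc, tetraploidScenario(lossRate = lossRate,
                                               seed = seed),
                       genomeId = "tet")
  selfPairs <- detectSyntenicPairs(tet, tet, makeHomologyTable(tet, tet))
  list(anc = anc, tet = tet, selfPairs = selfPairs)
}

test_that("homoeologous chromosome pairing matches the simulated truth", {
  fx <- makeTet()
  pairing <- pairHomoeologousChromosomes(fx$selfPairs, fx$tet)
  expect_equal(nrow(pairing), 7)
  ## truth: X_A pairs with X_B
  expect_true(all(sub("_A$", "", pairing$chrom1) ==
                  sub("_B$", "", pairing$chrom2) |
                  sub("_B$", "", pairing$chrom1) ==
                  sub("_A$", "", pairing$chrom2)))
  ## odd chromosome count is an error
  odd <- makeAnnot("odd", list(c1 = "g1", c2 = "g2", c3 = "g3"))
  expect_error(pairHomoeologousChromosomes(fx$selfPairs[0, ], odd),
               "odd chromosome count")
})

test_that("gene density rules the subgenome assignment", {
  fx <- makeTet()
  pairing <- pairHomoeologousChromosomes(fx$selfPairs, fx$tet)
  ## no loss: densities tie, resolved by name order with a warning
  expect_warning(assignSubgenomesByDensity(pairing[1, , drop = FALSE],
                                           fx$tet),
                 "equal gene density")
  part0 <- suppressWarnings(assignSubgenomesByDensity(pairing, fx$tet))
  expect_setequal(part0$subgenome[grepl("_A$", part0$chrom)], "DsA")
  ## planted extra loss on subgenome B pushes its chromosomes to DsB
  gt <- geneTable(fx$tet)
  set.seed(9)
  drop <- gt$gene_id[gt$subgenome == "B" & runif(nrow(gt)) < 0.25]
  thinned <- GenomeAnnotation("tet", gt[!gt$gene_id %in% drop, ],
                              seqlengths = chromosomeLengths(fx$tet))
  part <- assignSubgenomesByDensity(pairing, thinned)
  expect_setequal(part$subgenome[grepl("_B$", part$chrom)], "DsB")
  ## exactly one chromosome per subgenome per pair
  tab <- table(part$pair_id, part$subgenome)
  expect_true(all(tab == 1))
})

test_that("retention ratio counts syntenic survivors per window", {
  fx <- makeTet()
  pairs <- detectSyntenicPairs(fx$tet, fx$anc,
                               makeHomologyTable(fx$tet, fx$anc))
  ## no gene loss: every window and the global ratio are 1
  r <- retentionRatio(fx$anc, pairs, window = 10, step = 5)
  expect_equal(r$global, 1.0)
  expect_true(all(r$windows$fraction == 1.0))
  ## 95 of 100 ancestral genes retained -> 0.95, by construction
  anc100 <- makeAnnot("anc", list(k1 = sprintf("ANC_%03d", 1:100)))
  kept <- sprintf("ANC_%03d", 6:100)
  toy <- do.call(rbind, lapply(seq_along(kept), function(i)
    pairRow(paste0("d", i), kept[i], i - 1, i - 1, i, i)))
  expect_equal(retentionRatio(anc100, toy, window = 100)$global, 0.95)
})

test_that("dominance counting applies strict fold thresholds", {
  ## two homoeolog pairs on a 2-chromosome toy tetraploid
  ann <- makeAnnot("t", list(c1_A = c("x_A", "y_A"), c1_B = c("x_B", "y_B")))
  part <- data.frame(chrom = c("c1_A", "c1_B"),
                     subgenome = c("DsA", "DsB"), density = 1, pair_id = 1)
  pairs <- data.frame(gene_a = c("x_A", "y_A"), gene_b = c("x_B", "y_B"))
  tpm <- matrix(c(10, 10, 30, 10), 4, 1,
                dimnames = list(c("x_A", "x_B", "y_A", "y_B"), "s1"))
  tpm <- cbind(tpm, tpm)  # two identical samples
  colnames(tpm) <- c("s1", "s2")
  dom <- expressionDominance(ann, pairs, part, tpm)
  ## (10,10): fold exactly 1, counted nowhere; (30,10): 30.1/10.1 = 2.98
  expect_equal(dom$n_a_dominant[dom$threshold == 1], 1L)
  expect_equal(dom$n_a_dominant[dom$threshold == 2], 1L)
  expect_equal(dom$n_a_dominant[dom$threshold == 3], 0L)
  expect_true(all(dom$n_b_dominant == 0))
  ## monotone non-increasing in the threshold
  expect_true(all(diff(dom$n_a_dominant) <= 0))
  ## swapping subgenome labels swaps the counts exactly
  partSw <- transform(part, subgenome = c("DsB", "DsA"))
  domSw <- expressionDominance(ann, pairs, partSw, tpm)
  expect_equal(domSw$n_b_dominant, dom$n_a_dominant)
  expect_equal(domSw$n_a_dominant, dom$n_b_dominant)
})

test_that("a planted subgenome bias is detected as dominance", {
  anc <- buildAncestralKaryotype(genesPerBlock = 10)
  wins <- 0
  for (s in 1:5) {
    tet <- applyScenario(anc, tetraploidScenario(biasMean = 1, biasSd = 0.5,
                                                 seed = s),
                         genomeId = "tet")
    selfPairs <- detectSyntenicPairs(tet, tet, makeHomologyTable(tet, tet))
    pairing <- pairHomoeologousChromosomes(selfPairs, tet)
    part <- suppressWarnings(assignSubgenomesByDensity(pairing, tet))
    se <- simulateExpression(tet, seed = s + 100)
    dom <- expressionDominance(tet, selfPairs[, c("gene_a", "gene_b")],
                               part, se)
    ## truth: subgenome A carries the planted +1 log2 bias; map its count
    aChr <- part$subgenome[match(paste0("ACK1_A"), part$chrom)]
    biased <- if (aChr == "DsA") dom$n_a_dominant else dom$n_b_dominant
    other <- if (aChr == "DsA") dom$n_b_dominant else dom$n_a_dominant
    if (biased[2] > other[2]) wins <- wins + 1
  }
  expect_gte(wins, 4)   # f = 2 separates a log2 = 1 bias nearly always
})
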