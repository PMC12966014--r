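test_that("ancestral karyotype has the expected block structure", {
  anc <- buildAncestralKaryotype(nBlocks = 22, genesPerBlock = 50,
                                 spacingBp = 10000)
  expect_equal(length(anc), 22 * 50)
  expect_equal(length(chromosomes(anc)), 8)
  gt <- geneTable(anc)
  expect_false(anyNA(gt$gb_label))
  expect_equal(length(unique(gt$gb_label)), 22)
  ## blocks are contiguous and non-overlapping in gene order
  for (ch in unique(gt$chrom)) {
    lab <- gt$gb_label[gt$chrom == ch][order(gt$rank[gt$chrom == ch])]
    expect_equal(length(rle(lab)$values), length(unique(lab)))
  }
  expect_error(buildAncestralKaryotype(nBlocks = 27), "label space")
})

test_that("degenerate single-block karyotype collapses empty chromosomes", {
  anc <- buildAncestralKaryotype(nBlocks = 1, genesPerBlock = 10,
                                 spacingBp = 1000, geneLengthBp = 500)
  expect_equal(length(anc), 10)
  expect_equal(length(chromosomes(anc)), 1)
})

test_that("fusion, duplication and loss reshape the karyotype as specified", {
  anc <- buildAncestralKaryotype(genesPerBlock = 10)
  dip <- applyScenario(anc, EvolutionScenario(
    list(fusionEvent("ACK6", "ACK8")), seed = 1), genomeId = "dip")
  expect_equal(length(chromosomes(dip)), 7)
  expect_equal(length(dip), length(anc))   # conservation without loss

  tet <- applyScenario(anc, EvolutionScenario(
    list(fusionEvent("ACK6", "ACK8"), wgdEvent()), seed = 1),
    genomeId = "tet")
  expect_equal(length(chromosomes(tet)), 14)
  expect_equal(length(tet), 2 * length(anc))
  gt <- geneTable(tet)
  expect_setequal(unique(gt$subgenome), c("A", "B"))
  ## family shared between homoeologs, block label inherited unchanged
  byFam <- split(gt$gb_label, gt$family)
  expect_true(all(vapply(byFam, function(x) length(unique(x)) == 1,
                         logical(1))))
  expect_error(
    applyScenario(anc, EvolutionScenario(list(fusionEvent("ACK1", "nope")),
                                         seed = 1)),
    "unknown chromosome")
})

test_that("gene loss retains a binomial share of genes", {
  anc <- buildAncestralKaryotype(genesPerBlock = 91)  # 2002 genes
  n <- length(anc)
  lost <- applyScenario(anc, EvolutionScenario(
    list(geneLossEvent(0.05)), seed = 42), genomeId = "lossy")
  bounds <- qbinom(c(0.005, 0.995), n, 0.95)
  expect_gte(length(lost), bounds[1])
  expect_lte(length(lost), bounds[2])
})

test_that("identical scenario and seed reproduce identical genomes", {
  anc <- buildAncestralKaryotype(genesPerBlock = 10)
  sc <- tetraploidScenario(lossRate = 0.1, seed = 7)
  g1 <- applyScenario(anc, sc, genomeId = "x")
  g2 <- applyScenario(anc, sc, genomeId = "x")
  expect_identical(geneTable(g1), geneTable(g2))
})

test_that("unbiased homoeolog expression is centred and planted genes are exact", {
  anc <- buildAncestralKaryotype(genesPerBlock = 46)  # 1012 families
  tet <- applyScenario(anc, tetraploidScenario(seed = 2), genomeId = "tet")
  design <- sampleDesign()
  se <- simulateExpression(tet, design, biasMean = 0, biasSd = 0.5, seed = 11)
  tpm <- SummarizedExperiment::assay(se, "tpm")
  hp <- homoeologPairs(tet)
  lr <- log2(rowMeans(tpm[hp$gene_a, ]) / rowMeans(tpm[hp$gene_b, ]))
  expect_lt(abs(mean(lr)), 0.1)     # CLT bound at ~1000 pairs

  metab <- simulateMetabolites(design, seed = 5)
  planted <- data.frame(gene_id = geneTable(tet)$gene_id[1],
                        compound = "Q3G+Q7G", slope = 0.02, intercept = 1,
                        noise_sd = 0)
  se2 <- simulateExpression(tet, design, planted = planted,
                            metabolites = metab, seed = 11)
  total <- colSums(metab[c("Q3G", "Q7G"), ])
  x <- SummarizedExperiment::assay(se2, "tpm")[planted$gene_id, ]
  expect_equal(unname(cor(x, total)), 1)   # noise-free affine plant
  expect_error(
    simulateExpression(tet, design,
                       planted = transform(planted, gene_id = "absent"),
                       metabolites = metab),
    "not in genome")
})

test_that("codon divergence simulator honours its contracts", {
  sim0 <- simulateCodonDivergence(10, 100, 0, seed = 3)
  est0 <- ng86Batch(sim0$a, sim0$b)
  expect_true(all(est0$Ks == 0))
  sim <- simulateCodonDivergence(50, 200, 0.3, seed = 4)
  inFrameStops <- function(s) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    any(cods %in% c("TAA", "TAG", "TGA"))
  }
  expect_false(any(vapply(c(sim$a, sim$b), inFrameStops, logical(1))))
  expect_error(simulateCodonDivergence(5, 50, Inf), "saturation")
})
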