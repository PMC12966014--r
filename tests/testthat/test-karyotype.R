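## small helper: fragments object from an ancestor/descendant pair built
## by simulation, so projections can be tested against ground truth
simFragments <- function(desc, anc, ...) {
  hom <- makeHomologyTable(desc, anc)
  p <- detectSyntenicPairs(desc, anc, hom, ...)
  chainFragments(p)
}

test_that("block projection applies run and threshold rules", {
  ## one fragment: 7 genes labelled F then 3 labelled G
  anc <- makeAnnot("anc", list(k1 = paste0("ANC_", 1:10)))
  gbT <- data.frame(block = rep(c("F", "G"), c(7, 3)), chromosome = "k1",
                    gene_id = paste0("ANC_", 1:10),
                    block_order = rep(c(1, 2), c(7, 3)))
  p <- do.call(rbind, lapply(1:10, function(i)
    pairRow(paste0("d", i), paste0("ANC_", i), i - 1, i - 1,
            (i - 1) * 10000 + 1, (i - 1) * 10000 + 1)))
  fr <- chainFragments(p)
  pr <- projectGenomicBlocks(fr, gbT, minGenesPerCall = 5)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$block, "F")
  expect_equal(pr$n_genes, 7L)
  expect_equal(pr$purity, 0.7)
  ## all 10 labelled F: one pure projection
  gbF <- transform(gbT, block = "F", block_order = 1)
  prF <- projectGenomicBlocks(fr, gbF, minGenesPerCall = 5)
  expect_equal(prF$purity, 1.0)
  expect_equal(prF$n_genes, 10L)
  ## below threshold: nothing
  expect_equal(nrow(projectGenomicBlocks(
    chainFragments(p[1:3, ]), gbT, minGenesPerCall = 5)), 0)
})

test_that("copy numbers are 1 in the diploid and 2 in the tetraploid", {
  anc <- buildAncestralKaryotype(genesPerBlock = 10)
  gbT <- gbDefinitionTable(anc)
  dip <- applyScenario(anc, diploidScenario(seed = 3), genomeId = "dip")
  tet <- applyScenario(anc, tetraploidScenario(seed = 3), genomeId = "tet")
  cnD <- gbCopyNumber(projectGenomicBlocks(simFragments(dip, anc), gbT), gbT)
  cnT <- gbCopyNumber(projectGenomicBlocks(simFragments(tet, anc), gbT), gbT)
  expect_equal(nrow(cnD), 22)
  expect_true(all(cnD$copies == 1))
  expect_true(all(cnT$copies == 2))   # doubling after WGD
  ## empty projections report every label at 0
  empty <- detectSyntenicPairs(dip, anc, makeHomologyTable(dip, anc)[0, ])
  cn0 <- gbCopyNumber(projectGenomicBlocks(chainFragments(empty), gbT), gbT)
  expect_true(all(cn0$copies == 0))
})

test_that("block associations are adjacent, unordered and deduplicated", {
  pr <- data.frame(block = c("F", "G", "H"), chrom = "c1",
                   rank_start = c(0, 10, 20), rank_end = c(9, 19, 29),
                   start = c(1, 1e5, 2e5), end = c(9e4, 1.9e5, 2.9e5),
                   n_genes = 10, purity = 1, copy_index = 1)
  a <- extractGBAssociations(pr)
  expect_equal(paste(a$block1, a$block2, sep = "-"), c("F-G", "G-H"))
  expect_equal(nrow(extractGBAssociations(pr[1, ])), 0)
  prFGF <- transform(pr, block = c("F", "G", "F"))
  expect_equal(nrow(extractGBAssociations(prFGF)), 1)
})

test_that("association recovery fraction is a plain intersection ratio", {
  anc <- data.frame(block1 = LETTERS[1:17], block2 = LETTERS[2:18])
  det <- anc[1:15, ]
  expect_equal(associationRecoveryFraction(det, anc), 15 / 17)
  expect_equal(round(100 * associationRecoveryFraction(det, anc), 2), 88.24)
  expect_equal(associationRecoveryFraction(anc, anc), 1.0)
  expect_equal(associationRecoveryFraction(
    data.frame(block1 = "Y", block2 = "Z"), anc), 0.0)
  expect_error(associationRecoveryFraction(det, anc[0, ]), "undefined")
  ## invariant under chromosome relabelling: associations carry no
  ## chromosome names, so recovery depends only on the label pairs
})

test_that("chromosome events recover the simulated scenario", {
  anc <- buildAncestralKaryotype(genesPerBlock = 10)
  gbT <- gbDefinitionTable(anc)
  ## no events: 8 intact inheritances
  sameG <- applyScenario(anc, EvolutionScenario(list(), seed = 1),
                         genomeId = "same")
  ev0 <- inferChromosomeEvents(
    projectGenomicBlocks(simFragments(sameG, anc), gbT), gbT)
  expect_equal(ev0$n_intact, 8)
  expect_equal(ev0$n_fusion, 0)
  expect_false(any(ev0$events$rearranged))
  ## fusion + inversion across block boundaries (ranks 10..39 span the
  ## Q and R blocks of the fused ACK6 arm)
  dip <- applyScenario(anc, diploidScenario(invSpan = c(10, 49), seed = 2),
                       genomeId = "dip")
  ev <- inferChromosomeEvents(
    projectGenomicBlocks(simFragments(dip, anc), gbT), gbT)
  expect_equal(ev$n_intact, 6)
  expect_equal(ev$n_fusion, 1)
  fus <- ev$events[ev$events$type == "fusion", ]
  expect_equal(fus$ancestors, "ACK6+ACK8")
  expect_true(fus$rearranged)
})
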