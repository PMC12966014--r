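test_that("perfect collinearity yields one syntenic pair per gene", {
  ids <- sprintf("g%02d", 1:10)
  a <- makeAnnot("A", list(c1 = paste0("A_", ids)),
                 families = setNames(ids, paste0("A_", ids)))
  b <- makeAnnot("B", list(k1 = paste0("B_", ids)),
                 families = setNames(ids, paste0("B_", ids)))
  hom <- makeHomologyTable(a, b)
  p <- detectSyntenicPairs(a, b, hom, flankWindow = 2, minSupport = 1)
  expect_equal(nrow(p), 10)
  expect_true(all(p$support >= 1))
})

test_that("a translocated gene loses flanking support and is excluded", {
  ids <- sprintf("g%02d", 1:10)
  a <- makeAnnot("A", list(c1 = paste0("A_", ids)),
                 families = setNames(ids, paste0("A_", ids)))
  ## g05 moved to its own chromosome in genome B
  b <- makeAnnot("B", list(k1 = paste0("B_", ids[-5]), k2 = "B_g05"),
                 families = setNames(c(ids[-5], ids[5]),
                                     paste0("B_", c(ids[-5], ids[5]))))
  hom <- makeHomologyTable(a, b)
  p <- detectSyntenicPairs(a, b, hom, flankWindow = 2, minSupport = 1)
  ## brute-force support count for the moved pair: no other homolog pair
  ## shares its (c1, k2) chromosome combination
  expect_equal(sum(p$gene_b == "B_g05"), 0)
  expect_equal(nrow(p), 9)
})

test_that("empty or context-free homology yields an empty result", {
  a <- makeAnnot("A", list(c1 = c("A_x", "A_y")))
  b <- makeAnnot("B", list(k1 = c("B_x", "B_y")))
  expect_equal(nrow(detectSyntenicPairs(a, b, data.frame(
    gene_a = character(), gene_b = character(), similarity = numeric()))), 0)
  ## two homolog pairs on different chromosome combinations support nothing
  b2 <- makeAnnot("B", list(k1 = "B_x", k2 = "B_y"),
                  families = c(B_x = "A_x", B_y = "A_y"))
  hom <- data.frame(gene_a = c("A_x", "A_y"), gene_b = c("B_x", "B_y"),
                    similarity = 95)
  expect_equal(nrow(detectSyntenicPairs(a, b2, hom, 2, 1)), 0)
})

test_that("chaining honours the gene-count and distance boundaries", {
  chainN <- function(p) nrow(fragments(chainFragments(p)))
  ## 49 intervening genes, 400 kb: merged by the (strict) gene rule
  p1 <- rbind(pairRow("a1", "b1", 0, 0, 1, 1),
              pairRow("a2", "b2", 50, 50, 402001, 402001))
  expect_equal(chainN(p1), 1)
  ## 60 intervening genes, 250 kb: merged by the (inclusive) distance rule
  p2 <- rbind(pairRow("a1", "b1", 0, 0, 1, 1),
              pairRow("a2", "b2", 61, 61, 252001, 252001))
  expect_equal(chainN(p2), 1)
  ## 50 genes and 301 kb: both criteria fail, two fragments
  p3 <- rbind(pairRow("a1", "b1", 0, 0, 1, 1),
              pairRow("a2", "b2", 51, 51, 303001, 303001))
  expect_equal(chainN(p3), 2)
  ## exactly 300 kb between nearest ends is still within distance
  p4 <- rbind(pairRow("a1", "b1", 0, 0, 1, 1),
              pairRow("a2", "b2", 51, 51, 302001, 302001))
  expect_equal(chainN(p4), 1)
})

test_that("the merge must hold in both genomes unless relaxed", {
  ## close in genome A, far in genome B
  p <- rbind(pairRow("a1", "b1", 0, 0, 1, 1),
             pairRow("a2", "b2", 1, 80, 10001, 900001))
  expect_equal(nrow(fragments(chainFragments(p, maxGeneGap = 50,
                                             maxBpGap = 300000))), 2)
  expect_equal(nrow(fragments(chainFragments(p, maxGeneGap = 50,
                                             maxBpGap = 300000,
                                             bothGenomes = FALSE))), 1)
})

test_that("chaining agrees with the transitive-closure oracle and is a partition", {
  set.seed(401)
  for (rep in 1:8) {
    p <- randomPairTable(n = sample(10:40, 1), maxRank = 200)
    fr <- chainFragments(p)
    m <- members(fr)
    expect_setequal(m$gene_a, p$gene_a)              # partition: all pairs
    expect_equal(anyDuplicated(m$gene_a), 0)          # ... exactly once
    expect_equal(canonicalPartition(m), oracleChainPartition(p))
  }
})

test_that("chaining is symmetric and monotone in its gap parameters", {
  set.seed(402)
  for (rep in 1:5) {
    p <- randomPairTable(n = 25, maxRank = 120)
    fr <- chainFragments(p)
    sw <- chainFragments(swapPairGenomes(p))
    ## mirrored intervals, identical membership
    expect_equal(canonicalPartition(members(fr)),
                 canonicalPartition(members(sw), col = "gene_b"))
    f0 <- nrow(fragments(fr))
    expect_lte(nrow(fragments(chainFragments(p, maxGeneGap = 80))), f0)
    expect_lte(nrow(fragments(chainFragments(p, maxBpGap = 1e6))), f0)
  }
})

test_that("fragment orientation reflects rank direction agreement", {
  fwd <- do.call(rbind, lapply(0:9, function(i)
    pairRow(paste0("a", i), paste0("b", i), i, i, i * 10000 + 1,
            i * 10000 + 1)))
  expect_equal(fragments(chainFragments(fwd))$orientation, "same")
  rev <- do.call(rbind, lapply(0:9, function(i)
    pairRow(paste0("a", i), paste0("b", i), i, 9 - i, i * 10000 + 1,
            (9 - i) * 10000 + 1)))
  expect_equal(fragments(chainFragments(rev))$orientation, "inverted")
})
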