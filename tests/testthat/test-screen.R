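## a 300-aa protein with a perfect PSPG anchor window at position 101
makeMotifProtein <- function(mutate1 = NULL) {
  s <- rep("L", 300)
  anchors <- c(`1` = "W", `4` = "Q", `19` = "H", `24` = "S", `27` = "E")
  for (k in seq_along(anchors))
    s[100 + as.integer(names(anchors)[k])] <- anchors[k]
  if (!is.null(mutate1)) s[101] <- mutate1
  paste(s, collapse = "")
}

test_that("PSPG scan finds anchored windows and scores them", {
  prot <- c(ugt1 = makeMotifProtein())
  h <- scanPSPG(prot)
  expect_equal(nrow(h), 1)
  expect_equal(h$motif_start, 101L)
  expect_equal(h$anchor_score, 1.0)
  expect_equal(nchar(h$window), 44L)
  ## W -> A at the first anchor: score 0.8, reported only at min <= 4
  prot2 <- c(ugt2 = makeMotifProtein(mutate1 = "A"))
  h4 <- scanPSPG(prot2, minAnchorMatches = 4)
  expect_equal(h4$anchor_score, 0.8)
  expect_equal(nrow(scanPSPG(prot2, minAnchorMatches = 5)), 0)
  ## no anchors anywhere
  expect_equal(nrow(scanPSPG(c(p = paste(rep("A", 100), collapse = "")))), 0)
  ## too short to hold the motif
  expect_message(h0 <- scanPSPG(c(s = "WQHSE")), "shorter than 44")
  expect_equal(nrow(h0), 0)
})

test_that("correlation screen matches the exact t-transform", {
  samples <- paste0("s", 1:6)
  total <- setNames(c(10, 20, 30, 40, 50, 60), samples)
  expr <- rbind(prop = total * 0.3,            # r = +1
                anti = rev(unname(total)),     # r = -1
                noisy = c(12, 18, 33, 37, 55, 52),
                flat = rep(5, 6))
  colnames(expr) <- samples
  res <- correlationScreen(expr, total, rMin = 0.75, pMax = 1e-05)
  expect_equal(res$r[res$gene_id == "prop"], 1)
  expect_true(res$pass[res$gene_id == "prop"])
  expect_equal(res$r[res$gene_id == "anti"], -1)
  expect_false(res$pass[res$gene_id == "anti"])  # positive screen only
  expect_true(is.na(res$r[res$gene_id == "flat"]))
  expect_false(res$pass[res$gene_id == "flat"])
  ## oracle: cor.test probability, and smallish n fails P < 1e-05 even
  ## at strong r (here r ~ 0.98 at n = 6)
  ct <- cor.test(expr["noisy", ], total)
  noisy <- res[res$gene_id == "noisy", ]
  expect_equal(noisy$r, unname(ct$estimate))
  expect_equal(noisy$p_value, ct$p.value)
  ## an r = 0.9 at n = 6 has p around 0.015: passes r but not p
  r <- 0.9; t <- r * sqrt(4 / (1 - r^2)); p <- 2 * pt(-t, 4)
  expect_equal(round(p, 4), 0.0145)
  expect_gt(p, 1e-05)
  expect_error(correlationScreen(expr, total[1:5]), "do not match")
})

test_that("the planted correlated genes are exactly the screen hits", {
  set.seed(31)
  n <- 30   # enough samples that a null |r| > 0.75 is essentially impossible
  samples <- paste0("s", seq_len(n))
  total <- setNames(rlnorm(n, log(400), 0.5), samples)
  decoys <- matrix(rlnorm(200 * n, log(20), 1), 200,
                   dimnames = list(sprintf("decoy%03d", 1:200), samples))
  planted <- t(vapply(1:3, function(i) 2 + 0.05 * i * total, total))
  rownames(planted) <- paste0("ugt", 1:3)
  expr <- rbind(planted, decoys)
  res <- correlationScreen(expr, total, rMin = 0.75, pMax = 0.05)
  expect_setequal(res$gene_id[res$pass], rownames(planted))
})

test_that("metabolite folds reproduce ratio arithmetic and the one-fourth rule", {
  m <- matrix(c(454.84, 6.88,
                176.02, 2.91,
                125.96, 0.71,
                2.83, 1.48,
                5, 5,
                3, 0), 6, 2, byrow = TRUE,
              dimnames = list(c("Q3G", "Q7G", "Q3,7G", "quercetin",
                                "flat", "zeroed"), c("tetra", "dip")))
  f <- metaboliteFolds(m, "tetra", "dip")
  expect_equal(f$fold_rounded[f$compound == "Q3G"], 66)
  expect_equal(f$fold_rounded[f$compound == "Q7G"], 60)
  expect_equal(f$fold[f$compound == "flat"], 1)
  expect_false(f$differential[f$compound == "flat"])
  expect_false(f$differential[f$compound == "quercetin"])
  expect_true(all(f$differential[1:3]))
  expect_true(is.infinite(f$fold[f$compound == "zeroed"]))
  expect_true(f$differential[f$compound == "zeroed"])
  ## reciprocal folds multiply to one
  g <- metaboliteFolds(m[1:5, ], "dip", "tetra")
  expect_equal(f$fold[1:5] * g$fold, rep(1, 5), tolerance = 1e-12)
  ## rounding is half-away-from-zero, not banker's
  m2 <- matrix(c(3.5, 1), 1, 2, dimnames = list("x", c("a", "b")))
  expect_equal(metaboliteFolds(m2, "a", "b")$fold_rounded, 4)
})
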