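test_that("permuting an unused feature leaves the loss ratio at exactly 1", {
  tm <- tinyTrainedModel()
  fit <- tm$fit
  f <- 5L
  fit@params$layers[[1L]]$W[f, ] <- 0     # feature f disconnected
  imp <- permutationImportance(fit, tm$X, tm$y, nRounds = 8L,
                               subsamplePerClass = 20L, nPerm = 2L,
                               seed = 4L, L = 4L)
  expect_true(all(perRound(imp)[, f] == 1))
  expect_equal(unname(pValues(imp)[f]), 1)
})

test_that("a constant feature column has loss ratio exactly 1", {
  tm <- tinyTrainedModel()
  X <- tm$X
  X[, 7L] <- 2.5
  imp <- permutationImportance(tm$fit, X, tm$y, nRounds = 8L,
                               subsamplePerClass = 20L, nPerm = 2L,
                               seed = 4L, L = 4L)
  expect_true(all(perRound(imp)[, 7L] == 1))
})

test_that("the importance engine is deterministic and shape-correct", {
  tm <- tinyTrainedModel()
  imp1 <- permutationImportance(tm$fit, tm$X, tm$y, nRounds = 6L,
                                subsamplePerClass = 15L, nPerm = 3L,
                                seed = 11L, L = 4L)
  imp2 <- permutationImportance(tm$fit, tm$X, tm$y, nRounds = 6L,
                                subsamplePerClass = 15L, nPerm = 3L,
                                seed = 11L, L = 4L)
  expect_identical(perRound(imp1), perRound(imp2))
  expect_identical(dim(perRound(imp1)), c(6L, 24L))
  expect_identical(featureIdsOf(imp1)[1:2], c("pos1_pc1", "pos2_pc1"))
  expect_true(all(perRound(imp1) > 0))
  expect_true(all(fdrValues(imp1) >= pValues(imp1) - 1e-12))
})

test_that("p-values are the exact fraction of rounds at or below 1", {
  expect_equal(pvaluesFromRounds(c(1.2, 1.3, 0.9, 1.1)), 0.25)
  expect_equal(pvaluesFromRounds(c(1.01, 1.5, 2)), 0)
  expect_equal(pvaluesFromRounds(c(1, 0.5, 0.99)), 1)  # ratio == 1 counts
  ## matrix input: per-column fractions
  m <- cbind(a = c(1.2, 0.8), b = c(2, 3))
  expect_equal(pvaluesFromRounds(m), c(a = 0.5, b = 0))
})

test_that("p-values ignore the scale of super-unity ratios", {
  ## multiplying all ratios by factors that keep them > 1 leaves p at 0
  r <- c(1.1, 1.4, 2.0, 1.01)
  expect_equal(pvaluesFromRounds(r), 0)
  expect_equal(pvaluesFromRounds(r * 7), 0)
})

test_that("BH adjustment matches the reference step-up implementation", {
  set.seed(30)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1L))
    fdr <- benjaminiHochberg(p)
    expect_equal(fdr, oracleBH(p), tolerance = 1e-12)
    expect_true(all(fdr >= p - 1e-12))
    expect_true(all(fdr <= 1))
  }
  ## equal p-values are unchanged
  expect_equal(benjaminiHochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.5)),
               oracleBH(c(0.01, 0.02, 0.03, 0.5)))
  expect_error(benjaminiHochberg(c(0.5, 1.2)), "0, 1")
})

test_that("back-calculation reproduces the loading-weighted equation", {
  L <- 4L
  ## all ratios 1 -> back-calculated importance 1 for any defined property
  ones <- matrix(1, nrow = 3L, ncol = L * 6L)
  loads <- matrix(rnorm(5 * 6), 5, 6,
                  dimnames = list(paste0("P", 1:5), paste0("PC", 1:6)))
  loads[1, ] <- c(1, 0, 0, 0, 0, 0)     # P1 loads on PC1 only
  back <- backCalculate(fakeImportance(ones, L), fakePCA(loads))
  expect_true(all(abs(meanRatio(back)[, back@defined[1, ]] - 1) < 1e-12))

  ## a (1,0,...,0) loading vector copies the PC1 ratio at each position
  set.seed(31)
  pr <- matrix(runif(3 * L * 6, 0.5, 2), nrow = 3L)
  imp <- fakeImportance(pr, L)
  back2 <- backCalculate(imp, fakePCA(loads))
  pc1 <- pr[, 1:L]                      # columns pos1..pos4 of PC1
  expect_equal(unname(perRound(back2)[, , "P1"]), unname(pc1))

  ## random fixture vs direct evaluation of the printed equation
  for (prop in rownames(loads)) {
    l <- loads[prop, ]
    if (abs(sum(l)) < 1e-8) next
    for (pos in seq_len(L)) {
      direct <- vapply(1:3, function(r) {
        ratios <- pr[r, (0:5) * L + pos]
        sum(ratios * l) / sum(l)
      }, numeric(1))
      expect_equal(unname(perRound(back2)[, pos, prop]), direct,
                   tolerance = 1e-12)
    }
  }
  ## round-count conservation
  expect_identical(dim(perRound(back2)), c(3L, 4L, 5L))
})

test_that("near-zero signed loading sums are flagged undefined", {
  loads <- rbind(ok = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
                 zero = c(0.5, -0.5, 0.3, -0.3, 0.2, -0.2))
  colnames(loads) <- paste0("PC", 1:6)
  pr <- matrix(runif(2 * 24, 0.5, 2), nrow = 2L)
  back <- backCalculate(fakeImportance(pr, 4L), fakePCA(loads))
  expect_true(all(back@defined[, "ok"]))
  expect_false(any(back@defined[, "zero"]))
  expect_true(all(is.na(fdrValues(back)[, "zero"])))
  ## absolute-loading variant defines it again
  backAbs <- backCalculate(fakeImportance(pr, 4L), fakePCA(loads),
                           absLoadings = TRUE)
  expect_true(all(backAbs@defined))
})

test_that("property ranking is by maximum importance with lexicographic ties", {
  loads <- matrix(0, 3, 6, dimnames = list(c("peaky", "flat", "apeer"),
                                           paste0("PC", 1:6)))
  loads["peaky", ] <- c(1, 0, 0, 0, 0, 0)
  loads["flat", ] <- c(0, 1, 0, 0, 0, 0)
  loads["apeer", ] <- c(0, 0, 1, 0, 0, 0)
  L <- 4L
  pr <- matrix(1, nrow = 2L, ncol = L * 6L)
  pr[, 1L] <- 3            # PC1 at pos1: single large value -> "peaky"
  pr[, L + seq_len(L)] <- 1.4   # PC2 everywhere moderate -> "flat"
  pr[, 2L * L + seq_len(L)] <- 1.4 # PC3 same as flat -> tie with "apeer"
  back <- backCalculate(fakeImportance(pr, L), fakePCA(loads))
  rk <- rankProperties(back, 3L)
  expect_identical(rk[1L], "peaky")
  ## tie between flat and apeer broken lexicographically
  expect_identical(rk[2:3], c("apeer", "flat"))
  ## topN beyond the property count returns the full ranking
  expect_length(rankProperties(back, 10L), 3L)
})

test_that("region summaries count significant features where they are", {
  map <- regionMap()
  expect_identical(length(map@regions), 147L)
  expect_identical(as.character(regionOf(map, c(1L, 30L, 70L, 120L, 147L))),
                   c("FR1", "CDR1", "FR3", "CDR3", "FR4"))

  ## no significant features -> all-zero counts
  pr <- matrix(1.5, nrow = 4L, ncol = 147L * 6L)
  impNull <- fakeImportance(pr, 147L)
  impNull@fdr <- rep(1, ncol(pr))
  tabNull <- summarizeByRegion(impNull, map)
  expect_true(all(tabNull$sig_fdr0.05 == 0))
  expect_true(all(tabNull$sig_fdr0.1 == 0))

  ## all significance inside CDR3 -> CDR3 carries the total
  impC <- impNull
  cdr3 <- which(as.character(regionOf(map, impC@positions)) == "CDR3")
  impC@fdr[] <- 1
  impC@fdr[cdr3] <- 0.01
  impC@pValue[] <- 1
  impC@pValue[cdr3] <- 0.001
  tabC <- summarizeByRegion(impC, map)
  expect_identical(tabC$sig_fdr0.05[tabC$region == "CDR3"], length(cdr3))
  expect_identical(sum(tabC$sig_fdr0.05), length(cdr3))
})

test_that("importance tables serialize with regions attached", {
  tm <- tinyTrainedModel()
  imp <- permutationImportance(tm$fit, tm$X, tm$y, nRounds = 4L,
                               subsamplePerClass = 10L, nPerm = 2L,
                               seed = 2L, L = 4L)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeImportanceTSV(imp, path, regionMap(4L, c(FR1 = 1L, CDR1 = 2L,
                                                FR2 = 2L, CDR2 = 2L,
                                                FR3 = 3L, CDR3 = 3L,
                                                FR4 = 4L)))
  df <- utils::read.delim(path)
  expect_identical(nrow(df), 24L)
  expect_true(all(c("feature_id", "mean_ratio", "p_value", "fdr", "region")
                  %in% names(df)))
})
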