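test_that("confusion counts follow the tie-positive threshold rule", {
  expect_identical(confusionAtThreshold(c(0.9, 0.4), c(1, 0)),
                   c(TP = 1L, FP = 0L, FN = 0L, TN = 1L))
  ## a probability equal to the threshold predicts positive
  expect_identical(confusionAtThreshold(0.5, 0),
                   c(TP = 0L, FP = 1L, FN = 0L, TN = 0L))
  expect_error(confusionAtThreshold(numeric(0), integer(0)), "empty")
})

test_that("confusion counts match a brute-force loop on random instances", {
  set.seed(20)
  for (i in 1:5) {
    p <- runif(200)
    y <- rbinom(200, 1, 0.3)
    th <- runif(1, 0.2, 0.8)
    cc <- confusionAtThreshold(p, y, th)
    ref <- c(TP = 0L, FP = 0L, FN = 0L, TN = 0L)
    for (j in seq_along(p)) {
      pred <- p[j] >= th
      ref <- ref + c(TP = pred && y[j] == 1, FP = pred && y[j] == 0,
                     FN = !pred && y[j] == 1, TN = !pred && y[j] == 0)
    }
    expect_identical(cc, ref)
  }
})

test_that("the metric panel matches direct formula evaluation", {
  ## TP=3, FP=1, FN=1, TN=5 realized as probabilities around 0.5
  p <- c(rep(0.9, 3), rep(0.1, 1), 0.9, rep(0.1, 5))
  y <- c(rep(1, 3), rep(1, 1), 0, rep(0, 5))
  m <- computeMetrics(p, y)
  expect_equal(m[["f1"]], 6 / 8)
  expect_equal(m[["mcc"]], (3 * 5 - 1 * 1) / sqrt(4 * 4 * 6 * 6))
  expect_equal(m[["sensitivity"]], 3 / 4)
  expect_equal(m[["specificity"]], 5 / 6)
  expect_equal(m[["balanced_accuracy"]], (3 / 4 + 5 / 6) / 2)
  ## perfect separation
  mp <- computeMetrics(c(0.9, 0.9, 0.1), c(1, 1, 0))
  expect_equal(unname(mp[c("auroc", "f1", "mcc", "sensitivity", "specificity")]),
               rep(1, 5))
  ## constant probabilities give AUROC 0.5 under midranks
  expect_equal(computeMetrics(rep(0.4, 10), rep(0:1, 5))[["auroc"]], 0.5)
})

test_that("single-class labels leave auroc and mcc undefined with a warning", {
  expect_warning(m <- computeMetrics(c(0.2, 0.8), c(1, 1)), "single-class")
  expect_true(is.na(m[["auroc"]]))
  expect_true(is.na(m[["mcc"]]))
  expect_false(is.na(m[["bce_loss"]]))
})

test_that("AUROC is invariant under strictly monotone transforms", {
  set.seed(21)
  p <- runif(150)
  y <- rbinom(150, 1, 0.4)
  a0 <- computeMetrics(p, y)[["auroc"]]
  for (f in list(function(x) x^3, function(x) plogis(5 * x - 2),
                 function(x) exp(x) / (1 + exp(1)))) {
    expect_equal(computeMetrics(f(p), y)[["auroc"]], a0, tolerance = 1e-12)
  }
})

test_that("AUROC agrees with the all-pairs oracle and with pROC", {
  skip_if_not_installed("pROC")
  set.seed(22)
  for (i in 1:10) {
    n <- sample(20:200, 1L)
    p <- round(runif(n), 2)           # force ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2L) next
    a <- computeMetrics(p, y)[["auroc"]]
    expect_equal(a, oracleAUROC(p, y), tolerance = 1e-12)
    expect_equal(a, as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                                   direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("binary cross-entropy is the clipped mean negative log-likelihood", {
  p <- c(0.8, 0.3)
  y <- c(1, 0)
  expect_equal(computeMetrics(p, y)[["bce_loss"]],
               -mean(log(c(0.8, 0.7))))
  ## extreme probabilities stay finite through clipping
  expect_true(is.finite(computeMetrics(c(1, 0), c(0, 1))[["bce_loss"]]))
})

test_that("the random-classifier F1 baseline behaves as designed", {
  expect_equal(baselineF1(0.5), 0.5)
  ## low-prevalence limit: baseline approaches 2 * prevalence
  expect_equal(baselineF1(1e-4) / (2 * 1e-4), 1, tolerance = 1e-3)
  ## at the printed repertoire class sizes (~0.134M positive vs ~15M
  ## negative) the baseline is ~0.017
  expect_lt(abs(baselineF1(0.134 / (15 + 0.134)) - 0.017), 0.002)
  expect_error(baselineF1(0), "strictly")
  expect_error(baselineF1(1), "strictly")
})

test_that("cross-validation reports one row per fold and honest summaries", {
  set.seed(23)
  cfg <- generatorConfig(clonesPerAnimal = 150L, imbalance = 8,
                         effectSize = 0.9, plantedProperty = "KYTJ820101",
                         seed = 41L)
  tab <- generateRepertoire(cfg, panelTable())
  dd <- dedupBySequence(markHoldout(tab)$modelling)
  splits <- makeRandomKFold(dd, k = 3L, seed = 1L)
  mcfg <- modelConfig(learningRate = 5e-3, epochs = 3L, seed = 6L)
  rep_ <- crossValidate(dd, splits, panelPCA(), mcfg)
  expect_s4_class(rep_, "CVReport")
  expect_identical(nrow(perFold(rep_)), 3L)
  s <- cvSummary(rep_)
  expect_setequal(s$metric, c("bce_loss", "auroc", "f1", "mcc", "sensitivity",
                              "specificity", "balanced_accuracy"))
  ## summary recomputes from the per-fold rows
  expect_equal(s$mean[s$metric == "auroc"],
               mean(perFold(rep_)$auroc, na.rm = TRUE))
  ## identical folds by construction give SD = 0 for every metric
  rep2 <- crossValidate(dd, splits[c(1L, 1L, 1L)], panelPCA(), mcfg)
  expect_true(all(cvSummary(rep2)$sd == 0, na.rm = TRUE))
})

test_that("blocked cross-validation yields one fold per antigen group", {
  set.seed(24)
  cfg <- generatorConfig(clonesPerAnimal = 120L, imbalance = 6,
                         effectSize = 0.8, plantedProperty = "KYTJ820101",
                         seed = 43L)
  tab <- generateRepertoire(cfg, panelTable())
  modelling <- markHoldout(tab)$modelling
  splits <- makeBlockedFolds(modelling, "antigen_group")
  mcfg <- modelConfig(learningRate = 5e-3, epochs = 2L, seed = 6L)
  rep_ <- crossValidate(modelling, splits, panelPCA(), mcfg)
  expect_identical(nrow(perFold(rep_)), 3L)
  expect_true(all(grepl("^antigen_group=", perFold(rep_)$fold)))
})

test_that("holdout evaluation reuses the metric panel unchanged", {
  set.seed(25)
  cfg <- generatorConfig(clonesPerAnimal = 150L, imbalance = 6,
                         effectSize = 0.9, plantedProperty = "KYTJ820101",
                         fracPreimmune = 0.15, seed = 44L)
  tab <- generateRepertoire(cfg, panelTable())
  parts <- markHoldout(tab)
  dd <- dedupBySequence(parts$modelling)
  X <- encodeBatch(sequences(dd), panelPCA())
  mcfg <- modelConfig(learningRate = 5e-3, epochs = 3L, seed = 2L)
  fit <- trainModel(buildModel(mcfg), X, cloneLabels(dd))
  panel <- evaluateHoldout(fit, parts$holdout, panelPCA())
  expect_named(panel, c("bce_loss", "auroc", "f1", "mcc", "sensitivity",
                        "specificity", "balanced_accuracy"))
  hh <- dedupBySequence(parts$holdout)
  Xh <- encodeBatch(sequences(hh), panelPCA())
  direct <- suppressWarnings(
    computeMetrics(predictProba(fit, encodeBatch(
      sequences(parts$holdout), panelPCA())), cloneLabels(parts$holdout)))
  expect_equal(panel, direct)
})

test_that("ROC point dumps are monotone staircases ending at (1, 1)", {
  set.seed(26)
  p <- runif(60)
  y <- rbinom(60, 1, 0.5)
  rc <- rocPoints(p, y)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
  expect_equal(unlist(rc[nrow(rc), ]), c(fpr = 1, tpr = 1))
})
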