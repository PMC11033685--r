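# Fixtures are built in code: a tiny hand-transcribed AAindex text, a flat
# writer to round-trip real tables through the parser, and random clone
# tables for partition property tests.

# Two complete entries (Kyte-Doolittle hydropathy, Klein net charge) in
# AAindex1 flat format, values transcribed by hand.
tinyAAindexText <- function() {
  paste(
    "H KYTJ820101",
    "D Hydropathy index (Kyte-Doolittle, 1982)",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "    1.8    -4.5    -3.5    -3.5     2.5    -3.5    -3.5    -0.4    -3.2     4.5",
    "    3.8    -3.9     1.9     2.8    -1.6    -0.8    -0.7    -0.9    -1.3     4.2",
    "//",
    "H KLEP840101",
    "D Net charge (Klein et al., 1984)",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "     0.      1.      0.     -1.      0.      0.     -1.      0.      0.      0.",
    "     0.      1.      0.      0.      0.      0.      0.      0.      0.      0.",
    "//",
    sep = "\n")
}

# Hand-transcribed expected values of the two entries above, in canonical
# amino-acid row order (A R N D C Q E G H I L K M F P S T W Y V).
tinyAAindexValues <- function() {
  out <- cbind(
    KYTJ820101 = c(1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4, -3.2, 4.5,
                   3.8, -3.9, 1.9, 2.8, -1.6, -0.8, -0.7, -0.9, -1.3, 4.2),
    KLEP840101 = c(0, 1, 0, -1, 0, 0, -1, 0, 0, 0,
                   0, 1, 0, 0, 0, 0, 0, 0, 0, 0))
  rownames(out) <- c("A","R","N","D","C","Q","E","G","H","I",
                     "L","K","M","F","P","S","T","W","Y","V")
  out
}

# Serialize an AAPropertyMatrix back to AAindex1 flat format (independent
# of parseAAindex; used to round-trip real tables through the parser).
writeAAindexFlat <- function(M, path) {
  V <- propertyValues(M)
  con <- file(path, "wb")
  on.exit(close(con))
  for (id in colnames(V)) {
    v <- V[, id]
    writeLines(c(
      paste("H", id),
      "D synthetic round-trip fixture",
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      paste0("   ", paste(formatC(v[1:10], format = "g", digits = 10),
                          collapse = "  ")),
      paste0("   ", paste(formatC(v[11:20], format = "g", digits = 10),
                          collapse = "  ")),
      "//"), con, sep = "\n")
  }
  path
}

panelTable <- function() {
  parseAAindex(system.file("extdata", "aaindex_panel.txt", package = "polyspec"))
}

panelPCA <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fitPropertyPCA(panelTable())
    cache
  }
})

# Random aligned sequences over the amino-acid alphabet.
randomSeqs <- function(n, L = 147L, gapFrac = 0) {
  alpha <- c("A","R","N","D","C","Q","E","G","H","I",
             "L","K","M","F","P","S","T","W","Y","V")
  vapply(seq_len(n), function(i) {
    ch <- sample(alpha, L, replace = TRUE)
    if (gapFrac > 0) {
      g <- runif(L) < gapFrac
      ch[g] <- "."
    }
    paste(ch, collapse = "")
  }, character(1L))
}

# A small random clone table with duplicate sequences across animals and
# groups, for partition property tests. Uses the current RNG stream.
randomCloneTable <- function(nRecords = 120L, nDistinct = 60L, L = 30L) {
  pool <- randomSeqs(nDistinct, L)
  poolLabelPoly <- runif(nDistinct) < 0.3
  pick <- sample(nDistinct, nRecords, replace = TRUE)
  animals <- sprintf("an%02d", 1:6)
  groups <- rep(c("A1", "A2", "A3"), each = 2L)
  ai <- sample(6L, nRecords, replace = TRUE)
  poly <- poolLabelPoly[pick]
  df <- data.frame(
    clone_id = sprintf("r%04d", seq_len(nRecords)),
    animal = animals[ai],
    antigen_group = groups[ai],
    first_timepoint = sample(c("bleed1", "bleed2", "bleed3", "bleed4"),
                             nRecords, replace = TRUE),
    enriched_antigen = TRUE,
    enriched_polyantigen = poly,
    label = ifelse(poly, "polyspecific", "antigen_specific"),
    vh_aligned = pool[pick],
    stringsAsFactors = FALSE)
  new("CloneTable", clones = df, provenance = list())
}

# Independent metric formulas from confusion counts (the formula oracle);
# returns NA where a denominator vanishes, matching the documented
# convention.
oraclePanel <- function(TP, FP, FN, TN) {
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  f1 <- if (2 * TP + FP + FN > 0) (2 * TP) / (2 * TP + FP + FN) else NA_real_
  den <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (den > 0) (TP * TN - FP * FN) / sqrt(den) else NA_real_
  c(f1 = f1, mcc = mcc, sensitivity = sens, specificity = spec)
}

# Brute-force all-pairs AUROC with half-credit for ties.
oracleAUROC <- function(probs, y) {
  pos <- probs[y == 1]
  neg <- probs[y == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Reference BH step-up: sorted p * n / rank with cumulative minimum.
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# A small planted-signal data set (features + labels) for model tests:
# two informative columns among `d`, classes separated by `delta`.
toySeparable <- function(n = 400L, d = 2L, delta = 2) {
  y <- rep(0:1, length.out = n)
  X <- matrix(rnorm(n * d), n, d)
  X[y == 1, 1:2] <- X[y == 1, 1:2] + delta
  list(X = X, y = y)
}

# Small synthetic models/fixtures for importance tests: L = 4 positions x
# 6 components = 24 features keeps the permutation engine fast while
# exercising every code path.
tinyTrainedModel <- function(inputDim = 24L, seed = 3L) {
  cfg <- modelConfig(inputDim = inputDim, hiddenUnits = c(4L, 3L),
                     learningRate = 1e-2, epochs = 3L, batchSize = 16L,
                     seed = seed)
  set.seed(seed)
  X <- matrix(rnorm(80 * inputDim), 80)
  y <- rbinom(80, 1, 0.5)
  if (length(unique(y)) < 2) y[1:2] <- 0:1
  list(fit = trainModel(buildModel(cfg), X, y), X = X, y = y)
}

# A PropertyPCA with chosen loadings (validity-conforming filler scores).
fakePCA <- function(loadings) {
  k <- ncol(loadings)
  set.seed(99)
  sc <- scale(matrix(rnorm(20 * k), 20))
  attr(sc, "scaled:center") <- NULL
  attr(sc, "scaled:scale") <- NULL
  rownames(sc) <- c("A","R","N","D","C","Q","E","G","H","I",
                    "L","K","M","F","P","S","T","W","Y","V")
  new("PropertyPCA", loadings = loadings, scoresStd = sc,
      medians = apply(sc, 2, median),
      varianceExplained = rep(1 / k, k), nComponents = as.integer(k))
}

# An ImportanceResult carrying a chosen perRound matrix for L positions x
# k components.
fakeImportance <- function(perRound, L) {
  nf <- ncol(perRound)
  k <- nf %/% L
  pv <- pvaluesFromRounds(perRound)
  new("ImportanceResult",
      featureIds = encodingFeatureIds(L, k),
      positions = as.integer((seq_len(nf) - 1L) %% L + 1L),
      components = as.integer((seq_len(nf) - 1L) %/% L + 1L),
      perRound = perRound, meanRatio = colMeans(perRound),
      pValue = pv, fdr = benjaminiHochberg(pv))
}
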