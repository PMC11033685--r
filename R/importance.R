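## Permutation-based variable importance (dropout loss ratio), one-tailed
## nonparametric p-values, BH FDR, and back-calculation of importance onto
## the raw physico-chemical properties through the PCA loadings.
##
## Permuting a single input feature only shifts the first dense layer's
## pre-activation by a rank-1 update, so each permuted forward pass reuses
## the unpermuted pre-activation and costs O(n x units) instead of a full
## input-width matrix product.

#' Permutation feature importance (dropout loss ratio)
#'
#' In each resampling round, a class-balanced subsample
#' (subsamplePerClass clones per class, drawn with replacement) is scored
#' by the model to obtain the unpermuted binary cross-entropy; then, for
#' every feature separately, the feature's values are permuted across the
#' subsample nPerm times, the loss is recomputed, and the mean of the
#' nPerm permuted/unpermuted loss ratios is stored for that round. The
#' one-tailed p-value of a feature is the fraction of rounds whose ratio
#' is <= 1 (the null being that permuting the feature does not increase
#' the loss), corrected across features by Benjamini-Hochberg.
#'
#' @param model a trained [PolyspecModel-class]
#' @param features numeric matrix, width inputDim
#' @param labels class labels (polyspecific = positive)
#' @param nRounds resampling rounds (default 1000)
#' @param subsamplePerClass clones drawn per class per round (default 1500)
#' @param nPerm permutations averaged per round (default 3)
#' @param seed integer RNG seed
#' @param L aligned sequence length used to name features (default:
#'   inferred as inputDim / nComponents from the feature count)
#' @param nComponents principal components per position (default 6)
#' @return an [ImportanceResult-class]
#' @export
permutationImportance <- function(model, features, labels, nRounds = 1000L,
                                  subsamplePerClass = 1500L, nPerm = 3L,
                                  seed = 1L, L = NULL, nComponents = 6L) {
  stopifnot(is(model, "PolyspecModel"))
  cfg <- model@config
  if (ncol(features) != cfg@inputDim)
    stop(sprintf("feature width %d does not match inputDim %d",
                 ncol(features), cfg@inputDim))
  y <- .binLabels(labels)
  pos <- which(y == 1L)
  neg <- which(y == 0L)
  if (!length(pos) || !length(neg))
    stop("both classes must be present")
  nf <- ncol(features)
  if (is.null(L)) {
    if (nf %% nComponents != 0L)
      stop("feature count is not a multiple of nComponents; supply L")
    L <- nf %/% nComponents
  }
  fid <- if (!is.null(colnames(features))) colnames(features)
         else encodingFeatureIds(L, nComponents)
  W1 <- model@params$layers[[1L]]$W
  consts <- .inferConsts(model@params, cfg)
  m <- as.integer(subsamplePerClass)
  perRound <- matrix(NA_real_, nRounds, nf, dimnames = list(NULL, fid))
  chunkSize <- 24L    # features forwarded per batched inference call
  withSeed(seed, {
    for (r in seq_len(nRounds)) {
      idx <- c(sample(pos, m, replace = TRUE), sample(neg, m, replace = TRUE))
      Xs <- features[idx, , drop = FALSE]
      ys <- y[idx]
      n <- length(ys)
      Z1 <- Xs %*% W1
      ## base loss summed exactly like the per-segment losses below, so an
      ## unchanged prediction yields a ratio of exactly 1
      p0 <- pmin(pmax(.forwardFast(consts, Z1), BCE_CLIP), 1 - BCE_CLIP)
      ll0 <- -(ys * log(p0) + (1 - ys) * log(1 - p0))
      L0 <- as.numeric(rowsum(ll0, rep.int(1L, n))) / n
      ## permuted losses, batched: nPerm rank-1-updated copies of Z1 per
      ## feature, stacked for one forward pass per chunk of features
      sums <- numeric(nf)
      for (f0 in seq(1L, nf, by = chunkSize)) {
        fs <- f0:min(f0 + chunkSize - 1L, nf)
        Zbig <- Z1[rep(seq_len(n), length(fs) * nPerm), , drop = FALSE]
        seg <- 0L
        for (f in fs) {
          xf <- Xs[, f]
          w <- W1[f, ]
          for (t in seq_len(nPerm)) {
            rows <- seg * n + seq_len(n)
            delta <- xf[sample.int(n)] - xf
            Zbig[rows, ] <- Zbig[rows, ] + outer(delta, w)
            seg <- seg + 1L
          }
        }
        p <- pmin(pmax(.forwardFast(consts, Zbig), BCE_CLIP), 1 - BCE_CLIP)
        yb <- rep.int(ys, length(fs) * nPerm)
        ll <- -(yb * log(p) + (1 - yb) * log(1 - p))
        segMeans <- rowsum(ll, rep(seq_len(length(fs) * nPerm), each = n)) / n
        ## ratio per segment before averaging: an unchanged loss is then
        ## exactly 1 regardless of nPerm
        sums[fs] <- rowSums(matrix(segMeans / L0, nrow = length(fs),
                                   byrow = TRUE))
      }
      perRound[r, ] <- sums / nPerm
    }
  })
  pv <- pvaluesFromRounds(perRound)
  new("ImportanceResult", featureIds = fid,
      positions = as.integer((seq_len(nf) - 1L) %% L + 1L),
      components = as.integer((seq_len(nf) - 1L) %/% L + 1L),
      perRound = perRound, meanRatio = colMeans(perRound),
      pValue = pv, fdr = benjaminiHochberg(pv))
}

#' One-tailed p-values from per-round dropout loss ratios
#'
#' p = fraction of resampling rounds where the ratio was <= 1.
#'
#' @param perRound numeric matrix, rounds x features (or a vector for one
#'   feature)
#' @return numeric p-value vector
#' @export
pvaluesFromRounds <- function(perRound) {
  if (is.null(dim(perRound))) perRound <- matrix(perRound, ncol = 1L)
  if (nrow(perRound) < 1L) stop("at least one round is required")
  colMeans(perRound <= 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted values (capped at 1, order-preserving with the
#' input), as implemented by \code{stats::p.adjust(method = "BH")}.
#'
#' @param pValues numeric vector of p-values in [0, 1]
#' @return numeric vector of adjusted values
#' @export
benjaminiHochberg <- function(pValues) {
  if (any(pValues < 0 | pValues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pValues, method = "BH")
}

#' Back-calculate importance onto raw physico-chemical properties
#'
#' For each position and property, the per-round back-calculated
#' importance is the loading-weighted combination of that position's
#' per-component dropout loss ratios:
#' sum_i(ratio_i * loading_i) / sum_j(loading_j), with i, j over the
#' retained components and signed loadings by default. Because signed
#' loadings can sum to nearly zero, entries whose loading sum is below
#' \code{tol} in magnitude are flagged undefined and excluded from the FDR
#' correction; \code{absLoadings = TRUE} switches to absolute-value
#' weights (a plausible alternative reading, clearly non-default). Means,
#' p-values (fraction of rounds <= 1) and BH FDR (pooled over all defined
#' position x property entries) are then computed exactly as for the
#' direct features.
#'
#' @param imp an [ImportanceResult-class]
#' @param pca the [PropertyPCA-class] behind the encoding
#' @param positions positions to cover (default: all in \code{imp})
#' @param properties property accessions to cover (default: all in the
#'   PCA loadings)
#' @param absLoadings use absolute loadings as weights (default FALSE)
#' @param tol magnitude below which a loading sum counts as zero
#' @return a [BackCalcResult-class]
#' @export
backCalculate <- function(imp, pca, positions = NULL, properties = NULL,
                          absLoadings = FALSE, tol = 1e-8) {
  stopifnot(is(imp, "ImportanceResult"), is(pca, "PropertyPCA"))
  k <- pca@nComponents
  if (max(imp@components) != k)
    stop("importance components do not match the PCA component count")
  Lall <- max(imp@positions)
  if (is.null(positions)) positions <- seq_len(Lall)
  W <- pcaLoadings(pca)
  if (is.null(properties)) properties <- rownames(W)
  stopifnot(all(properties %in% rownames(W)))
  W <- W[properties, , drop = FALSE]
  if (absLoadings) W <- abs(W)
  denom <- rowSums(W)
  defined <- abs(denom) > tol
  Wn <- W / ifelse(defined, denom, NA_real_)   # P x k, rows sum to 1

  nR <- nrow(imp@perRound)
  nP <- length(positions)
  nQ <- length(properties)
  per <- array(NA_real_, dim = c(nR, nP, nQ),
               dimnames = list(NULL, positions, properties))
  for (r in seq_len(nR)) {
    R <- matrix(imp@perRound[r, ], nrow = Lall, ncol = k) # pos x comp
    per[r, , ] <- R[positions, , drop = FALSE] %*% t(Wn)
  }
  mn <- apply(per, c(2L, 3L), mean)
  pv <- apply(per <= 1, c(2L, 3L), mean)
  definedMat <- matrix(rep(defined, each = nP), nP, nQ,
                       dimnames = dimnames(mn))
  fdr <- matrix(NA_real_, nP, nQ, dimnames = dimnames(mn))
  fdr[definedMat] <- benjaminiHochberg(pv[definedMat])
  pv[!definedMat] <- NA_real_
  new("BackCalcResult", positions = as.integer(positions),
      propertyIds = properties, perRound = per, mean = mn, pValue = pv,
      fdr = fdr, defined = definedMat, absLoadings = absLoadings)
}

#' Rank properties by their maximum back-calculated importance
#'
#' Properties sorted in descending order of the maximum mean importance
#' across positions (undefined entries ignored); ties broken by property id
#' lexicographically.
#'
#' @param back a [BackCalcResult-class]
#' @param topN how many properties to return (default 10; a larger value
#'   returns the full ranking)
#' @return character vector of property accessions
#' @export
rankProperties <- function(back, topN = 10L) {
  stopifnot(is(back, "BackCalcResult"))
  m <- back@mean
  m[!back@defined] <- NA_real_
  maxImp <- apply(m, 2L, function(v) if (all(is.na(v))) -Inf else max(v, na.rm = TRUE))
  ord <- order(-maxImp, names(maxImp))
  utils::head(names(maxImp)[ord], topN)
}

#' Default framework/CDR region map
#'
#' Assigns each aligned position to FR1, CDR1, FR2, CDR2, FR3, CDR3 or FR4
#' as contiguous blocks. The default boundaries (FR1 = 1-25, CDR1 = 26-35,
#' FR2 = 36-49, CDR2 = 50-65, FR3 = 66-104, CDR3 = 105-140, FR4 = 141-147)
#' are a stand-in layout for the 147-position frame; real analyses should
#' supply the boundaries of their numbering scheme.
#'
#' @param L aligned sequence length (default 147)
#' @param ends named integer vector of region end positions in canonical
#'   order; the last entry must equal L
#' @return a [RegionMap-class]
#' @export
regionMap <- function(L = 147L,
                      ends = c(FR1 = 25L, CDR1 = 35L, FR2 = 49L, CDR2 = 65L,
                               FR3 = 104L, CDR3 = 140L, FR4 = 147L)) {
  stopifnot(identical(names(ends), REGION_LEVELS))
  if (utils::tail(ends, 1L) != L) stop("last region must end at L")
  reg <- factor(rep(REGION_LEVELS, times = diff(c(0L, unname(ends)))),
                levels = REGION_LEVELS)
  new("RegionMap", regions = reg)
}

#' Count significant features per region
#'
#' Tabulates, per antibody region, how many features (direct position x
#' component features, or back-calculated position x property entries)
#' fall below each FDR threshold.
#'
#' @param x an [ImportanceResult-class] or [BackCalcResult-class]
#' @param map a [RegionMap-class] covering the positions
#' @param thresholds FDR cutoffs (default 0.1 and 0.05)
#' @return data.frame with one row per region: total feature count and,
#'   per threshold, the significant count and fraction
#' @export
summarizeByRegion <- function(x, map = regionMap(),
                              thresholds = c(0.1, 0.05)) {
  stopifnot(is(map, "RegionMap"))
  if (is(x, "ImportanceResult")) {
    positions <- x@positions
    fdr <- x@fdr
  } else if (is(x, "BackCalcResult")) {
    grid <- expand.grid(pos = x@positions, prop = seq_along(x@propertyIds))
    keep <- x@defined[cbind(match(grid$pos, x@positions), grid$prop)]
    positions <- grid$pos[keep]
    fdr <- x@fdr[cbind(match(grid$pos, x@positions), grid$prop)][keep]
  } else stop("x must be an ImportanceResult or BackCalcResult")
  reg <- regionOf(map, positions)
  out <- data.frame(region = REGION_LEVELS,
                    n_features = as.integer(table(factor(reg, REGION_LEVELS))),
                    stringsAsFactors = FALSE)
  for (th in thresholds) {
    sig <- table(factor(reg[!is.na(fdr) & fdr < th], REGION_LEVELS))
    out[[sprintf("sig_fdr%g", th)]] <- as.integer(sig)
    out[[sprintf("frac_fdr%g", th)]] <-
      ifelse(out$n_features > 0, as.integer(sig) / out$n_features, 0)
  }
  out
}

#' Write importance tables as TSV
#'
#' Direct features: feature id, position, component, mean ratio, p, FDR and
#' region. Back-calculated: position, property, mean, p, FDR, defined flag
#' and region.
#'
#' @param x an [ImportanceResult-class] or [BackCalcResult-class]
#' @param path output TSV path
#' @param map a [RegionMap-class] (default layout)
#' @export
writeImportanceTSV <- function(x, path, map = regionMap()) {
  if (is(x, "ImportanceResult")) {
    df <- data.frame(feature_id = x@featureIds, position = x@positions,
                     component = x@components, mean_ratio = x@meanRatio,
                     p_value = x@pValue, fdr = x@fdr,
                     region = as.character(regionOf(map, x@positions)),
                     stringsAsFactors = FALSE)
  } else {
    grid <- expand.grid(pos = seq_along(x@positions),
                        prop = seq_along(x@propertyIds))
    df <- data.frame(position = x@positions[grid$pos],
                     property = x@propertyIds[grid$prop],
                     mean_importance = x@mean[cbind(grid$pos, grid$prop)],
                     p_value = x@pValue[cbind(grid$pos, grid$prop)],
                     fdr = x@fdr[cbind(grid$pos, grid$prop)],
                     defined = x@defined[cbind(grid$pos, grid$prop)],
                     region = as.character(regionOf(map, x@positions[grid$pos])),
                     stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
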