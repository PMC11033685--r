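## Metric panel and the cross-validation / holdout evaluation loops.
## Polyspecific is the positive class throughout; the classification
## threshold defaults to 0.5 with ties predicted positive.

METRIC_NAMES <- c("bce_loss", "auroc", "f1", "mcc", "sensitivity",
                  "specificity", "balanced_accuracy")

#' Confusion counts at a probability threshold
#'
#' Predicted positive iff probability >= threshold (a tie at the threshold
#' predicts positive).
#'
#' @param probs predicted probabilities
#' @param labels true labels (polyspecific = positive)
#' @param threshold probability cutoff (default 0.5)
#' @return named integer vector c(TP, FP, FN, TN)
#' @export
confusionAtThreshold <- function(probs, labels, threshold = 0.5) {
  y <- .binLabels(labels)
  if (!length(probs)) stop("empty input")
  if (length(probs) != length(y)) stop("probs and labels differ in length")
  pred <- probs >= threshold
  c(TP = sum(pred & y == 1L), FP = sum(pred & y == 0L),
    FN = sum(!pred & y == 1L), TN = sum(!pred & y == 0L))
}

## Midrank AUROC (equivalent to the Mann-Whitney statistic with tie
## midranks).
.aurocMidrank <- function(probs, y) {
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(probs, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Metric panel from confusion counts; denominator-zero cases yield NA.
.panelFromConfusion <- function(cc) {
  ## double precision: the MCC denominator overflows 32-bit integers
  TP <- as.numeric(cc[["TP"]]); FP <- as.numeric(cc[["FP"]])
  FN <- as.numeric(cc[["FN"]]); TN <- as.numeric(cc[["TN"]])
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  f1 <- if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN) else NA_real_
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (den > 0) (TP * TN - FP * FN) / sqrt(den) else NA_real_
  bal <- if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_
  c(f1 = f1, mcc = mcc, sensitivity = sens, specificity = spec,
    balanced_accuracy = bal)
}

#' Compute the metric panel
#'
#' Binary cross-entropy (probabilities clipped to [1e-7, 1 - 1e-7]),
#' midrank AUROC, and the threshold metrics F1, MCC, sensitivity,
#' specificity and balanced accuracy at the given cutoff. With single-class
#' labels, AUROC and MCC are undefined and reported as NA with a warning.
#'
#' @inheritParams confusionAtThreshold
#' @return named numeric vector over
#'   \code{c("bce_loss","auroc","f1","mcc","sensitivity","specificity","balanced_accuracy")}
#' @export
computeMetrics <- function(probs, labels, threshold = 0.5) {
  y <- .binLabels(labels)
  if (!length(probs)) stop("empty input")
  if (length(unique(y)) < 2L)
    warning("single-class labels: auroc and mcc are undefined")
  cc <- confusionAtThreshold(probs, y, threshold)
  c(bce_loss = .bce(probs, y), auroc = .aurocMidrank(probs, y),
    .panelFromConfusion(cc))
}

#' F1 of a label-independent random classifier
#'
#' Baseline F1 for a classifier whose predictions are independent of the
#' true label at the given positive-class prevalence, taking precision =
#' prevalence and recall = 1/2 (a coin-flip classifier):
#' F1 = 2 p (1/2) / (p + 1/2). At low prevalence this approaches 2p.
#'
#' @param prevalence positive-class prevalence in (0, 1)
#' @return baseline F1 value
#' @export
baselineF1 <- function(prevalence) {
  if (any(prevalence <= 0 | prevalence >= 1))
    stop("prevalence must lie strictly in (0, 1)")
  2 * prevalence * 0.5 / (prevalence + 0.5)
}

#' Cross-validate the classifier over a list of splits
#'
#' For each split: encode both sides, train a model on the training side
#' (with a fold-specific seed derived from the model config seed), predict
#' the validation side and compute the metric panel. Folds whose validation
#' side has a single class report NA for the undefined metrics.
#'
#' @param table a [CloneTable-class] holding the labeled clones
#' @param splits list of [DataSplit-class]
#' @param pca a fitted [PropertyPCA-class] for the encoding
#' @param config a [ModelConfig-class]
#' @param threshold probability cutoff (default 0.5)
#' @return a [CVReport-class]
#' @export
crossValidate <- function(table, splits, pca, config, threshold = 0.5) {
  stopifnot(is(table, "CloneTable"), length(splits) >= 1L)
  seqs <- sequences(table)
  labs <- cloneLabels(table)
  rows <- lapply(seq_along(splits), function(i) {
    sp <- splits[[i]]
    foldCfg <- config
    ## fold seed derived from the fold's content, so identical folds train
    ## identically and distinct folds get distinct streams
    h <- sum(vapply(c(sp@trainIds, sp@valIds),
                    function(s) sum(utf8ToInt(s)), numeric(1L))) %% 99991
    foldCfg@seed <- stageSeed(config@seed, 10L + h)
    Xtr <- encodeBatch(seqs[trainIds(sp)], pca)
    Xva <- encodeBatch(seqs[valIds(sp)], pca)
    fit <- trainModel(buildModel(foldCfg), Xtr, labs[trainIds(sp)])
    probs <- predictProba(fit, Xva)
    panel <- suppressWarnings(computeMetrics(probs, labs[valIds(sp)], threshold))
    data.frame(fold = sp@name, scheme = sp@scheme, t(panel),
               stringsAsFactors = FALSE)
  })
  perFold <- do.call(rbind, rows)
  summary <- data.frame(
    metric = METRIC_NAMES,
    mean = vapply(METRIC_NAMES, function(m) mean(perFold[[m]], na.rm = TRUE),
                  numeric(1L)),
    sd = vapply(METRIC_NAMES, function(m) stats::sd(perFold[[m]], na.rm = TRUE),
                numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  new("CVReport", perFold = perFold, summary = summary)
}

#' Evaluate a trained model on a holdout clone table
#'
#' Encodes the (labeled) holdout clones and reuses [computeMetrics()]
#' unchanged — the holdout path is the same metric panel as
#' cross-validation, applied to clones never seen in training.
#'
#' @param model a trained [PolyspecModel-class]
#' @param table a labeled [CloneTable-class] (e.g. the holdout side of
#'   [markHoldout()])
#' @param pca the [PropertyPCA-class] used for training
#' @param threshold probability cutoff
#' @return named numeric metric panel
#' @export
evaluateHoldout <- function(model, table, pca, threshold = 0.5) {
  df <- clones(table)
  df <- df[!is.na(df$label), ]
  X <- encodeBatch(stats::setNames(df$vh_aligned, df$clone_id), pca)
  suppressWarnings(computeMetrics(predictProba(model, X), df$label, threshold))
}

#' Write a cross-validation report as TSV and JSON
#'
#' @param report a [CVReport-class]
#' @param tsvPath per-fold TSV output path
#' @param jsonPath summary JSON output path (optional)
#' @export
writeCVReport <- function(report, tsvPath, jsonPath = NULL) {
  utils::write.table(perFold(report), tsvPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(jsonPath)) {
    s <- cvSummary(report)
    jsonlite::write_json(
      stats::setNames(lapply(seq_len(nrow(s)), function(i)
        list(mean = s$mean[i], sd = s$sd[i])), s$metric),
      jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(tsvPath)
}

#' ROC curve points
#'
#' FPR/TPR pairs over all distinct thresholds, for a simple curve dump.
#'
#' @inheritParams confusionAtThreshold
#' @return data.frame with columns fpr, tpr
#' @export
rocPoints <- function(probs, labels) {
  y <- .binLabels(labels)
  ord <- order(probs, decreasing = TRUE)
  tp <- cumsum(y[ord] == 1L)
  fp <- cumsum(y[ord] == 0L)
  keep <- !duplicated(probs[ord], fromLast = TRUE)
  data.frame(fpr = c(0, fp[keep] / max(1L, sum(y == 0L))),
             tpr = c(0, tp[keep] / max(1L, sum(y == 1L))))
}
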