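## Generics and accessor/show methods for the core classes.

#' @export
setGeneric("propertyIds", function(x) standardGeneric("propertyIds"))
#' @export
setGeneric("propertyValues", function(x) standardGeneric("propertyValues"))
#' @export
setGeneric("aminoAcids", function(x) standardGeneric("aminoAcids"))
#' @export
setGeneric("droppedProperties", function(x) standardGeneric("droppedProperties"))
#' @export
setGeneric("pcaLoadings", function(x) standardGeneric("pcaLoadings"))
#' @export
setGeneric("componentScores", function(x) standardGeneric("componentScores"))
#' @export
setGeneric("componentMedians", function(x) standardGeneric("componentMedians"))
#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))
#' @export
setGeneric("clones", function(x) standardGeneric("clones"))
#' @export
setGeneric("nClones", function(x) standardGeneric("nClones"))
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @export
setGeneric("cloneLabels", function(x) standardGeneric("cloneLabels"))
#' @export
setGeneric("trainIds", function(x) standardGeneric("trainIds"))
#' @export
setGeneric("valIds", function(x) standardGeneric("valIds"))
#' @export
setGeneric("splitScheme", function(x) standardGeneric("splitScheme"))
#' @export
setGeneric("trainingLog", function(x) standardGeneric("trainingLog"))
#' @export
setGeneric("modelConfigOf", function(x) standardGeneric("modelConfigOf"))
#' @export
setGeneric("perFold", function(x) standardGeneric("perFold"))
#' @export
setGeneric("cvSummary", function(x) standardGeneric("cvSummary"))
#' @export
setGeneric("featureIdsOf", function(x) standardGeneric("featureIdsOf"))
#' @export
setGeneric("meanRatio", function(x) standardGeneric("meanRatio"))
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))
#' @export
setGeneric("fdrValues", function(x) standardGeneric("fdrValues"))
#' @export
setGeneric("perRound", function(x) standardGeneric("perRound"))
#' @export
setGeneric("regionOf", function(x, positions) standardGeneric("regionOf"))

#' @describeIn AAPropertyMatrix-class property accessions
setMethod("propertyIds", "AAPropertyMatrix", function(x) colnames(x@values))
#' @describeIn AAPropertyMatrix-class the 20 x P value matrix
setMethod("propertyValues", "AAPropertyMatrix", function(x) x@values)
#' @describeIn AAPropertyMatrix-class one-letter amino-acid codes (row order)
setMethod("aminoAcids", "AAPropertyMatrix", function(x) rownames(x@values))
#' @describeIn AAPropertyMatrix-class accessions dropped for missing values
setMethod("droppedProperties", "AAPropertyMatrix", function(x) x@dropped)

setMethod("show", "AAPropertyMatrix", function(object) {
  cat(sprintf("AAPropertyMatrix: 20 amino acids x %d properties (%d dropped)\n",
              ncol(object@values), length(object@dropped)))
})

#' @describeIn PropertyPCA-class property x component loading matrix
setMethod("pcaLoadings", "PropertyPCA", function(x) x@loadings)
#' @describeIn PropertyPCA-class standardized 20 x k amino-acid scores
setMethod("componentScores", "PropertyPCA", function(x) x@scoresStd)
#' @describeIn PropertyPCA-class per-component medians used for 'X'
setMethod("componentMedians", "PropertyPCA", function(x) x@medians)
#' @describeIn PropertyPCA-class variance fractions of all nontrivial components
setMethod("varianceExplained", "PropertyPCA", function(x) x@varianceExplained)
#' @describeIn PropertyPCA-class number of retained components
setMethod("nComponents", "PropertyPCA", function(x) x@nComponents)

setMethod("show", "PropertyPCA", function(object) {
  k <- object@nComponents
  cat(sprintf(
    "PropertyPCA: %d properties -> %d components (%.1f%% variance explained)\n",
    nrow(object@loadings), k, 100 * sum(object@varianceExplained[seq_len(k)])))
})

#' @describeIn CloneTable-class underlying clone data.frame
setMethod("clones", "CloneTable", function(x) x@clones)
#' @describeIn CloneTable-class number of clone records
setMethod("nClones", "CloneTable", function(x) nrow(x@clones))
#' @describeIn CloneTable-class aligned VH sequences, named by clone id
setMethod("sequences", "CloneTable", function(x)
  stats::setNames(x@clones$vh_aligned, x@clones$clone_id))
#' @describeIn CloneTable-class specificity labels, named by clone id
setMethod("cloneLabels", "CloneTable", function(x)
  stats::setNames(x@clones$label, x@clones$clone_id))

setMethod("show", "CloneTable", function(object) {
  df <- object@clones
  cat(sprintf("CloneTable: %d clones, %d animals, %d antigen groups\n",
              nrow(df), length(unique(df$animal)),
              length(unique(df$antigen_group))))
  if (nrow(df))
    cat(sprintf("  labels: %s\n",
                paste(sprintf("%s=%d", names(table(df$label, useNA = "ifany")),
                              table(df$label, useNA = "ifany")), collapse = ", ")))
})

#' @describeIn DataSplit-class training-side clone ids
setMethod("trainIds", "DataSplit", function(x) x@trainIds)
#' @describeIn DataSplit-class validation-side clone ids
setMethod("valIds", "DataSplit", function(x) x@valIds)
#' @describeIn DataSplit-class partitioning scheme name
setMethod("splitScheme", "DataSplit", function(x) x@scheme)

setMethod("show", "DataSplit", function(object) {
  cat(sprintf("DataSplit '%s' (%s): %d train / %d validation\n", object@name,
              object@scheme, length(object@trainIds), length(object@valIds)))
})

#' @describeIn PolyspecModel-class per-epoch mean training loss
setMethod("trainingLog", "PolyspecModel", function(x) x@trainingLog)
#' @describeIn PolyspecModel-class the model's configuration
setMethod("modelConfigOf", "PolyspecModel", function(x) x@config)

setMethod("show", "PolyspecModel", function(object) {
  cfg <- object@config
  cat(sprintf("PolyspecModel: %d -> %s -> 1 (sigmoid), %s\n", cfg@inputDim,
              paste(cfg@hiddenUnits, collapse = " -> "),
              if (length(object@trainingLog))
                sprintf("trained %d epochs (final loss %.4f)",
                        length(object@trainingLog),
                        utils::tail(object@trainingLog, 1L))
              else "untrained"))
})

#' @describeIn CVReport-class per-fold metric rows
setMethod("perFold", "CVReport", function(x) x@perFold)
#' @describeIn CVReport-class mean/SD summary over folds
setMethod("cvSummary", "CVReport", function(x) x@summary)

setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport: %d folds\n", nrow(object@perFold)))
  s <- object@summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-18s %.3f (SD = %.3f)\n", s$metric[i], s$mean[i], s$sd[i]))
})

#' @describeIn ImportanceResult-class feature names "pos<i>_pc<j>"
setMethod("featureIdsOf", "ImportanceResult", function(x) x@featureIds)
#' @describeIn ImportanceResult-class per-feature mean dropout loss ratio
setMethod("meanRatio", "ImportanceResult", function(x) x@meanRatio)
#' @describeIn ImportanceResult-class per-feature one-tailed p-values
setMethod("pValues", "ImportanceResult", function(x) x@pValue)
#' @describeIn ImportanceResult-class per-feature BH-adjusted values
setMethod("fdrValues", "ImportanceResult", function(x) x@fdr)
#' @describeIn ImportanceResult-class round x feature ratio matrix
setMethod("perRound", "ImportanceResult", function(x) x@perRound)

setMethod("show", "ImportanceResult", function(object) {
  cat(sprintf(
    "ImportanceResult: %d features x %d rounds; %d at FDR < 0.05\n",
    length(object@featureIds), nrow(object@perRound),
    sum(object@fdr < 0.05, na.rm = TRUE)))
})

#' @describeIn BackCalcResult-class position x property mean importance
setMethod("meanRatio", "BackCalcResult", function(x) x@mean)
#' @describeIn BackCalcResult-class position x property p-values
setMethod("pValues", "BackCalcResult", function(x) x@pValue)
#' @describeIn BackCalcResult-class position x property BH-adjusted values
setMethod("fdrValues", "BackCalcResult", function(x) x@fdr)
#' @describeIn BackCalcResult-class rounds x position x property array
setMethod("perRound", "BackCalcResult", function(x) x@perRound)

setMethod("show", "BackCalcResult", function(object) {
  cat(sprintf(
    "BackCalcResult: %d positions x %d properties (%d undefined), %d at FDR < 0.05\n",
    length(object@positions), length(object@propertyIds),
    sum(!object@defined), sum(object@fdr < 0.05 & object@defined, na.rm = TRUE)))
})

#' @describeIn RegionMap-class region of each queried 1-based position
setMethod("regionOf", "RegionMap", function(x, positions) {
  stopifnot(all(positions >= 1L), all(positions <= length(x@regions)))
  x@regions[positions]
})

setMethod("show", "RegionMap", function(object) {
  tab <- table(object@regions)
  cat(sprintf("RegionMap over %d positions: %s\n", length(object@regions),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})
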