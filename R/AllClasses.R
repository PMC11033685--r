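## Central S4 classes. Constructors live next to the code that produces each
## object; validity methods encode the container contracts.

#' @import methods
NULL

## Canonical amino-acid row order used by AAindex tables:
## Ala Arg Asn Asp Cys Gln Glu Gly His Ile Leu Lys Met Phe Pro Ser Thr Trp Tyr Val
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

GAP_CHAR <- "."
UNKNOWN_CHAR <- "X"

TIMEPOINT_LEVELS <- c("preimmune", "bleed0", "bleed1", "bleed2", "bleed3", "bleed4")
EARLY_TIMEPOINTS <- c("preimmune", "bleed0")
LABEL_LEVELS <- c("antigen_specific", "polyspecific")

REGION_LEVELS <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")

#' Amino-acid physico-chemical property matrix
#'
#' A 20-row numeric matrix, one row per standard amino acid (in the canonical
#' AAindex row order Ala..Val) and one column per retained physico-chemical
#' property. Properties whose published values contain missing entries may
#' have been dropped or mean-imputed at parse time; the accessions of dropped
#' properties are kept for the parse report.
#'
#' @slot values numeric matrix, 20 x P, dimnames = (one-letter codes, accessions)
#' @slot dropped character, accessions removed because of missing values
#' @export
setClass("AAPropertyMatrix",
  representation(values = "matrix", dropped = "character"))

setValidity("AAPropertyMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (nrow(v) != 20L) return("property matrix must have exactly 20 rows")
  if (!identical(rownames(v), AA_ORDER))
    return("rows must be the 20 standard amino acids in canonical order")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    return("property ids (column names) must be present and unique")
  if (anyNA(v)) return("property matrix must contain no missing values")
  if (ncol(v) < 1L) return("at least one property is required")
  TRUE
})

#' PCA compression of an amino-acid property matrix
#'
#' Holds the decomposition of the column-standardized property matrix:
#' property loadings, standardized per-amino-acid component scores (the
#' values substituted for residues during encoding), per-component medians
#' (used to impute 'X'), and the variance explained by every nontrivial
#' component.
#'
#' @slot loadings numeric matrix, P properties x nComponents
#' @slot scoresStd numeric matrix, 20 amino acids x nComponents; each column
#'   has mean 0 and sd 1 (n-1 denominator) across the 20 amino acids
#' @slot medians numeric, per-component median of scoresStd
#' @slot varianceExplained numeric, fractions over all nontrivial components
#' @slot nComponents integer, retained component count
#' @export
setClass("PropertyPCA",
  representation(loadings = "matrix", scoresStd = "matrix",
                 medians = "numeric", varianceExplained = "numeric",
                 nComponents = "integer"))

setValidity("PropertyPCA", function(object) {
  k <- object@nComponents
  if (length(k) != 1L || k < 1L) return("nComponents must be a positive scalar")
  if (ncol(object@loadings) != k || ncol(object@scoresStd) != k)
    return("loadings and scoresStd must have nComponents columns")
  if (nrow(object@scoresStd) != 20L)
    return("scoresStd must have 20 rows (amino acids)")
  if (length(object@medians) != k)
    return("medians must have one entry per retained component")
  ve <- object@varianceExplained
  if (length(ve) < k) return("varianceExplained must cover the retained components")
  if (any(diff(ve) > 1e-9)) return("varianceExplained must be non-increasing")
  if (abs(sum(ve) - 1) > 1e-6) return("varianceExplained must sum to 1")
  TRUE
})

#' Table of antibody clones
#'
#' Wraps a data.frame of clone records: an aligned VH sequence of fixed
#' length over the 20 amino acids plus '.' (alignment gap) and 'X'
#' (undetermined residue), together with the study metadata (animal, antigen
#' group, first-observed timepoint, enrichment outcomes, specificity label).
#' The label is tied to the enrichment outcomes: a clone enriched by both
#' its antigen and the polyantigen mix is polyspecific, one enriched by the
#' antigen only is antigen-specific, and unenriched clones carry no label.
#'
#' @slot clones data.frame with columns clone_id, animal, antigen_group,
#'   first_timepoint, enriched_antigen, enriched_polyantigen, label,
#'   vh_aligned
#' @slot provenance list; generator configuration or input-file path
#' @export
setClass("CloneTable",
  representation(clones = "data.frame", provenance = "list"))

CLONE_COLUMNS <- c("clone_id", "animal", "antigen_group", "first_timepoint",
                   "enriched_antigen", "enriched_polyantigen", "label",
                   "vh_aligned")

setValidity("CloneTable", function(object) {
  df <- object@clones
  miss <- setdiff(CLONE_COLUMNS, names(df))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(df$clone_id)) return("clone_ids must be unique")
  if (nrow(df)) {
    if (length(unique(nchar(df$vh_aligned))) != 1L)
      return("all aligned sequences must have the same length")
    bad <- grepl(sprintf("[^%s.X]", paste(AA_ORDER, collapse = "")), df$vh_aligned)
    if (any(bad))
      return(sprintf("illegal sequence characters in rows: %s",
                     paste(utils::head(which(bad), 5L), collapse = ", ")))
    if (!all(df$first_timepoint %in% TIMEPOINT_LEVELS))
      return("first_timepoint outside the known timepoint levels")
    if (!is.logical(df$enriched_antigen) || !is.logical(df$enriched_polyantigen))
      return("enrichment columns must be logical")
    expected <- ifelse(!df$enriched_antigen, NA_character_,
                ifelse(df$enriched_polyantigen, "polyspecific", "antigen_specific"))
    if (!identical(as.character(df$label), expected)) {
      off <- which(!(is.na(df$label) & is.na(expected)) &
                   (is.na(df$label) | is.na(expected) | df$label != expected))
      return(sprintf("label inconsistent with enrichment outcomes in rows: %s",
                     paste(utils::head(off, 5L), collapse = ", ")))
    }
  }
  TRUE
})

#' Train/validation split
#'
#' Disjoint, sequence-deduplicated train and validation clone-id sets
#' produced by one of the four partitioning schemes. After overlap
#' elimination no aligned sequence string occurs on both sides.
#'
#' @slot name character fold name
#' @slot scheme one of random_kfold, repeated_subsample, blocked_animal,
#'   blocked_antigen
#' @slot trainIds,valIds character clone-id vectors
#' @export
setClass("DataSplit",
  representation(name = "character", scheme = "character",
                 trainIds = "character", valIds = "character"))

SPLIT_SCHEMES <- c("random_kfold", "repeated_subsample",
                   "blocked_animal", "blocked_antigen")

setValidity("DataSplit", function(object) {
  if (!object@scheme %in% SPLIT_SCHEMES)
    return(paste("unknown scheme:", object@scheme))
  if (length(intersect(object@trainIds, object@valIds)))
    return("train and validation id sets overlap")
  TRUE
})

#' Classifier configuration
#'
#' Architecture and training hyperparameters of the fully connected
#' classifier: hidden layer sizes (each hidden layer is dense -> batch
#' normalization -> ELU -> dropout), dropout rate, ELU alpha, Adam learning
#' rate, minibatch size (split evenly between the two classes), epoch count
#' and the RNG seed. Batch-normalization epsilon/momentum are exposed so the
#' normalization is fully specified.
#'
#' @slot inputDim integer feature count
#' @slot hiddenUnits integer vector of hidden layer sizes
#' @slot dropoutRate numeric in [0, 1)
#' @slot eluAlpha numeric ELU saturation parameter
#' @slot learningRate numeric Adam step size
#' @slot batchSize even integer; batchSize/2 clones drawn per class
#' @slot epochs integer
#' @slot seed integer
#' @slot bnEps,bnMomentum numeric batch-normalization constants
#' @export
setClass("ModelConfig",
  representation(inputDim = "integer", hiddenUnits = "integer",
                 dropoutRate = "numeric", eluAlpha = "numeric",
                 learningRate = "numeric", batchSize = "integer",
                 epochs = "integer", seed = "integer",
                 bnEps = "numeric", bnMomentum = "numeric"))

setValidity("ModelConfig", function(object) {
  if (length(object@hiddenUnits) < 1L || any(object@hiddenUnits < 1L))
    return("hiddenUnits must be nonempty with all sizes >= 1")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    return("dropoutRate must be in [0, 1)")
  if (object@batchSize %% 2L != 0L || object@batchSize < 2L)
    return("batchSize must be even and >= 2")
  if (object@inputDim < 1L) return("inputDim must be >= 1")
  if (object@epochs < 0L) return("epochs must be >= 0")
  if (object@learningRate <= 0) return("learningRate must be > 0")
  TRUE
})

#' Trained (or freshly initialized) classifier
#'
#' Holds all layer parameters, including batch-normalization running
#' statistics, plus the configuration and the per-epoch mean training loss.
#' Inference is deterministic: dropout is inactive and batch normalization
#' uses the running statistics.
#'
#' @slot params list of per-layer parameter arrays
#' @slot config ModelConfig
#' @slot trainingLog numeric, one mean binary cross-entropy per epoch
#' @export
setClass("PolyspecModel",
  representation(params = "list", config = "ModelConfig",
                 trainingLog = "numeric"))

#' Cross-validation report
#'
#' Per-fold metric panels and their mean/SD summary (SD over folds, n-1
#' denominator), mirroring the mean (SD) reporting convention used for
#' repertoire-scale cross-validation.
#'
#' @slot perFold data.frame, one row per fold, one column per metric
#' @slot summary data.frame with columns metric, mean, sd
#' @export
setClass("CVReport",
  representation(perFold = "data.frame", summary = "data.frame"))

#' Permutation feature importance result
#'
#' Per-feature dropout-loss-ratio distribution over resampling rounds, with
#' the round mean, the one-tailed nonparametric p-value (fraction of rounds
#' with ratio <= 1) and its Benjamini-Hochberg FDR.
#'
#' @slot featureIds character "pos<i>_pc<j>" feature names
#' @slot positions,components integer decomposition of the feature ids
#' @slot perRound numeric matrix, nRounds x nFeatures
#' @slot meanRatio,pValue,fdr numeric per-feature summaries
#' @export
setClass("ImportanceResult",
  representation(featureIds = "character", positions = "integer",
                 components = "integer", perRound = "matrix",
                 meanRatio = "numeric", pValue = "numeric", fdr = "numeric"))

setValidity("ImportanceResult", function(object) {
  p <- length(object@featureIds)
  if (ncol(object@perRound) != p) return("perRound must have one column per feature")
  if (length(object@meanRatio) != p || length(object@pValue) != p ||
      length(object@fdr) != p)
    return("per-feature summaries must match the feature count")
  if (any(object@pValue < 0 | object@pValue > 1, na.rm = TRUE))
    return("p-values must lie in [0, 1]")
  if (any(object@fdr + 1e-12 < object@pValue, na.rm = TRUE))
    return("FDR must be >= p-value elementwise")
  TRUE
})

#' Back-calculated importance on raw physico-chemical properties
#'
#' Importance of each (position, property) pair obtained by projecting the
#' per-component dropout loss ratios back through the property's PCA
#' loadings (signed weighted mean by default). Pairs whose loading sum is
#' numerically zero are flagged undefined and excluded from the FDR
#' correction.
#'
#' @slot positions integer positions covered
#' @slot propertyIds character property accessions covered
#' @slot perRound numeric array, nRounds x nPositions x nProperties
#' @slot mean,pValue,fdr numeric matrices, nPositions x nProperties
#' @slot defined logical matrix; FALSE where the loading sum underflowed
#' @slot absLoadings logical; TRUE if absolute loadings were used
#' @export
setClass("BackCalcResult",
  representation(positions = "integer", propertyIds = "character",
                 perRound = "array", mean = "matrix", pValue = "matrix",
                 fdr = "matrix", defined = "matrix", absLoadings = "logical"))

setValidity("BackCalcResult", function(object) {
  d <- dim(object@perRound)
  if (length(d) != 3L) return("perRound must be a 3-d array")
  if (d[2L] != length(object@positions) || d[3L] != length(object@propertyIds))
    return("perRound extents must match positions x properties")
  if (!all(dim(object@mean) == d[2:3])) return("mean matrix has wrong shape")
  ok <- object@defined
  if (any(object@fdr[ok] + 1e-12 < object@pValue[ok], na.rm = TRUE))
    return("FDR must be >= p-value elementwise")
  TRUE
})

#' Map from aligned positions to antibody regions
#'
#' Total assignment of every aligned position 1..L to one of the framework
#' and CDR regions (FR1, CDR1, FR2, CDR2, FR3, CDR3, FR4), as contiguous
#' blocks in canonical order.
#'
#' @slot regions factor of length L with levels FR1..FR4
#' @export
setClass("RegionMap", representation(regions = "factor"))

setValidity("RegionMap", function(object) {
  r <- object@regions
  if (!identical(levels(r), REGION_LEVELS)) return("region levels must be FR1..FR4")
  if (anyNA(r)) return("every position must be assigned a region")
  idx <- as.integer(r)
  if (any(diff(idx) < 0L))
    return("regions must form contiguous blocks in canonical order")
  TRUE
})
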