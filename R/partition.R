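## Train/validation partitioning. All schemes work on the sequence-
## deduplicated table (the unit of splitting is the unique aligned
## sequence, represented by its first clone record), and every emitted
## split has train/validation overlaps explicitly eliminated so the two
## sides are disjoint both as id sets and as sequence-string sets.

#' Deduplicate a clone table by aligned sequence
#'
#' Keeps the first record of every unique sequence. Sequences carrying
#' conflicting labels across records (both classes) are dropped entirely,
#' with a message reporting the count.
#'
#' @param table a [CloneTable-class]
#' @return a [CloneTable-class] of unique-sequence representative records
#' @export
dedupBySequence <- function(table) {
  stopifnot(is(table, "CloneTable"))
  df <- clones(table)
  nlab <- tapply(df$label, df$vh_aligned,
                 function(l) length(unique(l[!is.na(l)])))
  conflict <- names(nlab)[nlab > 1L]
  if (length(conflict))
    message(sprintf("dropping %d sequence(s) with conflicting labels",
                    length(conflict)))
  df <- df[!df$vh_aligned %in% conflict, ]
  df <- df[!duplicated(df$vh_aligned), ]
  rownames(df) <- NULL
  new("CloneTable", clones = df, provenance = table@provenance)
}

.newSplit <- function(name, scheme, trainIds, valIds) {
  new("DataSplit", name = name, scheme = scheme,
      trainIds = as.character(trainIds), valIds = as.character(valIds))
}

#' Random k-fold cross-validation splits
#'
#' Partitions the unique sequences into k folds of near-equal size (sizes
#' differ by at most one); each fold in turn is the validation set.
#'
#' @param table a [CloneTable-class] (deduplicated internally)
#' @param k number of folds (default 10)
#' @param seed integer RNG seed
#' @return list of [DataSplit-class]
#' @export
makeRandomKFold <- function(table, k = 10L, seed = 1L) {
  dd <- dedupBySequence(table)
  ids <- clones(dd)$clone_id
  n <- length(ids)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop(sprintf("k = %d exceeds the %d unique sequences", k, n))
  fold <- withSeed(seed, sample(rep_len(seq_len(k), n)))
  lapply(seq_len(k), function(f)
    eliminateOverlap(.newSplit(sprintf("fold%02d", f), "random_kfold",
                               ids[fold != f], ids[fold == f]), dd))
}

#' Repeated random subsampling splits
#'
#' Draws \code{reps} independent validation subsets of size
#' \code{round(fracVal * N)} from the unique sequences; validation sets of
#' different repetitions may overlap each other.
#'
#' @param table a [CloneTable-class] (deduplicated internally)
#' @param fracVal validation fraction in (0, 1) (default 0.1)
#' @param reps number of repetitions (default 10)
#' @param seed integer RNG seed
#' @return list of [DataSplit-class]
#' @export
makeRepeatedSubsamples <- function(table, fracVal = 0.1, reps = 10L, seed = 1L) {
  if (fracVal <= 0 || fracVal >= 1) stop("fracVal must lie strictly in (0, 1)")
  dd <- dedupBySequence(table)
  ids <- clones(dd)$clone_id
  n <- length(ids)
  nVal <- round(fracVal * n)
  if (nVal < 1L || nVal >= n)
    stop("degenerate fracVal: empty validation or training side")
  withSeed(seed, lapply(seq_len(as.integer(reps)), function(r) {
    val <- sample(ids, nVal)
    eliminateOverlap(.newSplit(sprintf("rep%02d", r), "repeated_subsample",
                               setdiff(ids, val), val), dd)
  }))
}

#' Group-blocked cross-validation splits
#'
#' One split per level of the blocking variable (animal or antigen group):
#' the level's clones form the validation set and all other levels form the
#' training set. A sequence observed in several levels (e.g. a clone found
#' in multiple animals) would appear on both sides; overlap elimination
#' removes it from the training side.
#'
#' @param table a [CloneTable-class]
#' @param groupBy \code{"antigen_group"} or \code{"animal"}
#' @return list of [DataSplit-class]
#' @export
makeBlockedFolds <- function(table, groupBy = c("antigen_group", "animal")) {
  groupBy <- match.arg(groupBy)
  dd <- dedupBySequence(table)
  full <- clones(table)
  rep_ <- clones(dd)
  levelsOf <- sort(unique(full[[groupBy]]))
  if (length(levelsOf) < 2L)
    stop(sprintf("blocking variable '%s' has a single level", groupBy))
  scheme <- if (groupBy == "animal") "blocked_animal" else "blocked_antigen"
  ## every level each sequence occurs in, over the full record set
  seqLevels <- tapply(full[[groupBy]], full$vh_aligned, unique, simplify = FALSE)
  lapply(levelsOf, function(lev) {
    inLevel <- vapply(seqLevels[rep_$vh_aligned], function(g) lev %in% g,
                      logical(1L))
    eliminateOverlap(.newSplit(paste0(groupBy, "=", lev), scheme,
                               rep_$clone_id[!inLevel],
                               rep_$clone_id[inLevel]), dd)
  })
}

#' Eliminate train/validation sequence overlap
#'
#' Any aligned sequence occurring on both sides of a split is removed from
#' one side (by default the training side, preserving the validation
#' distribution used for reporting). Each side is also internally
#' deduplicated by sequence.
#'
#' @param split a [DataSplit-class]
#' @param table the [CloneTable-class] the ids refer to
#' @param removeFrom side to prune: \code{"train"} (default) or
#'   \code{"validation"}
#' @return a [DataSplit-class] with sequence-disjoint sides
#' @export
eliminateOverlap <- function(split, table, removeFrom = c("train", "validation")) {
  removeFrom <- match.arg(removeFrom)
  stopifnot(is(split, "DataSplit"), is(table, "CloneTable"))
  seqs <- sequences(table)
  missing <- setdiff(c(split@trainIds, split@valIds), names(seqs))
  if (length(missing))
    stop(sprintf("split references unknown clone ids (e.g. %s)", missing[1L]))
  tr <- split@trainIds[!duplicated(seqs[split@trainIds])]
  va <- split@valIds[!duplicated(seqs[split@valIds])]
  shared <- intersect(seqs[tr], seqs[va])
  if (length(shared)) {
    if (removeFrom == "train") tr <- tr[!seqs[tr] %in% shared]
    else va <- va[!seqs[va] %in% shared]
  }
  .newSplit(split@name, split@scheme, tr, va)
}

#' Serialize splits to JSON and back
#'
#' Stores scheme, fold name and the two id lists per split so a
#' partitioning can be reused across runs.
#'
#' @param splits list of [DataSplit-class]
#' @param path JSON file path
#' @return \code{readSplits}: list of [DataSplit-class]
#' @export
writeSplits <- function(splits, path) {
  payload <- lapply(splits, function(s)
    list(name = s@name, scheme = s@scheme,
         train_ids = s@trainIds, val_ids = s@valIds))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeSplits
#' @export
readSplits <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(payload, function(s)
    .newSplit(s$name, s$scheme, unlist(s$train_ids), unlist(s$val_ids)))
}
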