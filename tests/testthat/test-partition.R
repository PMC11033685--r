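splitSeqs <- function(sp, tab) {
  seqs <- sequences(tab)
  list(train = unname(seqs[trainIds(sp)]), val = unname(seqs[valIds(sp)]))
}

expectValidSplit <- function(sp, tab) {
  ss <- splitSeqs(sp, tab)
  expect_length(intersect(trainIds(sp), valIds(sp)), 0L)
  expect_length(intersect(ss$train, ss$val), 0L)
  expect_false(anyDuplicated(ss$train) > 0)
  expect_false(anyDuplicated(ss$val) > 0)
}

test_that("random k-fold partitions the unique sequences into near-equal folds", {
  set.seed(10)
  tab <- randomCloneTable(300L, 200L)
  dd <- dedupBySequence(tab)
  n <- nClones(dd)
  splits <- makeRandomKFold(tab, k = 10L, seed = 3L)
  expect_length(splits, 10L)
  sizes <- vapply(splits, function(s) length(valIds(s)), integer(1L))
  expect_lte(diff(range(sizes)), 1L)
  expect_identical(sum(sizes), n)
  allVal <- unlist(lapply(splits, valIds))
  expect_false(anyDuplicated(allVal) > 0)           # pairwise disjoint
  expect_setequal(allVal, clones(dd)$clone_id)      # union = everything
  ## determinism
  again <- makeRandomKFold(tab, k = 10L, seed = 3L)
  expect_identical(lapply(splits, valIds), lapply(again, valIds))
  expect_error(makeRandomKFold(tab, k = n + 1L), "exceeds")
})

test_that("repeated subsampling draws the configured validation fraction", {
  set.seed(11)
  tab <- randomCloneTable(250L, 150L)
  n <- nClones(dedupBySequence(tab))
  splits <- makeRepeatedSubsamples(tab, fracVal = 0.1, reps = 10L, seed = 4L)
  expect_length(splits, 10L)
  for (sp in splits) {
    expect_identical(length(valIds(sp)), as.integer(round(0.1 * n)))
    expectValidSplit(sp, tab)
  }
  ## validation sets of different reps may overlap (they are independent)
  ov <- length(intersect(valIds(splits[[1L]]), valIds(splits[[2L]])))
  expect_gte(ov, 0L)
  ## a single rep is a plain holdout split
  expect_length(makeRepeatedSubsamples(tab, reps = 1L, seed = 4L), 1L)
  expect_error(makeRepeatedSubsamples(tab, fracVal = 0), "strictly")
})

test_that("blocked folds are group-pure after overlap elimination", {
  set.seed(12)
  tab <- randomCloneTable(400L, 180L)
  full <- clones(tab)
  byAntigen <- makeBlockedFolds(tab, "antigen_group")
  expect_length(byAntigen, 3L)
  byAnimal <- makeBlockedFolds(tab, "animal")
  expect_length(byAnimal, 6L)
  seqGroups <- tapply(full$antigen_group, full$vh_aligned, unique,
                      simplify = FALSE)
  for (i in seq_along(byAntigen)) {
    sp <- byAntigen[[i]]
    expectValidSplit(sp, tab)
    lev <- sub("^antigen_group=", "", sp@name)
    ss <- splitSeqs(sp, tab)
    ## no training sequence is observed in the validation group
    expect_false(any(vapply(seqGroups[ss$train],
                            function(g) lev %in% g, logical(1L))))
    ## every validation sequence is observed in the validation group
    expect_true(all(vapply(seqGroups[ss$val],
                           function(g) lev %in% g, logical(1L))))
  }
  ## single-level blocking is rejected
  one <- tab
  one@clones$antigen_group <- "A1"
  expect_error(makeBlockedFolds(one, "antigen_group"), "single level")
})

test_that("overlap elimination prunes the requested side only", {
  df <- data.frame(
    clone_id = c("a", "b", "c", "d"),
    animal = "an01", antigen_group = "A1", first_timepoint = "bleed1",
    enriched_antigen = TRUE, enriched_polyantigen = FALSE,
    label = "antigen_specific",
    vh_aligned = c("AAA", "CCC", "AAA", "DDD"),
    stringsAsFactors = FALSE)
  tab <- new("CloneTable", clones = df, provenance = list())
  sp <- new("DataSplit", name = "f", scheme = "random_kfold",
            trainIds = c("a", "b"), valIds = c("c", "d"))
  ## "AAA" occurs on both sides: training loses it, validation keeps it
  out <- eliminateOverlap(sp, tab)
  expect_identical(trainIds(out), "b")
  expect_identical(valIds(out), c("c", "d"))
  ## the opposite policy prunes validation
  out2 <- eliminateOverlap(sp, tab, removeFrom = "validation")
  expect_identical(trainIds(out2), c("a", "b"))
  expect_identical(valIds(out2), "d")
  ## identity when nothing is shared
  sp3 <- new("DataSplit", name = "f", scheme = "random_kfold",
             trainIds = "b", valIds = "d")
  out3 <- eliminateOverlap(sp3, tab)
  expect_identical(trainIds(out3), "b")
  expect_identical(valIds(out3), "d")
  expect_error(eliminateOverlap(
    new("DataSplit", name = "f", scheme = "random_kfold",
        trainIds = "zz", valIds = "d"), tab), "unknown clone ids")
})

test_that("sequences with conflicting labels are dropped entirely", {
  df <- data.frame(
    clone_id = c("a", "b", "c"),
    animal = "an01", antigen_group = "A1", first_timepoint = "bleed1",
    enriched_antigen = TRUE,
    enriched_polyantigen = c(TRUE, FALSE, FALSE),
    label = c("polyspecific", "antigen_specific", "antigen_specific"),
    vh_aligned = c("AAA", "AAA", "CCC"),
    stringsAsFactors = FALSE)
  tab <- new("CloneTable", clones = df, provenance = list())
  expect_message(dd <- dedupBySequence(tab), "conflicting labels")
  expect_identical(clones(dd)$clone_id, "c")
})

test_that("every scheme emits valid splits across random tables and seeds", {
  set.seed(99)
  for (rep in 1:8) {
    tab <- randomCloneTable(sample(80:200, 1L), sample(40:120, 1L))
    seed <- sample.int(1000L, 1L)
    splits <- c(makeRandomKFold(tab, k = 4L, seed = seed),
                makeRepeatedSubsamples(tab, reps = 3L, seed = seed),
                makeBlockedFolds(tab, "antigen_group"),
                makeBlockedFolds(tab, "animal"))
    for (sp in splits) {
      expectValidSplit(sp, tab)
      expect_true(validObject(sp))
    }
  }
})

test_that("splits serialize to JSON and back losslessly", {
  set.seed(13)
  tab <- randomCloneTable(100L, 60L)
  splits <- makeRandomKFold(tab, k = 5L, seed = 2L)
  path <- withr::local_tempfile(fileext = ".json")
  writeSplits(splits, path)
  back <- readSplits(path)
  expect_identical(lapply(back, trainIds), lapply(splits, trainIds))
  expect_identical(lapply(back, valIds), lapply(splits, valIds))
  expect_identical(vapply(back, splitScheme, ""),
                   vapply(splits, splitScheme, ""))
})
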