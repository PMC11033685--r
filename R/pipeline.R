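## End-to-end orchestration: generate (or load) clones -> mark holdout ->
## fit encoding -> splits -> cross-validate -> final model -> holdout
## evaluation -> permutation importance -> back-calculation -> reports.
## One global seed fans out to per-stage seeds via stageSeed().

.defaultRunConfig <- function() {
  list(
    seed = 1L,
    property_table = "builtin",       # "builtin" (bundled AAindex), or a path
    na_policy = "drop",
    clone_table = NULL,               # CSV path; NULL -> synthetic generator
    generator = list(),               # overrides for generatorConfig()
    encoder = list(n_components = 6L),
    split = list(scheme = "random_kfold", k = 10L, frac_val = 0.1,
                 reps = 10L, group_by = "antigen_group"),
    model = list(),                   # overrides for modelConfig()
    importance = list(n_rounds = 100L, subsample_per_class = 300L, n_perm = 3L)
  )
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a pipeline run configuration
#'
#' Accepts a YAML file path or a list of overrides; unspecified settings
#' fall back to the defaults (synthetic generator input, bundled AAindex
#' property table, random 10-fold splitting, importance at 100 rounds x
#' 300 clones per class).
#'
#' @param config YAML path or list
#' @return a complete configuration list
#' @export
runConfig <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  .mergeConfig(.defaultRunConfig(), config)
}

.configHash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}

## log lines go to stderr and, during a run, to <runDir>/run.log
.logState <- new.env(parent = emptyenv())

.log <- function(fmt, ...) {
  line <- sprintf(paste0("[polyspec] ", fmt), ...)
  message(line)
  if (!is.null(.logState$file))
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), line, "\n",
        file = .logState$file, append = TRUE, sep = "")
}

#' Run the full analysis pipeline
#'
#' Executes every stage into a fresh run directory (refusing to reuse a
#' non-empty one, so no artifact is silently overwritten): clone
#' generation or loading, holdout marking, property-PCA fitting, split
#' construction, cross-validation, final-model training on the full
#' modelling set, holdout evaluation, permutation importance and
#' back-calculation. All artifacts are stamped with the config hash and
#' seed; reruns with the same config and seed reproduce the same artifacts.
#'
#' @param config a [runConfig()] list or YAML path
#' @param outDir run directory to create
#' @return invisibly, the run directory path
#' @export
runPipeline <- function(config, outDir) {
  cfg <- runConfig(config)
  ## startup validation before any artifact is written
  if (!identical(cfg$property_table, "builtin") &&
      !file.exists(cfg$property_table))
    stop(sprintf("property table not found: %s", cfg$property_table))
  if (!is.null(cfg$clone_table) && !file.exists(cfg$clone_table))
    stop(sprintf("clone table not found: %s", cfg$clone_table))
  if (dir.exists(outDir) && length(list.files(outDir)))
    stop(sprintf("run directory %s already exists and is not empty", outDir))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  .logState$file <- file.path(outDir, "run.log")
  on.exit(.logState$file <- NULL)
  seed <- as.integer(cfg$seed)
  stamp <- list(config_hash = .configHash(cfg), seed = seed)
  jsonlite::write_json(c(stamp, list(config = cfg)),
                       file.path(outDir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  .log("stage 1/7: property table + PCA")
  properties <- if (identical(cfg$property_table, "builtin"))
    aaindexTable(naPolicy = cfg$na_policy)
  else parseAAindex(cfg$property_table, naPolicy = cfg$na_policy)
  pca <- fitPropertyPCA(properties, nComponents = cfg$encoder$n_components)

  .log("stage 2/7: clone table")
  table <- if (is.null(cfg$clone_table)) {
    gen <- do.call(generatorConfig,
                   c(cfg$generator, list(seed = stageSeed(seed, 1L))))
    generateRepertoire(gen, properties)
  } else readCloneTable(cfg$clone_table)
  writeCloneTable(table, file.path(outDir, "clones.csv"))

  .log("stage 3/7: holdout marking")
  parts <- markHoldout(table)
  modelling <- parts$modelling

  .log("stage 4/7: splits (%s)", cfg$split$scheme)
  splits <- switch(cfg$split$scheme,
    random_kfold = makeRandomKFold(modelling, k = cfg$split$k,
                                   seed = stageSeed(seed, 2L)),
    repeated_subsample = makeRepeatedSubsamples(
      modelling, fracVal = cfg$split$frac_val, reps = cfg$split$reps,
      seed = stageSeed(seed, 2L)),
    blocked_antigen = makeBlockedFolds(modelling, "antigen_group"),
    blocked_animal = makeBlockedFolds(modelling, "animal"),
    stop(sprintf("unknown split scheme '%s'", cfg$split$scheme)))
  writeSplits(splits, file.path(outDir, "splits.json"))

  mcfg <- do.call(modelConfig, c(
    cfg$model,
    list(inputDim = nchar(clones(table)$vh_aligned[1L]) *
           cfg$encoder$n_components,
         seed = stageSeed(seed, 3L))))

  .log("stage 5/7: cross-validation (%d folds)", length(splits))
  report <- crossValidate(modelling, splits, pca, mcfg)
  writeCVReport(report, file.path(outDir, "cv_folds.tsv"),
                file.path(outDir, "cv_summary.json"))

  .log("stage 6/7: final model + holdout evaluation")
  dd <- dedupBySequence(modelling)
  X <- encodeBatch(sequences(dd), pca)
  final <- trainModel(buildModel(mcfg), X, cloneLabels(dd))
  writeModel(final, file.path(outDir, "model.json"))
  holdoutPanel <- if (nClones(parts$holdout))
    evaluateHoldout(final, parts$holdout, pca) else NULL
  jsonlite::write_json(as.list(holdoutPanel),
                       file.path(outDir, "holdout_metrics.json"),
                       auto_unbox = TRUE, digits = NA)

  .log("stage 7/7: importance + back-calculation")
  imp <- permutationImportance(
    final, X, cloneLabels(dd),
    nRounds = cfg$importance$n_rounds,
    subsamplePerClass = cfg$importance$subsample_per_class,
    nPerm = cfg$importance$n_perm, seed = stageSeed(seed, 4L),
    nComponents = cfg$encoder$n_components)
  map <- regionMap(nchar(clones(table)$vh_aligned[1L]))
  writeImportanceTSV(imp, file.path(outDir, "importance.tsv"), map)
  back <- backCalculate(imp, pca)
  writeImportanceTSV(back, file.path(outDir, "importance_backcalc.tsv"), map)
  jsonlite::write_json(
    list(top_properties = rankProperties(back, 10L)),
    file.path(outDir, "top_properties.json"))

  reportRun(outDir)
  .log("run complete: %s", outDir)
  invisible(outDir)
}

#' Render a human-readable run summary
#'
#' Writes \code{report.md} into the run directory: the per-scheme metric
#' table as mean (SD) rows, the holdout panel, and the top-10 property
#' ranking. Incomplete runs produce a partial report with notes on the
#' missing stages.
#'
#' @param runDir a directory produced by [runPipeline()]
#' @return invisibly, the report path
#' @export
reportRun <- function(runDir) {
  p <- function(...) file.path(runDir, ...)
  if (!file.exists(p("run.json"))) stop("not a run directory (run.json missing)")
  meta <- jsonlite::read_json(p("run.json"))
  lines <- c("# polyspec run report", "",
             sprintf("- config hash: `%s`", meta$config_hash),
             sprintf("- seed: %s", meta$seed), "")
  if (file.exists(p("cv_summary.json"))) {
    s <- jsonlite::read_json(p("cv_summary.json"))
    lines <- c(lines, "## Cross-validation (mean; SD across folds)", "",
               "| metric | mean | SD |", "|---|---|---|",
               vapply(names(s), function(m)
                 sprintf("| %s | %.3f | %.3f |", m, s[[m]]$mean, s[[m]]$sd),
                 character(1L)), "")
  } else lines <- c(lines, "_cross-validation stage missing_", "")
  if (file.exists(p("holdout_metrics.json"))) {
    h <- jsonlite::read_json(p("holdout_metrics.json"))
    if (length(h))
      lines <- c(lines, "## Holdout evaluation", "",
                 vapply(names(h), function(m) {
                   v <- h[[m]]
                   sprintf("- %s: %s", m,
                           if (is.null(v) || !length(v)) "NA"
                           else sprintf("%.3f", as.numeric(v)))
                 }, character(1L)), "")
  }
  if (file.exists(p("top_properties.json"))) {
    tp <- unlist(jsonlite::read_json(p("top_properties.json"))$top_properties)
    lines <- c(lines, "## Top properties by back-calculated importance", "",
               sprintf("%d. %s", seq_along(tp), tp), "")
  } else lines <- c(lines, "_importance stage missing_", "")
  writeLines(lines, p("report.md"))
  invisible(p("report.md"))
}
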