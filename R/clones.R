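## Synthetic antibody repertoires emulating an immunization study layout:
## several antigen groups x several animals, timepoints preimmune..bleed4,
## a strong antigen-specific:polyspecific class imbalance, clone sharing
## across animals/groups, and planted class-dependent physico-chemical
## shifts at chosen positions (by exponential tilting of the background
## residue distribution along a chosen property's standardized values).

ANTIGEN_GROUPS <- function(n) paste0("A", seq_len(n))

#' Synthetic repertoire generator configuration
#'
#' @param clonesPerAnimal clones generated per animal
#' @param nAnimalsPerAntigen animals per immunization antigen (default 3)
#' @param nAntigens number of immunization antigens / groups (default 3)
#' @param imbalance antigen-specific : polyspecific odds (default 113, i.e.
#'   a 1:113 polyspecific:antigen-specific ratio per animal)
#' @param plantedPositions 1-based aligned positions carrying the planted
#'   class effect (default: five framework-3 positions)
#' @param plantedProperty accession of the property whose standardized
#'   values drive the planted shift; required when \code{effectSize > 0}
#' @param effectSize mean shift, in standardized property units, of the
#'   polyspecific class at the planted positions (default 0 = null model)
#' @param fracPreimmune fraction of clones first observed at
#'   preimmune/bleed0 (holdout-triggering timepoints)
#' @param fracShared fraction of sequences duplicated into a second animal
#'   (possibly of another antigen group)
#' @param tpWeightsSpecific,tpWeightsPoly per-class sampling weights over
#'   bleed1..bleed4 for the first-observed timepoint; the defaults skew
#'   polyspecific mass to bleed1-2 and antigen-specific mass to bleed4
#' @param L aligned sequence length (default 147)
#' @param seed integer RNG seed
#' @return a \code{GeneratorConfig} object
#' @export
generatorConfig <- function(clonesPerAnimal = 2000L,
                            nAnimalsPerAntigen = 3L,
                            nAntigens = 3L,
                            imbalance = 113,
                            plantedPositions = c(70L, 75L, 80L, 85L, 90L),
                            plantedProperty = NA_character_,
                            effectSize = 0,
                            fracPreimmune = 0.05,
                            fracShared = 0.02,
                            tpWeightsSpecific = c(0.15, 0.20, 0.25, 0.40),
                            tpWeightsPoly = c(0.40, 0.35, 0.15, 0.10),
                            L = 147L,
                            seed = 1L) {
  new("GeneratorConfig",
      clonesPerAnimal = as.integer(clonesPerAnimal),
      nAnimalsPerAntigen = as.integer(nAnimalsPerAntigen),
      nAntigens = as.integer(nAntigens),
      imbalance = as.numeric(imbalance),
      plantedPositions = as.integer(plantedPositions),
      plantedProperty = as.character(plantedProperty),
      effectSize = as.numeric(effectSize),
      fracPreimmune = as.numeric(fracPreimmune),
      fracShared = as.numeric(fracShared),
      tpWeightsSpecific = as.numeric(tpWeightsSpecific),
      tpWeightsPoly = as.numeric(tpWeightsPoly),
      L = as.integer(L),
      seed = as.integer(seed))
}

#' @rdname generatorConfig
#' @export
setClass("GeneratorConfig",
  representation(clonesPerAnimal = "integer", nAnimalsPerAntigen = "integer",
                 nAntigens = "integer", imbalance = "numeric",
                 plantedPositions = "integer", plantedProperty = "character",
                 effectSize = "numeric", fracPreimmune = "numeric",
                 fracShared = "numeric", tpWeightsSpecific = "numeric",
                 tpWeightsPoly = "numeric", L = "integer", seed = "integer"))

setValidity("GeneratorConfig", function(object) {
  if (object@imbalance <= 0) return("imbalance must be > 0")
  fr <- c(object@fracPreimmune, object@fracShared)
  if (any(fr < 0 | fr > 1)) return("fractions must lie in [0, 1]")
  if (any(object@plantedPositions < 1L | object@plantedPositions > object@L))
    return("planted positions must lie in [1, L]")
  if (length(object@tpWeightsSpecific) != 4L ||
      length(object@tpWeightsPoly) != 4L)
    return("timepoint weights must cover bleed1..bleed4")
  if (any(object@tpWeightsSpecific < 0) || any(object@tpWeightsPoly < 0))
    return("timepoint weights must be non-negative")
  if (object@clonesPerAnimal < 1L) return("clonesPerAnimal must be >= 1")
  TRUE
})

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf(
    "GeneratorConfig: %d antigens x %d animals x %d clones, 1:%g imbalance%s\n",
    object@nAntigens, object@nAnimalsPerAntigen, object@clonesPerAnimal,
    object@imbalance,
    if (object@effectSize > 0)
      sprintf(", %s planted at %d positions (effect %.2f)",
              object@plantedProperty, length(object@plantedPositions),
              object@effectSize)
    else ", null (no planted effect)"))
})

## Fixed background residue profile: a deterministic function of L alone,
## built from broadly protein-like base frequencies perturbed per position
## with an internally fixed RNG stream.
.backgroundProfile <- function(L) {
  base <- c(A = 8.3, R = 5.5, N = 4.1, D = 5.5, C = 1.4, Q = 3.9, E = 6.7,
            G = 7.1, H = 2.3, I = 5.9, L = 9.7, K = 5.8, M = 2.4, F = 3.9,
            P = 4.7, S = 6.6, T = 5.4, W = 1.1, Y = 2.9, V = 6.9)
  base <- base / sum(base)
  withSeed(900147L, {
    noise <- matrix(stats::rgamma(20L * L, shape = 6), nrow = 20L)
    prof <- base * noise
    sweep(prof, 2L, colSums(prof), `/`)
  }) -> prof
  rownames(prof) <- AA_ORDER
  prof
}

## Standardized property values (mean 0, sd 1 over the 20 amino acids).
.standardizedProperty <- function(properties, id) {
  V <- propertyValues(properties)
  if (!id %in% colnames(V))
    stop(sprintf("planted property '%s' is absent from the property table", id))
  v <- V[, id]
  (v - mean(v)) / stats::sd(v)
}

## Solve the exponential-tilt strength theta such that the tilted
## distribution q(a) ~ p(a) exp(theta s_a) shifts E[s] by delta.
.solveTilt <- function(p, s, delta) {
  shift <- function(theta) {
    w <- p * exp(theta * s - max(theta * s)) # guard overflow
    sum(w * s) / sum(w) - sum(p * s)
  }
  maxShift <- max(s[p > 0]) - sum(p * s)
  if (delta >= maxShift - 1e-6) {
    warning("effect size at or beyond the achievable shift; ",
            "tilted distribution degenerates towards the extreme residue")
    return(500)
  }
  stats::uniroot(function(th) shift(th) - delta, lower = 0, upper = 500,
                 extendInt = "upX", tol = 1e-9)$root
}

#' Generate a synthetic labeled repertoire
#'
#' Draws aligned VH sequences position-wise from a fixed background residue
#' profile (with a variable-length gap block in the CDR3 region), assigns
#' each clone to the polyspecific class by a Bernoulli draw with odds
#' 1:imbalance per animal, and, for polyspecific clones, tilts the residue
#' distribution at the planted positions so the expected standardized value
#' of the planted property shifts by \code{effectSize}. First-observed
#' timepoints are drawn per class (polyspecific mass skewed to bleed1-2),
#' a fraction of clones is first observed preimmune/bleed0, and a fraction
#' of sequences is duplicated into a second animal. Deterministic under a
#' fixed config seed.
#'
#' @param config a [generatorConfig()]
#' @param properties an [AAPropertyMatrix-class]; required when
#'   \code{effectSize > 0} (source of the planted property's values)
#' @return a [CloneTable-class]
#' @export
generateRepertoire <- function(config, properties = NULL) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  L <- config@L
  prof <- .backgroundProfile(L)
  tilt <- NULL
  if (config@effectSize > 0) {
    if (is.null(properties))
      stop("a property table is required to plant an effect")
    s <- .standardizedProperty(properties, config@plantedProperty)
    tilt <- lapply(config@plantedPositions, function(i) {
      p <- prof[, i]
      theta <- .solveTilt(p, s, config@effectSize)
      w <- p * exp(theta * s - max(theta * s))
      w / sum(w)
    })
    names(tilt) <- as.character(config@plantedPositions)
  }

  groups <- ANTIGEN_GROUPS(config@nAntigens)
  nAnimals <- config@nAntigens * config@nAnimalsPerAntigen
  animalIds <- sprintf("an%02d", seq_len(nAnimals))
  animalGroup <- rep(groups, each = config@nAnimalsPerAntigen)

  withSeed(config@seed, {
    n <- nAnimals * config@clonesPerAnimal
    animal <- rep(animalIds, each = config@clonesPerAnimal)
    group <- rep(animalGroup, each = config@clonesPerAnimal)
    poly <- stats::rbinom(n, 1L, 1 / (1 + config@imbalance)) == 1L

    ## residues, position by position
    chars <- matrix("", nrow = n, ncol = L)
    for (i in seq_len(L)) {
      chars[, i] <- sample(AA_ORDER, n, replace = TRUE, prob = prof[, i])
      key <- as.character(i)
      if (!is.null(tilt) && key %in% names(tilt) && any(poly))
        chars[poly, i] <- sample(AA_ORDER, sum(poly), replace = TRUE,
                                 prob = tilt[[key]])
    }

    ## variable-length CDR3: gap out the middle of the CDR3 block
    cdr3 <- which(as.character(regionOf(regionMap(L), seq_len(L))) == "CDR3")
    if (length(cdr3) > 2L) {
      blockLen <- length(cdr3)
      occ <- pmin(pmax(round(stats::rnorm(n, mean = 18, sd = 4)), 8L), blockLen)
      left <- ceiling(occ / 2)
      right <- occ - left
      for (b in seq_along(cdr3)) {
        gap <- (b > left) & (b <= blockLen - right)
        if (any(gap)) chars[gap, cdr3[b]] <- GAP_CHAR
      }
    }
    seqsv <- do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))

    ## first-observed timepoints
    early <- stats::runif(n) < config@fracPreimmune
    tp <- character(n)
    tp[early] <- sample(EARLY_TIMEPOINTS, sum(early), replace = TRUE)
    lateSpec <- !early & !poly
    latePoly <- !early & poly
    bleeds <- TIMEPOINT_LEVELS[3:6]
    tp[lateSpec] <- sample(bleeds, sum(lateSpec), replace = TRUE,
                           prob = config@tpWeightsSpecific)
    tp[latePoly] <- sample(bleeds, sum(latePoly), replace = TRUE,
                           prob = config@tpWeightsPoly)

    df <- data.frame(
      clone_id = sprintf("c%07d", seq_len(n)),
      animal = animal,
      antigen_group = group,
      first_timepoint = tp,
      enriched_antigen = TRUE,
      enriched_polyantigen = poly,
      label = ifelse(poly, "polyspecific", "antigen_specific"),
      vh_aligned = seqsv,
      stringsAsFactors = FALSE)

    ## duplicate a fraction of sequences into a second animal
    nShared <- round(config@fracShared * n)
    if (nShared > 0L) {
      src <- sample.int(n, nShared)
      dest <- vapply(df$animal[src], function(a)
        sample(setdiff(animalIds, a), 1L), character(1L))
      copies <- df[src, ]
      copies$clone_id <- sprintf("c%07d", n + seq_len(nShared))
      copies$animal <- dest
      copies$antigen_group <- animalGroup[match(dest, animalIds)]
      df <- rbind(df, copies)
    }
    rownames(df) <- NULL
    df
  }) -> df

  new("CloneTable", clones = df,
      provenance = list(generator = config))
}

#' Split a clone table into modelling and holdout sets
#'
#' The holdout set collects every clone whose sequence is tied to a
#' holdout trigger: first observed at preimmune or bleed0 (likely
#' immunization-independent), or shared between different antigen groups.
#' All records carrying a triggered sequence move to the holdout side, so
#' the two returned tables are sequence-disjoint and partition the input.
#'
#' @param table a [CloneTable-class]
#' @return list with elements \code{modelling} and \code{holdout}
#' @export
markHoldout <- function(table) {
  stopifnot(is(table, "CloneTable"))
  df <- clones(table)
  earlySeqs <- unique(df$vh_aligned[df$first_timepoint %in% EARLY_TIMEPOINTS])
  groupsPerSeq <- tapply(df$antigen_group, df$vh_aligned,
                         function(g) length(unique(g)))
  sharedSeqs <- names(groupsPerSeq)[groupsPerSeq > 1L]
  trigger <- df$vh_aligned %in% c(earlySeqs, sharedSeqs)
  mk <- function(rows) new("CloneTable", clones = {
    out <- df[rows, ]; rownames(out) <- NULL; out
  }, provenance = table@provenance)
  list(modelling = mk(!trigger), holdout = mk(trigger))
}

#' Read and write clone tables as CSV
#'
#' Lossless round-trip of the clone-table columns; on read, the label
#' column is validated against the enrichment booleans and offending rows
#' are reported.
#'
#' @param path CSV file path
#' @param table a [CloneTable-class]
#' @return \code{readCloneTable}: a [CloneTable-class]
#' @export
readCloneTable <- function(path) {
  header <- names(utils::read.csv(path, nrows = 0L))
  miss <- setdiff(CLONE_COLUMNS, header)
  if (length(miss))
    stop(sprintf("clone table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = list(clone_id = "character",
                                          vh_aligned = "character",
                                          label = "character"))
  df <- df[, CLONE_COLUMNS]
  df$label[df$label == ""] <- NA_character_
  new("CloneTable", clones = df, provenance = list(path = path))
}

#' @rdname readCloneTable
#' @export
writeCloneTable <- function(table, path) {
  stopifnot(is(table, "CloneTable"))
  utils::write.csv(clones(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export clone sequences as FASTA
#'
#' Writes vh_aligned with a description line carrying the clone metadata.
#'
#' @param table a [CloneTable-class]
#' @param path output FASTA path
#' @export
writeCloneFasta <- function(table, path) {
  df <- clones(table)
  nm <- sprintf("%s animal=%s antigen_group=%s first_timepoint=%s label=%s",
                df$clone_id, df$animal, df$antigen_group, df$first_timepoint,
                ifelse(is.na(df$label), "unlabeled", df$label))
  writeAlignedFasta(stats::setNames(df$vh_aligned, nm), path)
}
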