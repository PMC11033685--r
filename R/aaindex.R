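## AAindex1 property tables: flat-file parser and the bundled-database
## loader. An AAindex1 entry looks like
##
##   H ACCESSION
##   D free-text description
##   ...
##   I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
##      v(A) v(R) v(N) v(D) v(C) v(Q) v(E) v(G) v(H) v(I)
##      v(L) v(K) v(M) v(F) v(P) v(S) v(T) v(W) v(Y) v(V)
##   //
##
## Only the H line, the I header and the two value rows are interpreted.

## The expected I-line column headers, fixing the amino-acid order.
AAINDEX_I_HEADER <- c("A/L", "R/K", "N/M", "D/F", "C/P",
                      "Q/S", "E/T", "G/W", "H/Y", "I/V")

#' Construct an amino-acid property matrix
#'
#' @param values numeric 20 x P matrix; rownames must be (a permutation of)
#'   the 20 standard one-letter codes, colnames the unique property ids.
#'   Rows are reordered to the canonical AAindex order Ala..Val.
#' @param dropped character, accessions removed upstream (parse report)
#' @return an [AAPropertyMatrix-class] object
#' @export
AAPropertyMatrix <- function(values, dropped = character()) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  if (!setequal(rownames(values), AA_ORDER))
    stop("rownames must be the 20 standard amino-acid one-letter codes")
  new("AAPropertyMatrix", values = values[AA_ORDER, , drop = FALSE],
      dropped = as.character(dropped))
}

#' Parse an AAindex1 flat file into a property matrix
#'
#' Reads every entry of an AAindex1-format file (accession line \code{H},
#' index header \code{I} naming the 20 amino acids, two rows of 10 values,
#' \code{//} terminator) into one column per property. Entries containing
#' any missing value (\code{NA} in the file) are, under the default policy,
#' dropped and recorded in the parse report ([droppedProperties()]); under
#' \code{naPolicy = "impute-mean"} missing cells are replaced by the mean of
#' the property's observed values. Column order follows file order.
#'
#' @param file path to an AAindex1-format file
#' @param text optional character scalar/vector with the file content
#'   (overrides \code{file})
#' @param naPolicy \code{"drop"} (default) or \code{"impute-mean"}
#' @return an [AAPropertyMatrix-class]
#' @examples
#' panel <- parseAAindex(system.file("extdata", "aaindex_panel.txt",
#'                                   package = "polyspec"))
#' propertyIds(panel)
#' @export
parseAAindex <- function(file, text = NULL, naPolicy = c("drop", "impute-mean")) {
  naPolicy <- match.arg(naPolicy)
  lines <- if (!is.null(text)) {
    unlist(strsplit(paste(text, collapse = "\n"), "\r?\n"))
  } else {
    readLines(file, warn = FALSE)
  }
  ## split into entries on '//' terminators
  term <- grep("^//", lines)
  if (!length(term)) stop("no '//'-terminated AAindex entries found")
  starts <- c(1L, utils::head(term, -1L) + 1L)
  cols <- list()
  dropped <- character()
  for (e in seq_along(term)) {
    chunk <- lines[starts[e]:(term[e] - 1L)]
    chunk <- chunk[nzchar(trimws(chunk))]
    if (!length(chunk)) next
    hline <- grep("^H ", chunk, value = TRUE)
    if (!length(hline)) stop("entry without an 'H' accession line")
    acc <- trimws(sub("^H ", "", hline[1L]))
    iline <- grep("^I ", chunk)
    if (!length(iline))
      stop(sprintf("entry %s: missing 'I' index header", acc))
    header <- strsplit(trimws(sub("^I ", "", chunk[iline[1L]])), "[[:space:]]+")[[1L]]
    if (!identical(header, AAINDEX_I_HEADER))
      stop(sprintf("entry %s: unexpected amino acids in index header", acc))
    if (length(chunk) < iline[1L] + 2L)
      stop(sprintf("entry %s: expected two value rows after the index header", acc))
    rows <- chunk[iline[1L] + 1:2]
    vals <- lapply(rows, function(r) {
      toks <- strsplit(trimws(r), "[[:space:]]+")[[1L]]
      if (length(toks) != 10L)
        stop(sprintf("entry %s: value row has %d fields, expected 10",
                     acc, length(toks)))
      isna <- toks %in% c("NA", "-")
      v <- suppressWarnings(as.numeric(toks))
      if (any(is.na(v) & !isna))
        stop(sprintf("entry %s: non-numeric value field '%s'",
                     acc, toks[which(is.na(v) & !isna)[1L]]))
      v
    })
    v <- c(vals[[1L]], vals[[2L]])
    if (anyNA(v)) {
      if (naPolicy == "drop") {
        dropped <- c(dropped, acc)
        next
      }
      v[is.na(v)] <- mean(v, na.rm = TRUE)
    }
    if (acc %in% names(cols))
      stop(sprintf("duplicate accession %s", acc))
    cols[[acc]] <- v
  }
  if (!length(cols))
    stop("no properties retained: every entry contained missing values")
  values <- do.call(cbind, cols)
  rownames(values) <- AA_ORDER
  AAPropertyMatrix(values, dropped = dropped)
}

#' The bundled AAindex property collection
#'
#' Builds the full amino-acid property matrix from the AAindex collection
#' distributed with the \pkg{seqinr} package (544 indices), applying the
#' same missing-value policy as [parseAAindex()]. This is the table used to
#' fit the physico-chemical PCA encoding at full scale.
#'
#' @inheritParams parseAAindex
#' @return an [AAPropertyMatrix-class]
#' @export
aaindexTable <- function(naPolicy = c("drop", "impute-mean")) {
  naPolicy <- match.arg(naPolicy)
  aaindex <- NULL # silence R CMD check; bound by data() below
  utils::data("aaindex", package = "seqinr", envir = environment())
  vals <- vapply(aaindex, function(x) unname(x$I), numeric(20L))
  colnames(vals) <- vapply(aaindex, function(x) x$H, character(1L))
  rownames(vals) <- AA_ORDER
  complete <- colSums(is.na(vals)) == 0L
  if (naPolicy == "drop") {
    AAPropertyMatrix(vals[, complete, drop = FALSE],
                     dropped = colnames(vals)[!complete])
  } else {
    for (j in which(!complete))
      vals[is.na(vals[, j]), j] <- mean(vals[, j], na.rm = TRUE)
    AAPropertyMatrix(vals)
  }
}
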