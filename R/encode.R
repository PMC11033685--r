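## Physico-chemical PCA encoding of aligned VH sequences.
##
## The property matrix is column-standardized and decomposed by SVD; each
## residue is then replaced by its standardized score on the first
## nComponents principal components, flattening positions so that position i
## / component j lands at vector element ((j-1)*L)+i (1-based). Gaps ('.')
## encode to 0 and undetermined residues ('X') to the per-component median
## score.

#' Fit the property PCA used for sequence encoding
#'
#' Standardizes every property column (zero mean, unit variance, n-1
#' denominator) of the amino-acid property matrix and decomposes it by
#' singular value decomposition. The retained components' 20 amino-acid
#' scores are themselves standardized (these are the values substituted
#' during encoding), and their medians are kept for 'X' imputation.
#' Variance-explained fractions are reported over all nontrivial components
#' (a column-centered 20-row matrix has rank at most 19, so at most 19
#' components carry variance). Component signs are fixed deterministically:
#' each component is oriented so that its largest-absolute property loading
#' is positive.
#'
#' @param M an [AAPropertyMatrix-class]
#' @param nComponents number of components to retain (default 6)
#' @return a [PropertyPCA-class]
#' @examples
#' pca <- fitPropertyPCA(parseAAindex(system.file("extdata",
#'   "aaindex_panel.txt", package = "polyspec")))
#' sum(varianceExplained(pca)[1:6])
#' @export
fitPropertyPCA <- function(M, nComponents = 6L) {
  stopifnot(is(M, "AAPropertyMatrix"))
  nComponents <- as.integer(nComponents)
  V <- propertyValues(M)
  sds <- apply(V, 2L, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant property column(s): %s",
                 paste(colnames(V)[sds == 0], collapse = ", ")))
  X <- scale(V)                         # 20 x P, centered, unit variance
  sv <- svd(X)
  tol <- max(dim(X)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (nComponents > rank)
    stop(sprintf("nComponents = %d exceeds the rank (%d) of the standardized matrix",
                 nComponents, rank))
  ve <- sv$d[seq_len(rank)]^2 / sum(sv$d[seq_len(rank)]^2)
  loadings <- sv$v[, seq_len(nComponents), drop = FALSE]
  ## deterministic sign convention: largest-absolute loading positive
  flip <- vapply(seq_len(nComponents), function(j) {
    l <- loadings[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1L))
  loadings <- sweep(loadings, 2L, flip, `*`)
  rownames(loadings) <- colnames(V)
  colnames(loadings) <- paste0("PC", seq_len(nComponents))
  scores <- X %*% loadings              # 20 x k
  scoresStd <- scale(scores)
  attr(scoresStd, "scaled:center") <- NULL
  attr(scoresStd, "scaled:scale") <- NULL
  rownames(scoresStd) <- rownames(V)
  new("PropertyPCA", loadings = loadings, scoresStd = scoresStd,
      medians = apply(scoresStd, 2L, stats::median),
      varianceExplained = ve, nComponents = nComponents)
}

#' Feature names of the flattened encoding
#'
#' @param L aligned sequence length
#' @param k number of principal components
#' @return character vector "pos<i>_pc<j>" in flattened order, i.e. element
#'   ((j-1)*L)+i names position i, component j
#' @export
encodingFeatureIds <- function(L, k) {
  as.vector(vapply(seq_len(k),
                   function(j) sprintf("pos%d_pc%d", seq_len(L), j),
                   character(L)))
}

## residue -> lookup-row index; stops with 1-based position on illegal chars
.residueIndex <- function(seqs, alphabet) {
  L <- nchar(seqs[1L])
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(seqs), ncol = L, byrow = TRUE)
  idx <- matrix(match(chars, alphabet), nrow = length(seqs), ncol = L)
  if (anyNA(idx)) {
    bad <- which(is.na(idx), arr.ind = TRUE)[1L, ]
    stop(sprintf("illegal character '%s' at position %d of sequence %d",
                 chars[bad[1L], bad[2L]], bad[2L], bad[1L]))
  }
  idx
}

#' Encode aligned sequences into PCA feature matrices
#'
#' \code{encodeBatch} maps each aligned sequence (fixed length L over the 20
#' amino acids plus '.' and 'X') to a numeric vector of length L x
#' nComponents: the residue at position i contributes its standardized
#' component scores at elements ((j-1)*L)+i, gaps contribute 0, and 'X'
#' contributes the per-component median score. \code{encodeSequence} is the
#' single-sequence convenience wrapper.
#'
#' @param seqs character vector of aligned sequences (all the same length)
#' @param seq a single aligned sequence
#' @param pca a fitted [PropertyPCA-class]
#' @return \code{encodeBatch}: numeric matrix, one row per sequence, with
#'   feature-id column names; \code{encodeSequence}: named numeric vector
#' @examples
#' pca <- fitPropertyPCA(parseAAindex(system.file("extdata",
#'   "aaindex_panel.txt", package = "polyspec")))
#' fv <- encodeSequence(strrep("A", 147), pca)
#' length(fv)  # 147 x 6 = 882
#' @export
encodeBatch <- function(seqs, pca) {
  stopifnot(is(pca, "PropertyPCA"))
  k <- pca@nComponents
  if (length(seqs) == 0L)
    return(matrix(numeric(0L), nrow = 0L, ncol = 0L))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences have mixed lengths; all must be pre-aligned to the same L")
  L <- lens[1L]
  ## lookup rows: 20 amino acids, then gap (zeros), then X (medians)
  lookup <- rbind(pca@scoresStd, 0, pca@medians)
  alphabet <- c(rownames(pca@scoresStd), GAP_CHAR, UNKNOWN_CHAR)
  idx <- .residueIndex(seqs, alphabet)
  out <- matrix(0, nrow = length(seqs), ncol = L * k,
                dimnames = list(names(seqs), encodingFeatureIds(L, k)))
  for (j in seq_len(k))
    out[, (j - 1L) * L + seq_len(L)] <-
      matrix(lookup[idx, j], nrow = length(seqs), ncol = L)
  out
}

#' @rdname encodeBatch
#' @export
encodeSequence <- function(seq, pca) {
  stopifnot(length(seq) == 1L)
  drop(encodeBatch(seq, pca))
}

#' Write an encoded feature matrix as TSV
#'
#' One row per sequence with a header row of feature ids and a leading
#' \code{clone_id} column.
#'
#' @param features matrix from [encodeBatch()] with rownames
#' @param path output file
#' @export
writeEncodedTSV <- function(features, path) {
  df <- data.frame(clone_id = rownames(features), features,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read and write aligned sequences as FASTA
#'
#' Thin wrappers around \pkg{seqinr}'s FASTA I/O preserving '.' gap
#' characters; sequence names are clone ids.
#'
#' @param path FASTA file path
#' @param seqs named character vector of aligned sequences
#' @return \code{readAlignedFasta}: named character vector
#' @export
readAlignedFasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  stats::setNames(toupper(unlist(recs)), names(recs))
}

#' @rdname readAlignedFasta
#' @export
writeAlignedFasta <- function(seqs, path) {
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = 80L)
  invisible(path)
}
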