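#' Load the embedded BLOSUM62 substitution matrix
#'
#' Returns the standard BLOSUM62 integer log-odds matrix over the 20 amino
#' acids, read from the plain-text copy shipped with the package. Two residues
#' are treated as "similar" by the substitution machinery when their score is
#' at or above the BLOSUM threshold (1 by default elsewhere in the package).
#'
#' @return A symmetric 20 x 20 integer matrix with residue dimnames.
#' @examples
#' b <- load_blosum62()
#' b["S", "N"]  # 1: serine/asparagine count as similar
#' @export
load_blosum62 <- function() {
  path <- system.file("extdata", "blosum62.tsv", package = "motifgram",
                      mustWork = TRUE)
  read_substitution_matrix(path)
}

#' Read a substitution matrix from a TSV file
#'
#' Expects a square, symmetric matrix with single-letter residue row and
#' column names covering the 20-letter amino-acid alphabet. Any matrix in this
#' layout (BLOSUM80, PAM variants, ...) can be plugged into the substitution
#' step.
#'
#' @param path Path to a tab-separated matrix with residue headers.
#' @return A symmetric integer matrix with residue dimnames.
#' @export
read_substitution_matrix <- function(path) {
  m <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  storage.mode(m) <- "integer"
  if (!identical(rownames(m), colnames(m))) {
    abort("substitution matrix rows and columns must carry the same residue names")
  }
  missing <- setdiff(AA_ALPHABET, rownames(m))
  if (length(missing) > 0) {
    abort(paste0("substitution matrix is missing residues: ",
                 paste(missing, collapse = ", ")))
  }
  if (!isSymmetric(unname(m))) {
    abort("substitution matrix must be symmetric")
  }
  m
}

# Residues beta with score(alpha, beta) >= threshold, excluding alpha itself.
positive_partners <- function(alpha, matrix, threshold = 1L) {
  row <- matrix[alpha, ]
  setdiff(names(row)[row >= threshold], alpha)
}
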