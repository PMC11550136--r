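# Fixed alphabet order used by every one-hot index in the package.
DNA_ALPHABET <- c("A", "C", "G", "T")

#' One-hot encode DNA sequences
#'
#' Converts a character vector of equal-length DNA sequences over
#' \{A,C,G,T\} into an \code{N x L x 4} binary array with exactly one 1 per
#' (sequence, position), using the fixed alphabet order A, C, G, T.
#' Lower-case input is upper-cased first.
#'
#' @param seqs character vector of DNA sequences, all the same length.
#' @return numeric array of dimension \code{c(N, L, 4)} with dimnames
#'   \code{list(NULL, NULL, c("A","C","G","T"))}.
#' @seealso [decode_onehot()]
#' @examples
#' x <- encode_onehot(c("ACGT", "TTGA"))
#' dim(x)
#' decode_onehot(x)
#' @export
encode_onehot <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1)
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("ragged sequence lengths: ", paste(unique(lens), collapse = ", "))
  }
  L <- lens[1]
  N <- length(seqs)
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = N, ncol = L, byrow = TRUE)
  idx <- match(chars, DNA_ALPHABET)
  if (anyNA(idx)) {
    bad <- which(is.na(idx), arr.ind = FALSE)[1]
    n <- ((bad - 1L) %% N) + 1L
    l <- ((bad - 1L) %/% N) + 1L
    stop(sprintf("invalid character '%s' in sequence %d at position %d",
                 chars[n, l], n, l))
  }
  m <- matrix(0, N * L, 4L)
  m[cbind(seq_len(N * L), as.vector(idx))] <- 1
  array(m, dim = c(N, L, 4L), dimnames = list(NULL, NULL, DNA_ALPHABET))
}

#' Decode a one-hot (or soft) batch back to sequences
#'
#' Inverse of [encode_onehot()]. For soft inputs (rows on the probability
#' simplex) the per-position argmax is taken, first index winning ties.
#'
#' @param x numeric array \code{N x L x 4}.
#' @return character vector of \code{N} sequences.
#' @export
decode_onehot <- function(x) {
  stopifnot(is.array(x), length(dim(x)) == 3L, dim(x)[3] == 4L)
  N <- dim(x)[1]; L <- dim(x)[2]
  m <- matrix(x, N * L, 4L)
  k <- max.col(m, ties.method = "first")
  chars <- matrix(DNA_ALPHABET[k], nrow = N, ncol = L)
  apply(chars, 1, paste0, collapse = "")
}

# internal: N x L integer matrix of category indices (1..4)
seq_to_index <- function(seqs) {
  x <- encode_onehot(seqs)
  N <- dim(x)[1]; L <- dim(x)[2]
  matrix(max.col(matrix(x, N * L, 4L)), N, L)
}
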