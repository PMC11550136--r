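#' Read fixed-alphabet DNA sequences from a FASTA file
#'
#' Thin wrapper around \code{Biostrings::readDNAStringSet} that enforces the
#' package's strict \{A,C,G,T\} alphabet: ambiguity codes (N, R, ...) are
#' rejected, not randomised, because all training corpora handled here are
#' unambiguous. Lower-case residues are upper-cased; record order and
#' headers are preserved.
#'
#' @param path path to a FASTA file.
#' @return named character vector of upper-case sequences (names = headers).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  freq <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs),
                                      letters = "ACGT", OR = 0)
  nonacgt <- nchar(seqs) - rowSums(freq)
  if (any(nonacgt > 0)) {
    i <- which(nonacgt > 0)[1]
    ch <- setdiff(unique(strsplit(seqs[i], "")[[1]]), DNA_ALPHABET)[1]
    stop(sprintf(
      "record %d ('%s') contains non-ACGT residue '%s'; ambiguity codes are rejected",
      i, names(seqs)[i], ch))
  }
  seqs
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs character vector of sequences; names, if present, become the
#'   FASTA headers (otherwise \code{seq_1 ... seq_N}).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), length(seqs) >= 1)
  nm <- names(seqs)
  if (is.null(nm)) nm <- sprintf("seq_%d", seq_along(seqs))
  set <- Biostrings::DNAStringSet(toupper(seqs))
  names(set) <- nm
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
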