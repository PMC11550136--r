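#' Default genomic background base composition
#'
#' Per-base background probabilities used for PSSM log-odds throughout the
#' package, in alphabet order A, C, G, T. Taken from the composition of the
#' E. coli promoter corpus this model family targets
#' (A 0.266, C 0.218, G 0.225, T 0.291).
#'
#' @return named numeric vector of length 4 summing to 1.
#' @export
default_background <- function() {
  c(A = 0.266, C = 0.218, G = 0.225, T = 0.291)
}

#' Construct a position matrix (PFM / probabilities / PSSM)
#'
#' A \code{position_matrix} holds a motif's count matrix (PFM, W x 4),
#' its pseudocount-smoothed probability matrix, and optionally a log-odds
#' matrix (PSSM) against a background composition.
#'
#' @param counts W x 4 nonnegative matrix of base counts (columns in
#'   alphabet order A, C, G, T; a matrix with those colnames in any order is
#'   re-ordered).
#' @param pseudocount value added to every cell before normalising rows
#'   (default 0.1).
#' @param name optional motif identifier.
#' @return object of class \code{position_matrix} with elements
#'   \code{counts}, \code{probs}, \code{width}, \code{pseudocount},
#'   \code{name}, and (after [build_pssm()]) \code{log_odds},
#'   \code{background}.
#' @export
position_matrix <- function(counts, pseudocount = 0.1, name = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L) stop("counts must have 4 columns (A,C,G,T)")
  if (!is.null(colnames(counts))) {
    if (!setequal(colnames(counts), DNA_ALPHABET)) {
      stop("count columns must be named A,C,G,T")
    }
    counts <- counts[, DNA_ALPHABET, drop = FALSE]
  } else {
    colnames(counts) <- DNA_ALPHABET
  }
  if (any(counts < 0)) stop("negative counts in PFM")
  sm <- counts + pseudocount
  probs <- sm / rowSums(sm)
  structure(list(counts = counts, probs = probs, width = nrow(counts),
                 pseudocount = pseudocount, name = name),
            class = "position_matrix")
}

#' @export
print.position_matrix <- function(x, ...) {
  cat(sprintf("position_matrix '%s': width %d, consensus %s%s\n",
              if (is.null(x$name)) "?" else x$name, x$width, consensus(x),
              if (is.null(x$log_odds)) "" else " (PSSM built)"))
  invisible(x)
}

#' Consensus sequence of a position matrix
#' @param pm a \code{position_matrix}.
#' @return character scalar, the column-wise argmax base string.
#' @export
consensus <- function(pm) {
  stopifnot(inherits(pm, "position_matrix"))
  paste0(DNA_ALPHABET[max.col(pm$probs, ties.method = "first")],
         collapse = "")
}

#' Parse a JASPAR-format PFM file
#'
#' Accepts the JASPAR text layout: an optional \code{>ID name} header
#' followed by four base rows, either \code{A [ 1 2 3 ]} (bracketed) or
#' \code{A 1 2 3}. Rows may appear in any order; all four of A, C, G, T
#' must be present with equal column counts.
#'
#' @param path path to a JASPAR PFM file.
#' @inheritParams position_matrix
#' @return a [position_matrix()].
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.1) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  name <- NULL
  if (length(lines) && startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    name <- strsplit(name, "\\s+")[[1]][1]
    lines <- lines[-1]
  }
  rows <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([ACGTacgt])\\s*\\[?([^]]*)\\]?\\s*$", ln))[[1]]
    if (length(m) == 0) stop("unparseable PFM line: '", ln, "'")
    base <- toupper(m[2])
    vals <- suppressWarnings(as.numeric(strsplit(trimws(m[3]), "\\s+")[[1]]))
    if (anyNA(vals) || length(vals) == 0) {
      stop("non-numeric counts on PFM line: '", ln, "'")
    }
    if (base %in% names(rows)) stop("duplicate base row '", base, "'")
    rows[[base]] <- vals
  }
  missing <- setdiff(DNA_ALPHABET, names(rows))
  if (length(missing)) {
    stop("missing base row(s): ", paste(missing, collapse = ", "))
  }
  lens <- vapply(rows, length, 1L)
  if (length(unique(lens)) != 1L) stop("unequal column counts across base rows")
  counts <- do.call(cbind, rows[DNA_ALPHABET])
  if (any(counts < 0)) stop("negative counts in PFM file ", path)
  position_matrix(counts, pseudocount = pseudocount, name = name)
}

#' Build the log-odds (PSSM) form of a position matrix
#'
#' Fills \code{log_odds[w, k] = log2(probs[w, k] / background[k])}, the
#' standard bits-scaled PSSM against a strictly positive background.
#'
#' @param pm a [position_matrix()].
#' @param background length-4 probability vector (A,C,G,T order); defaults
#'   to [default_background()].
#' @return the input \code{position_matrix} with \code{log_odds} and
#'   \code{background} filled.
#' @export
build_pssm <- function(pm, background = default_background()) {
  stopifnot(inherits(pm, "position_matrix"))
  background <- as.numeric(background)
  if (length(background) != 4L) stop("background must have 4 entries")
  if (any(background <= 0)) stop("background entries must be strictly positive")
  background <- background / sum(background)
  pm$background <- stats::setNames(background, DNA_ALPHABET)
  pm$log_odds <- sweep(log2(pm$probs), 2, log2(background), "-")
  pm
}

# internal: scores of every window of `seq` under a built PSSM.
# Returns numeric vector of length L - W + 1 (0-based window starts are
# seq_along(scores) - 1).
window_scores <- function(seq, pm) {
  if (is.null(pm$log_odds)) pm <- build_pssm(pm)
  W <- pm$width
  L <- nchar(seq)
  if (W > L) stop("motif width ", W, " exceeds sequence length ", L)
  idx <- match(strsplit(toupper(seq), "")[[1]], DNA_ALPHABET)
  if (anyNA(idx)) stop("non-ACGT character in sequence")
  nwin <- L - W + 1L
  sc <- numeric(nwin)
  for (w in seq_len(W)) {
    sc <- sc + pm$log_odds[cbind(w, idx[w:(w + nwin - 1L)])]
  }
  sc
}

#' Best PSSM hit in a sequence
#'
#' Scans the forward strand of \code{seq} with a log-odds matrix and
#' returns the best-scoring window; ties are broken leftmost. Windows
#' scoring below \code{threshold} are ignored (the permissive default of
#' -1000 bits never filters, so a hit is always reported: the convention
#' used to avoid false negatives in occurrence analyses).
#'
#' @param seq a DNA sequence (character scalar).
#' @param pm a [position_matrix()]; the PSSM is built on the fly with
#'   \code{background} if absent.
#' @param background background passed to [build_pssm()] when needed.
#' @param threshold minimum score for a window to count as a hit.
#' @return list with \code{start} (0-based), \code{end} (0-based,
#'   exclusive), \code{score}; or \code{NULL} if no window clears the
#'   threshold.
#' @export
scan_best_hit <- function(seq, pm, background = default_background(),
                          threshold = -1000) {
  if (is.null(pm$log_odds)) pm <- build_pssm(pm, background)
  sc <- window_scores(seq, pm)
  ok <- which(sc >= threshold)
  if (length(ok) == 0L) return(NULL)
  best <- ok[which.max(sc[ok])]
  list(start = best - 1L, end = best - 1L + pm$width, score = sc[best])
}

#' Greedy similarity filter on equal-length sequences
#'
#' Single order-stable pass keeping a sequence only if its Hamming distance
#' to every previously kept sequence is at least \code{min_mismatches}.
#' Used to guarantee a corpus is "unique in at least m of L bp".
#'
#' @param seqs character vector of equal-length sequences.
#' @param min_mismatches minimum pairwise Hamming distance to retain.
#' @return subset of \code{seqs}, original order preserved.
#' @export
similarity_filter <- function(seqs, min_mismatches) {
  stopifnot(length(seqs) >= 1, min_mismatches >= 0)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must have equal length")
  if (min_mismatches > L) {
    warning("min_mismatches exceeds sequence length; only the first sequence is kept")
  }
  idx <- seq_to_index(seqs)           # N x L integers
  keep <- 1L
  for (i in seq_along(seqs)[-1]) {
    d <- rowSums(idx[keep, , drop = FALSE] !=
                 matrix(idx[i, ], length(keep), L, byrow = TRUE))
    if (all(d >= min_mismatches)) keep <- c(keep, i)
  }
  seqs[keep]
}
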