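# Shared fixtures: built in code so the suite has no binary data.

fixture_pfm_paths <- function() {
  sort(list.files(system.file("extdata", package = "promdiff"),
                  pattern = "^synthetic_motif_.*\\.pfm$", full.names = TRUE))
}

fixture_motifs <- function(n = 6) {
  paths <- fixture_pfm_paths()
  lapply(paths[seq_len(n)], read_jaspar_pfm)
}

# a deterministic strong PFM from a consensus string (counts 20 vs 1)
consensus_pfm <- function(consensus, name = consensus, strength = 20) {
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  counts <- matrix(1, length(idx), 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  counts[cbind(seq_along(idx), idx)] <- strength
  position_matrix(counts, name = name)
}

random_acgt <- function(n, L, seed = NULL) {
  draw <- function() {
    apply(matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L),
          1, paste0, collapse = "")
  }
  if (is.null(seed)) draw() else promdiff:::with_seed(seed, draw())
}

# naive Levenshtein DP oracle, O(L^2)
naive_levenshtein <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  D <- matrix(0L, length(A) + 1L, length(B) + 1L)
  D[, 1] <- 0:length(A)
  D[1, ] <- 0:length(B)
  for (i in seq_along(A)) {
    for (j in seq_along(B)) {
      D[i + 1, j + 1] <- min(D[i, j + 1] + 1L, D[i + 1, j] + 1L,
                             D[i, j] + (A[i] != B[j]))
    }
  }
  D[length(A) + 1L, length(B) + 1L]
}

# naive overlapping k-mer counter
naive_kmer_counts <- function(seqs, k) {
  out <- new.env()
  for (s in seqs) {
    for (i in seq_len(nchar(s) - k + 1)) {
      km <- substr(s, i, i + k - 1)
      out[[km]] <- (if (is.null(out[[km]])) 0 else out[[km]]) + 1
    }
  }
  as.list(out)
}
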