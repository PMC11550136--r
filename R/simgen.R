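# Synthetic-data generators: the motif-pair decoupling corpus, PSSM and
# random controls, and a promoter-like labelled benchmark with planted
# -35/-10 boxes. All are seeded and reproducible; planted coordinates are
# 0-based half-open.

# internal: sample n sequences column-wise from a probability matrix
sample_from_probs <- function(probs, n) {
  W <- nrow(probs)
  ks <- vapply(seq_len(W), function(w) {
    sample.int(4L, n, replace = TRUE, prob = probs[w, ])
  }, integer(n))
  if (n == 1L) ks <- matrix(ks, 1L, W)
  apply(matrix(DNA_ALPHABET[ks], n, W), 1, paste0, collapse = "")
}

#' Sample a motif instance from its position frequency matrix
#'
#' Draws each position independently from the PFM's pseudocount-smoothed
#' column probabilities.
#'
#' @param pm a [position_matrix()].
#' @param n number of instances (default 1).
#' @param seed optional seed; when NULL the current RNG stream is used.
#' @return character vector of \code{n} strings of the motif width.
#' @export
sample_motif_instance <- function(pm, n = 1, seed = NULL) {
  stopifnot(inherits(pm, "position_matrix"))
  if (is.null(seed)) sample_from_probs(pm$probs, n)
  else with_seed(seed, sample_from_probs(pm$probs, n))
}

# internal: n uniform random ACGT sequences of length L
uniform_sequences <- function(n, L) {
  if (n == 0L) return(character(0))
  k <- sample.int(4L, n * L, replace = TRUE)
  apply(matrix(DNA_ALPHABET[k], n, L), 1, paste0, collapse = "")
}

#' Construct one planted motif-pair sequence
#'
#' Implements the pseudo-sequence design: sample instances X and Y from
#' the two PFMs, generate a random spacer G of \code{gap_length} bp,
#' generate a random template of \code{template_length} bp, and replace a
#' uniformly chosen equal-length region with X + G + Y.
#'
#' @param motif_x,motif_y [position_matrix()] objects.
#' @param gap_length spacer length between the motifs (default 13).
#' @param template_length total sequence length (default 50).
#' @param seed optional seed.
#' @return list with \code{sequence} and 0-based half-open coordinates
#'   \code{x_start}, \code{x_end}, \code{y_start}, \code{y_end}.
#' @export
make_pair_sequence <- function(motif_x, motif_y, gap_length = 13,
                               template_length = 50, seed = NULL) {
  run <- function() {
    wx <- motif_x$width
    wy <- motif_y$width
    ins <- wx + gap_length + wy
    if (ins > template_length) {
      stop(sprintf("insert %d bp exceeds template %d bp", ins, template_length))
    }
    X <- sample_from_probs(motif_x$probs, 1)
    Y <- sample_from_probs(motif_y$probs, 1)
    G <- uniform_sequences(1, gap_length)
    H <- uniform_sequences(1, template_length)
    off <- sample.int(template_length - ins + 1L, 1L) - 1L   # 0-based
    seq <- paste0(substr(H, 1, off), X, G, Y,
                  substr(H, off + ins + 1, template_length))
    list(sequence = seq,
         x_start = off, x_end = off + wx,
         y_start = off + wx + gap_length,
         y_end = off + wx + gap_length + wy)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Build the motif-pair decoupling corpus
#'
#' All ordered pairs (including self-pairs) of the supplied motifs -- six
#' motifs give 6 x 6 = 36 combinations -- each contributing
#' \code{per_pair} planted sequences via [make_pair_sequence()]. The
#' canonical corpus is 36 pairs x 1,000 = 36,000 sequences of 50 bp.
#'
#' @param motifs list of [position_matrix()] objects (canonically 6; a
#'   different count triggers a warning unless \code{strict = FALSE}).
#' @param per_pair sequences per ordered pair (default 1000).
#' @param gap_length,template_length see [make_pair_sequence()].
#' @param seed integer seed.
#' @param strict warn when the motif count differs from 6.
#' @return data.frame with columns \code{sequence}, \code{pair_id}
#'   (\code{"<i>_<j>"} using motif names or indices), \code{x_start},
#'   \code{x_end}, \code{y_start}, \code{y_end}.
#' @export
build_pair_dataset <- function(motifs, per_pair = 1000, gap_length = 13,
                               template_length = 50, seed = 0,
                               strict = TRUE) {
  stopifnot(is.list(motifs), length(motifs) >= 1)
  if (strict && length(motifs) != 6L) {
    warning("canonical corpus uses 6 motifs (36 ordered pairs); got ",
            length(motifs))
  }
  nm <- vapply(seq_along(motifs), function(i) {
    n <- motifs[[i]]$name
    if (is.null(n)) as.character(i) else n
  }, "")
  with_seed(seed, {
    out <- vector("list", length(motifs)^2)
    k <- 0L
    for (i in seq_along(motifs)) {
      for (j in seq_along(motifs)) {
        k <- k + 1L
        recs <- replicate(per_pair,
          make_pair_sequence(motifs[[i]], motifs[[j]], gap_length,
                             template_length), simplify = FALSE)
        out[[k]] <- data.frame(
          sequence = vapply(recs, `[[`, "", "sequence"),
          pair_id = paste0(nm[i], "_", nm[j]),
          x_start = vapply(recs, `[[`, 0, "x_start"),
          x_end = vapply(recs, `[[`, 0, "x_end"),
          y_start = vapply(recs, `[[`, 0, "y_start"),
          y_end = vapply(recs, `[[`, 0, "y_end"))
      }
    }
    do.call(rbind, out)
  })
}

#' Sample a PSSM control set
#'
#' Position-independent sampling from a width-L probability matrix (the
#' per-column composition of a natural corpus), the classical control for
#' generative models: it preserves positional base frequencies but no
#' higher-order structure.
#'
#' @param pm a [position_matrix()] whose width equals the target length.
#' @param n number of sequences.
#' @param seed integer seed.
#' @return character vector of \code{n} sequences.
#' @export
sample_pssm_control <- function(pm, n, seed = 0) {
  stopifnot(inherits(pm, "position_matrix"), n >= 0)
  if (n == 0L) return(character(0))
  with_seed(seed, sample_from_probs(pm$probs, n))
}

#' Generate i.i.d. random sequences with controlled GC content
#'
#' @param n number of sequences.
#' @param L sequence length.
#' @param gc total probability of G or C per position (split equally;
#'   A/T share the remainder equally). Default 0.5.
#' @param seed integer seed.
#' @return character vector of \code{n} sequences.
#' @export
random_sequences <- function(n, L, gc = 0.5, seed = 0) {
  stopifnot(gc >= 0, gc <= 1, n >= 0, L >= 1)
  if (n == 0L) return(character(0))
  pr <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)   # A C G T
  with_seed(seed, {
    k <- sample.int(4L, n * L, replace = TRUE, prob = pr)
    apply(matrix(DNA_ALPHABET[k], n, L), 1, paste0, collapse = "")
  })
}

#' PFMs of the canonical -35 and -10 promoter boxes
#'
#' Synthetic count matrices built from the sigma-70 consensus elements
#' TTGACA (-35) and TATAAT (-10): the consensus base carries most of the
#' mass with the remainder spread uniformly. These stand in for
#' experimentally derived box PFMs in simulations and scanning.
#'
#' @param strength count assigned to the consensus base per column; the
#'   three alternatives share 3 counts (default 17, i.e. 85\% consensus).
#' @return list with \code{minus35} and \code{minus10}
#'   [position_matrix()] objects.
#' @export
promoter_box_pfms <- function(strength = 17) {
  mk <- function(consensus, name) {
    idx <- match(strsplit(consensus, "")[[1]], DNA_ALPHABET)
    counts <- matrix(1, length(idx), 4, dimnames = list(NULL, DNA_ALPHABET))
    counts[cbind(seq_along(idx), idx)] <- strength
    position_matrix(counts, name = name)
  }
  list(minus35 = mk("TTGACA", "box35"), minus10 = mk("TATAAT", "box10"))
}

#' Synthetic promoter benchmark with noisy expression labels
#'
#' Generates a promoter-like labelled corpus standing in for experimental
#' 50-bp sigma-70 promoter datasets, so that predictor and end-to-end
#' pipelines are testable without external data. Each sequence carries a
#' -35 box and a -10 box sampled from [promoter_box_pfms()], separated by
#' a spacer of round(N(17, 1)) bp clipped to [15, 19]; the -10 box ends 7
#' bp before the 3' end (the transcription-start side). The expression
#' label is the sum of the two planted instances' PSSM log-odds scores
#' plus Gaussian noise with \code{noise_sd} times the signal's standard
#' deviation.
#'
#' This generator emulates motif-strength-driven expression only; it has
#' none of the UP-element, discriminator or context effects of real
#' promoters.
#'
#' @param n number of sequences (>= 1).
#' @param L sequence length (default 50).
#' @param noise_sd label noise as a fraction of the signal SD
#'   (default 0.2).
#' @param seed integer seed.
#' @param box_strength passed to [promoter_box_pfms()].
#' @return list with \code{sequences}, \code{expression}, and
#'   \code{truth} (data.frame: spacer, box35_start, box10_start, and the
#'   noiseless \code{signal}), plus the generating \code{pfms}.
#' @export
synth_promoter_benchmark <- function(n, L = 50, noise_sd = 0.2, seed = 0,
                                     box_strength = 17) {
  stopifnot(n >= 1, L >= 40)
  pfms <- promoter_box_pfms(box_strength)
  p35 <- build_pssm(pfms$minus35)
  p10 <- build_pssm(pfms$minus10)
  with_seed(seed, {
    spacer <- pmin(pmax(round(stats::rnorm(n, 17, 1)), 15), 19)
    b35 <- sample_from_probs(p35$probs, n)
    b10 <- sample_from_probs(p10$probs, n)
    right <- 7L                       # bases 3' of the -10 box
    b10_start <- L - right - 6L       # 0-based
    b35_start <- b10_start - spacer - 6L
    seqs <- character(n)
    for (i in seq_len(n)) {
      pad_left <- uniform_sequences(1, b35_start[i])
      gap <- uniform_sequences(1, spacer[i])
      tail <- uniform_sequences(1, right)
      seqs[i] <- paste0(pad_left, b35[i], gap, b10[i], tail)
    }
    score_inst <- function(inst, pm) {
      idx <- seq_to_index(inst)
      vapply(seq_along(inst), function(i) {
        sum(pm$log_odds[cbind(seq_len(pm$width), idx[i, ])])
      }, 0)
    }
    signal <- score_inst(b35, p35) + score_inst(b10, p10)
    expr <- signal + stats::rnorm(n, 0, noise_sd * stats::sd(signal))
    list(sequences = seqs, expression = expr,
         truth = data.frame(spacer = spacer, box35_start = b35_start,
                            box10_start = b10_start, signal = signal),
         pfms = pfms)
  })
}
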