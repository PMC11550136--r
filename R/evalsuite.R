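# Evaluation statistics for generated sequence sets: GC-content JS
# divergence, k-mer frequency correlation, PSSM scanning and inter-motif
# spacing, edit-distance diversity, poly-A/T screening, per-epoch
# robustness tracking, and the cross-entropy decoupling score for
# motif-pair grammars.

#' GC content of sequences
#'
#' @param seqs character vector of DNA sequences.
#' @return numeric vector: (#G + #C) / length per sequence.
#' @export
gc_content <- function(seqs) {
  stopifnot(is.character(seqs), all(nchar(seqs) > 0))
  seqs <- toupper(seqs)
  (nchar(seqs) - nchar(gsub("[GC]", "", seqs))) / nchar(seqs)
}

#' Jensen-Shannon divergence between two probability vectors
#'
#' \eqn{JS(P,Q) = \frac12 KL(P\|M) + \frac12 KL(Q\|M)} with
#' \eqn{M = (P+Q)/2}. Reported in bits by default (\code{base = 2});
#' \code{base = exp(1)} gives nats. Bounded by \eqn{\log_base 2}
#' (1 bit) for disjoint supports.
#'
#' @param p,q nonnegative vectors of equal length (normalised
#'   internally).
#' @param base logarithm base (default 2).
#' @return scalar divergence.
#' @export
js_divergence <- function(p, q, base = 2) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * (log(a[i], base) - log(b[i], base)))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Averaged JS divergence of GC-content distributions
#'
#' Compares the GC-content distribution of a generated set against a
#' reference set. For each of \code{n_seeds} replications, both GC lists
#' are randomly subsampled to the smaller of the two sizes, histogrammed
#' on a shared grid of \code{bins} equal bins over [0, 1] with an epsilon
#' floor, and their JS divergence computed; the mean over replications is
#' returned.
#'
#' @param gen,nat character vectors of sequences.
#' @param n_seeds number of subsampling replications (default 3).
#' @param bins histogram bins over [0, 1] (default 50).
#' @param base logarithm base (default 2, bits).
#' @param eps smoothing floor added to every bin (default 1e-9).
#' @param seed integer seed for the subsampling.
#' @return mean JS divergence across replications.
#' @export
gc_js_divergence <- function(gen, nat, n_seeds = 3, bins = 50, base = 2,
                             eps = 1e-9, seed = 0) {
  stopifnot(length(gen) >= 1, length(nat) >= 1)
  P <- gc_content(gen)
  Q <- gc_content(nat)
  n <- min(length(P), length(Q))
  brk <- seq(0, 1, length.out = bins + 1)
  histo <- function(x) {
    h <- tabulate(pmin(pmax(findInterval(x, brk, rightmost.closed = TRUE),
                            1L), bins), bins)
    h <- h / sum(h) + eps
    h / sum(h)
  }
  with_seed(seed, {
    mean(vapply(seq_len(n_seeds), function(i) {
      js_divergence(histo(sample(P, n)), histo(sample(Q, n)), base = base)
    }, 0))
  })
}

#' Pearson correlation of k-mer frequency spectra
#'
#' Counts every overlapping k-mer in each set, normalises the two
#' count vectors (length \eqn{4^k}) to frequencies, and returns their
#' Pearson correlation.
#'
#' @param gen,nat character vectors of sequences (each of length >= k).
#' @param k k-mer size (default 6).
#' @return scalar Pearson r.
#' @export
kmer_pearson <- function(gen, nat, k = 6) {
  if (k > min(nchar(c(gen, nat)))) {
    stop("k exceeds the shortest sequence length")
  }
  freq <- function(seqs) {
    cnt <- colSums(Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(toupper(seqs)), width = k))
    cnt / sum(cnt)
  }
  pearson(freq(gen), freq(nat))
}

# internal: Gaussian KDE evaluated on a grid, scipy-style bandwidth
# (kernel sd = cov_factor * sd(x)), renormalised to sum 1 on the grid
kde_on_grid <- function(x, grid, cov_factor = 0.5) {
  bw <- cov_factor * stats::sd(x)
  if (!is.finite(bw) || bw < 1e-8) bw <- 1e-2   # degenerate: near point mass
  d <- rowSums(matrix(vapply(x, function(xi) stats::dnorm(grid, xi, bw),
                             numeric(length(grid))),
                      nrow = length(grid))) / length(x)
  if (sum(d) == 0) d <- rep(1, length(grid))
  d / sum(d)
}

#' Inter-motif distances between the -35 and -10 boxes
#'
#' For each sequence, finds the best-scoring hit of each box PSSM on the
#' forward strand (threshold -1000: a hit is always called) and records
#' the spacer \code{start(-10) - end(-35)} in 0-based half-open
#' coordinates. Negative values (overlapping or inverted hits) are
#' retained. A Gaussian KDE with covariance factor \code{kde_cov} is
#' evaluated on the integer grid spanning the observed distances.
#'
#' @param seqs character vector of sequences.
#' @param pssm35,pssm10 [position_matrix()] objects for the two boxes
#'   (PSSMs built on the fly against \code{background} if needed).
#' @param kde_cov KDE covariance factor (default 0.5).
#' @param background background for [build_pssm()].
#' @return list with \code{distances} (integer vector), \code{grid},
#'   \code{density} (sums to 1 on the grid), and \code{mode} (grid value
#'   of maximal density).
#' @export
inter_motif_distances <- function(seqs, pssm35, pssm10, kde_cov = 0.5,
                                  background = default_background()) {
  if (is.null(pssm35$log_odds)) pssm35 <- build_pssm(pssm35, background)
  if (is.null(pssm10$log_odds)) pssm10 <- build_pssm(pssm10, background)
  d <- vapply(seqs, function(s) {
    h35 <- scan_best_hit(s, pssm35)
    h10 <- scan_best_hit(s, pssm10)
    h10$start - h35$end
  }, 0, USE.NAMES = FALSE)
  grid <- seq(min(d), max(d))
  dens <- kde_on_grid(d, grid, kde_cov)
  list(distances = d, grid = grid, density = dens,
       mode = grid[which.max(dens)])
}

#' Average minimum intra-sample edit distance (diversity)
#'
#' For each sequence, the minimum Levenshtein distance to any other
#' sequence in the set; the mean of these minima measures sampling
#' diversity (0 when any duplicate pair exists everywhere, large when
#' samples are mutually distant).
#'
#' @param seqs character vector (>= 2 sequences).
#' @param subsample optional cap: when set and smaller than
#'   \code{length(seqs)}, a random subset of this size is scored.
#' @param seed seed used only when subsampling.
#' @return scalar mean of per-sequence minimum edit distances.
#' @export
min_edit_diversity <- function(seqs, subsample = NULL, seed = 0) {
  if (length(seqs) < 2) stop("need at least 2 sequences")
  if (!is.null(subsample) && subsample < length(seqs)) {
    seqs <- with_seed(seed, sample(seqs, subsample))
  }
  D <- utils::adist(seqs)
  diag(D) <- NA_integer_
  mean(apply(D, 1, min, na.rm = TRUE))
}

#' Fraction of sequences containing a poly-A or poly-T run
#'
#' Flags sequences carrying four or more consecutive identical A's or
#' T's (synthesis-risk homopolymers). The alternative reading -- four or
#' more consecutive bases each of which is A or T, e.g. "ATAT" -- is
#' available via \code{mode = "mixed"}.
#'
#' @param seqs character vector of sequences.
#' @param min_run run length that triggers the flag (default 4).
#' @param mode \code{"homopolymer"} (default) or \code{"mixed"}.
#' @return fraction of flagged sequences in [0, 1].
#' @export
polyAT_fraction <- function(seqs, min_run = 4, mode = c("homopolymer", "mixed")) {
  mode <- match.arg(mode)
  stopifnot(length(seqs) >= 1)
  seqs <- toupper(seqs)
  pat <- if (mode == "homopolymer") {
    sprintf("A{%d,}|T{%d,}", min_run, min_run)
  } else {
    sprintf("[AT]{%d,}", min_run)
  }
  mean(grepl(pat, seqs))
}

#' Gap distribution between a planted motif pair
#'
#' For each sequence, the best hit of motif X is located on the forward
#' strand; motif Y is then scanned over windows starting at or after the
#' X hit's end (the planted-order convention, which keeps self-pairs
#' x == y well defined), and the gap \code{start(Y) - end(X)} recorded.
#' With \code{y_scan = "global"}, Y is scanned over the whole sequence
#' and sequences with negative gaps are discarded instead. The gap
#' histogram is smoothed by a Gaussian KDE (covariance factor
#' \code{kde_cov}) evaluated on the integer grid 0..L and renormalised.
#'
#' @param seqs character vector of equal-length sequences.
#' @param pfm_x,pfm_y [position_matrix()] objects.
#' @param kde_cov KDE covariance factor (default 0.5).
#' @param y_scan \code{"downstream"} (default) or \code{"global"}.
#' @param background background for [build_pssm()].
#' @return object of class \code{gap_distribution}: list with
#'   \code{support} (0..L), \code{density} (sums to 1), \code{gaps},
#'   \code{mode}, \code{n_used}, \code{n_total}.
#' @export
gap_distribution <- function(seqs, pfm_x, pfm_y, kde_cov = 0.5,
                             y_scan = c("downstream", "global"),
                             background = default_background()) {
  y_scan <- match.arg(y_scan)
  if (is.null(pfm_x$log_odds)) pfm_x <- build_pssm(pfm_x, background)
  if (is.null(pfm_y$log_odds)) pfm_y <- build_pssm(pfm_y, background)
  L <- max(nchar(seqs))
  gaps <- integer(0)
  for (s in seqs) {
    scx <- window_scores(s, pfm_x)
    xs <- which.max(scx)                     # leftmost best, 1-based
    x_end <- xs - 1L + pfm_x$width           # 0-based exclusive
    scy <- window_scores(s, pfm_y)
    if (y_scan == "downstream") {
      from <- x_end + 1L                     # 1-based window index
      if (from > length(scy)) next
      ys <- from - 1L + which.max(scy[from:length(scy)])
    } else {
      ys <- which.max(scy)
    }
    g <- (ys - 1L) - x_end
    if (g >= 0L) gaps <- c(gaps, g)
  }
  support <- 0:L
  dens <- if (length(gaps) == 0) rep(1 / (L + 1), L + 1)
          else kde_on_grid(gaps, support, kde_cov)
  structure(list(support = support, density = dens, gaps = gaps,
                 mode = support[which.max(dens)],
                 n_used = length(gaps), n_total = length(seqs)),
            class = "gap_distribution")
}

#' @export
print.gap_distribution <- function(x, ...) {
  cat(sprintf("gap_distribution: %d/%d sequences, mode %d bp\n",
              x$n_used, x$n_total, x$mode))
  invisible(x)
}

#' @export
plot.gap_distribution <- function(x, ...) {
  graphics::plot(x$support, x$density, type = "h", xlab = "gap (bp)",
                 ylab = "density", ...)
  invisible(x)
}

#' Decoupling score between two gap distributions
#'
#' \eqn{val = -\log_2 H(dist_{gen}, dist_{ori})} where
#' \eqn{H(p, q) = -\sum_g p(g) \ln q(g)} is the cross-entropy (natural
#' log inside, base-2 log outside) of the generated distribution against
#' the original, epsilon-smoothed. Larger values mean the generated
#' sequences concentrate their gaps where the original grammar does.
#'
#' @param dist_gen,dist_ori [gap_distribution()] objects (or lists with
#'   \code{support} and \code{density}).
#' @param eps smoothing floor (default 1e-9).
#' @return scalar score.
#' @export
decoupling_val <- function(dist_gen, dist_ori, eps = 1e-9) {
  support <- sort(unique(c(dist_gen$support, dist_ori$support)))
  align <- function(d) {
    v <- numeric(length(support))
    v[match(d$support, support)] <- d$density
    (v + eps) / sum(v + eps)
  }
  p <- align(dist_gen)
  q <- align(dist_ori)
  H <- -sum(p * log(q))
  if (H <= 0) stop("cross-entropy must be positive")
  -log2(H)
}

#' Decoupling heatmap over all motif pairs
#'
#' For every ordered motif pair (x, y), computes the [gap_distribution()]
#' of the generated set and of the original corpus slice carrying that
#' pair id, and their [decoupling_val()]. Entries with an empty original
#' slice are NA.
#'
#' @param gen_seqs character vector of model-generated sequences.
#' @param ori data.frame from [build_pair_dataset()] (columns
#'   \code{sequence}, \code{pair_id}).
#' @param motifs named list of [position_matrix()] objects in the order
#'   used to build \code{ori}.
#' @param ... passed to [gap_distribution()].
#' @return P x P numeric matrix of scores (rows = motif x, cols = motif
#'   y) with attribute \code{color_clip = c(5.5, 18)}, the conventional
#'   rendering range (values themselves are not clipped).
#' @export
decoupling_heatmap <- function(gen_seqs, ori, motifs, ...) {
  nm <- vapply(seq_along(motifs), function(i) {
    n <- motifs[[i]]$name
    if (is.null(n)) as.character(i) else n
  }, "")
  P <- length(motifs)
  M <- matrix(NA_real_, P, P, dimnames = list(nm, nm))
  for (i in seq_len(P)) {
    for (j in seq_len(P)) {
      pid <- paste0(nm[i], "_", nm[j])
      slice <- ori$sequence[ori$pair_id == pid]
      if (length(slice) == 0) {
        warning("no original sequences for pair ", pid)
        next
      }
      dg <- gap_distribution(gen_seqs, motifs[[i]], motifs[[j]], ...)
      do <- gap_distribution(slice, motifs[[i]], motifs[[j]], ...)
      M[i, j] <- decoupling_val(dg, do)
    }
  }
  attr(M, "color_clip") <- c(5.5, 18)
  M
}

#' Track generation robustness across training epochs
#'
#' Given per-epoch sample sets from a generator, computes the diversity
#' ([min_edit_diversity()]), mean GC content and [polyAT_fraction()] of
#' each epoch's set, plus absolute differences between adjacent epochs
#' (stability: a robust generator shows small deltas).
#'
#' @param per_epoch_samples list (>= 2 elements) of character vectors.
#' @param subsample optional diversity subsampling cap per epoch.
#' @return data.frame with one row per epoch: \code{epoch},
#'   \code{diversity}, \code{mean_gc}, \code{polyat}, and
#'   \code{d_diversity}, \code{d_gc}, \code{d_polyat} (NA in row 1).
#' @export
robustness_track <- function(per_epoch_samples, subsample = NULL) {
  stopifnot(is.list(per_epoch_samples), length(per_epoch_samples) >= 2)
  n <- length(per_epoch_samples)
  df <- data.frame(
    epoch = seq_len(n),
    diversity = vapply(per_epoch_samples, min_edit_diversity, 0,
                       subsample = subsample),
    mean_gc = vapply(per_epoch_samples, function(s) mean(gc_content(s)), 0),
    polyat = vapply(per_epoch_samples, polyAT_fraction, 0))
  df$d_diversity <- c(NA, abs(diff(df$diversity)))
  df$d_gc <- c(NA, abs(diff(df$mean_gc)))
  df$d_polyat <- c(NA, abs(diff(df$polyat)))
  df
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided signed-rank test between paired metric lists (e.g. per-seed
#' diversity of two generators).
#'
#' @param a,b numeric vectors of equal length (paired).
#' @return two-sided p-value.
#' @export
wilcoxon_compare <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (all(a == b)) stop("all paired differences are zero; test undefined")
  stats::wilcox.test(a, b, paired = TRUE)$p.value
}
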