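test_that("GC content and JS divergence hit their analytic fixed points", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("AAAA"), 0)
  expect_equal(gc_content("GGGCCC"), 1)

  # hand-computed two-bin example: 0.27807 bits (= 0.192745 nats)
  expect_equal(js_divergence(c(0.8, 0.2), c(0.2, 0.8)), 0.2780719,
               tolerance = 1e-6)
  expect_equal(js_divergence(c(0.8, 0.2), c(0.2, 0.8), base = exp(1)),
               0.1927448, tolerance = 1e-6)
  # identical distributions -> 0; disjoint -> saturates at 1 bit (ln 2 nats)
  expect_equal(js_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(js_divergence(c(1, 0), c(0, 1)), 1)

  set.seed(1)
  seqs <- random_acgt(300, 50)
  expect_lt(gc_js_divergence(seqs, seqs, seed = 2), 1e-6)
  gcj <- gc_js_divergence(random_sequences(300, 50, gc = 1, seed = 3),
                          random_sequences(300, 50, gc = 0, seed = 4),
                          seed = 5)
  expect_equal(gcj, 1, tolerance = 1e-4)   # disjoint GC histograms
})

test_that("k-mer spectra match a naive counting oracle", {
  set.seed(2)
  seqs <- random_acgt(10, 50)
  expect_equal(kmer_pearson(seqs, seqs, k = 6), 1)

  # oracle agreement at k = 3 on the raw counts
  k <- 3
  cnt <- colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = k))
  oracle <- naive_kmer_counts(seqs, k)
  for (km in names(oracle)) {
    expect_equal(unname(cnt[km]), oracle[[km]])
  }
  expect_equal(sum(cnt), sum(unlist(oracle)))

  # disjoint homopolymer spectra anti-correlate
  expect_lt(kmer_pearson(rep(strrep("A", 20), 5), rep(strrep("T", 20), 5)), 0)
  expect_error(kmer_pearson("ACG", "ACG", k = 6), "exceeds")
})

test_that("PSSM scanning agrees with exhaustive window scoring", {
  pm <- build_pssm(consensus_pfm("TTGACA"))
  set.seed(3)
  hits <- 0
  for (i in 1:300) {
    flank <- random_acgt(2, 22)
    s <- paste0(flank[1], "TTGACA", flank[2])
    h <- scan_best_hit(s, pm)
    # exhaustive oracle
    sc <- vapply(1:(nchar(s) - 5), function(j) {
      idx <- match(strsplit(substr(s, j, j + 5), "")[[1]], c("A", "C", "G", "T"))
      sum(pm$log_odds[cbind(1:6, idx)])
    }, 0)
    expect_equal(h$score, max(sc))
    expect_equal(h$start, which.max(sc) - 1L)   # leftmost tie-break
    if (h$start == 22) hits <- hits + 1
  }
  expect_gte(hits / 300, 0.99)   # planted consensus recovered

  # threshold filters: an impossible threshold yields no hit
  expect_null(scan_best_hit("ACGTACGTACGT", pm, threshold = 1e6))
})

test_that("edit-distance diversity matches the DP oracle and worked triple", {
  expect_equal(min_edit_diversity(c("AAAA", "AAAT", "TTTT")), 5 / 3)
  expect_equal(min_edit_diversity(rep("ACGT", 4)), 0)
  expect_error(min_edit_diversity("ACGT"), "at least 2")

  set.seed(4)
  for (i in 1:50) {
    a <- random_acgt(1, sample(5:12, 1))
    b <- random_acgt(1, sample(5:12, 1))
    expect_equal(unname(utils::adist(a, b)[1, 1]), naive_levenshtein(a, b))
  }
})

test_that("poly-A/T screening distinguishes homopolymer and mixed readings", {
  expect_equal(polyAT_fraction("AAAAGG"), 1)
  expect_equal(polyAT_fraction("ATATATAT"), 0)                 # homopolymer
  expect_equal(polyAT_fraction("ATATATAT", mode = "mixed"), 1)
  expect_equal(polyAT_fraction("GCGCGC"), 0)
  expect_equal(polyAT_fraction(c("AAAA", "GGGG", "TTTTT", "ACGT")), 0.5)
})

test_that("gap distributions recover planted spacers and normalise", {
  m1 <- consensus_pfm("TGACTC")
  m2 <- consensus_pfm("CACGTG")
  ds <- build_pair_dataset(list(m1, m2), per_pair = 150, seed = 7,
                           strict = FALSE)
  for (pid in unique(ds$pair_id)) {
    ij <- match(strsplit(pid, "_")[[1]], c("TGACTC", "CACGTG"))
    gd <- gap_distribution(ds$sequence[ds$pair_id == pid],
                           list(m1, m2)[[ij[1]]], list(m1, m2)[[ij[2]]])
    expect_equal(sum(gd$density), 1, tolerance = 1e-9)
    expect_true(abs(gd$mode - 13) <= 1)
  }

  # single sequence: density is point-mass-like at its gap
  one <- make_pair_sequence(m1, m2, seed = 9)
  gd1 <- gap_distribution(one$sequence, m1, m2)
  expect_equal(gd1$mode, 13L)
  expect_gt(max(gd1$density), 0.99)
})

test_that("decoupling score matches its closed form and orders sanely", {
  unif3 <- structure(list(support = 12:14, density = rep(1 / 3, 3)),
                     class = "gap_distribution")
  expect_equal(decoupling_val(unif3, unif3), -log2(log(3)),
               tolerance = 1e-6)   # = -0.13566...

  peak <- function(center, spread) {
    d <- stats::dnorm(0:50, center, spread)
    structure(list(support = 0:50, density = d / sum(d)),
              class = "gap_distribution")
  }
  sharp <- peak(13, 0.6)
  # identical sharp distributions beat mismatched ones
  expect_gt(decoupling_val(sharp, sharp), decoupling_val(peak(30, 0.6), sharp))
  # val rises as dist_gen concentrates on the reference mode
  vals <- vapply(c(8, 4, 2, 1), function(sp) decoupling_val(peak(13, sp), sharp), 0)
  expect_true(all(diff(vals) > 0))
})

test_that("decoupling heatmap covers all ordered pairs", {
  m1 <- consensus_pfm("TGACTC", name = "m1")
  m2 <- consensus_pfm("CACGTG", name = "m2")
  ds <- build_pair_dataset(list(m1, m2), per_pair = 60, seed = 12,
                           strict = FALSE)
  # self-comparison: generated := original; all cells finite
  M <- decoupling_heatmap(ds$sequence, ds, list(m1, m2))
  expect_equal(dim(M), c(2L, 2L))
  expect_true(all(is.finite(M)))
  expect_equal(attr(M, "color_clip"), c(5.5, 18))
  expect_warning(
    decoupling_heatmap(ds$sequence, ds[ds$pair_id != "m1_m2", ],
                       list(m1, m2)),
    "no original sequences")
})

test_that("robustness tracking reports per-epoch metrics and deltas", {
  set.seed(13)
  fixed <- random_acgt(30, 20)
  rt <- robustness_track(list(fixed, fixed, fixed))
  expect_equal(nrow(rt), 3L)
  expect_true(all(rt$d_diversity[-1] == 0))
  expect_true(all(rt$d_gc[-1] == 0))

  # collapsing generator: diversity decreases monotonically
  collapse <- list(random_acgt(30, 20),
                   c(rep("AAAAAAAAAAAAAAAAAAAA", 15), random_acgt(15, 20)),
                   rep("AAAAAAAAAAAAAAAAAAAA", 30))
  rt2 <- robustness_track(collapse)
  expect_true(all(diff(rt2$diversity) < 0))
  expect_error(robustness_track(list(fixed)), ">= 2")
})

test_that("paired Wilcoxon test gives exact small-sample p-values", {
  b <- c(1.2, 3.4, 0.5, 2.2, 5.1, 0.3, 2.8, 1.9, 4.4, 3.3)
  # distinct all-positive differences: the all-plus sign assignment is the
  # most extreme of the 2^10, so the exact two-sided p is 2/2^10
  shift <- seq(0.5, 5, by = 0.5)
  expect_equal(wilcoxon_compare(b + shift, b), 2 / 2^10, tolerance = 1e-12)
  expect_error(wilcoxon_compare(b, b), "zero")
  expect_error(wilcoxon_compare(1:3, 1:4), "equal length")
  set.seed(14)
  p <- wilcoxon_compare(rnorm(100), rnorm(100))
  expect_gt(p, 1e-4)   # symmetric noise rarely gives extreme p
})

test_that("inter-motif distance analysis retains sign and normalises", {
  boxes <- promoter_box_pfms()
  # abutting planted motifs -> distance 0
  set.seed(15)
  seqs0 <- vapply(1:20, function(i) {
    paste0(random_acgt(1, 20), "TTGACA", "TATAAT", random_acgt(1, 18))
  }, "")
  d0 <- inter_motif_distances(seqs0, boxes$minus35, boxes$minus10)
  expect_true(all(d0$distances == 0))
  expect_equal(sum(d0$density), 1, tolerance = 1e-9)

  # reversed order yields negative distances, retained
  seqs_neg <- vapply(1:10, function(i) {
    paste0(random_acgt(1, 15), "TATAAT", random_acgt(1, 5), "TTGACA",
           random_acgt(1, 14))
  }, "")
  dn <- inter_motif_distances(seqs_neg, boxes$minus35, boxes$minus10)
  expect_true(all(dn$distances < 0))
})
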