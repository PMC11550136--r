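test_that("one-hot encoding round-trips and has simplex rows", {
  x <- encode_onehot("ACGT")
  expect_equal(dim(x), c(1L, 4L, 4L))
  expect_equal(matrix(x[1, , ], 4, 4), diag(4))   # one symbol per category
  expect_equal(decode_onehot(encode_onehot("TATAAT")), "TATAAT")

  set.seed(7)
  seqs <- random_acgt(3, 50)
  b <- encode_onehot(seqs)
  expect_equal(dim(b), c(3L, 50L, 4L))
  expect_true(all(abs(apply(b, c(1, 2), sum) - 1) < 1e-12))
  expect_equal(decode_onehot(b), seqs)

  # property: random round trips at several lengths
  for (L in c(1, 7, 33)) {
    s <- random_acgt(5, L)
    expect_equal(decode_onehot(encode_onehot(s)), s)
  }
})

test_that("encoding rejects bad input with informative errors", {
  expect_error(encode_onehot(c("ACGT", "ACG")), "ragged")
  expect_error(encode_onehot("ACNT"), "invalid character 'N'.*position 3")
  expect_error(encode_onehot("acgu"), "invalid character")
  expect_equal(decode_onehot(encode_onehot("acgt")), "ACGT")  # case folding
})

test_that("FASTA I/O preserves order, headers and rejects ambiguity codes", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">p1 first", "ACGTACGT", ">p2 second", "ttgacatt"), f)
  s <- read_fasta(f)
  expect_equal(unname(s), c("ACGTACGT", "TTGACATT"))
  expect_equal(names(s), c("p1 first", "p2 second"))

  f2 <- tempfile(fileext = ".fa")
  write_fasta(s, f2)
  expect_equal(read_fasta(f2), s)

  f3 <- tempfile(fileext = ".fa")
  writeLines(c(">ok", "ACGT", ">bad", "ACNT"), f3)
  expect_error(read_fasta(f3), "record 2.*'N'")

  f4 <- tempfile(fileext = ".fa")
  writeLines(character(0), f4)
  expect_error(read_fasta(f4), "empty")
})

test_that("JASPAR PFM parsing handles counts, pseudocounts and errors", {
  f <- tempfile(fileext = ".pfm")
  writeLines(c(">M1 test",
               "A [ 1 8 0 1 1 1 ]",
               "C [ 1 0 0 1 1 1 ]",
               "G [ 1 0 8 1 1 1 ]",
               "T [ 1 0 0 1 1 1 ]"), f)
  pm <- read_jaspar_pfm(f)
  expect_s3_class(pm, "position_matrix")
  expect_equal(pm$width, 6L)
  expect_equal(pm$name, "M1")
  # uniform column -> 0.25 each
  expect_equal(unname(pm$probs[1, ]), rep(0.25, 4))
  # column (8,0,0,0) with pseudocount 0.1 -> P(A) = 8.1/8.4
  expect_equal(unname(pm$probs[2, "A"]), 8.1 / 8.4)
  expect_true(all(abs(rowSums(pm$probs) - 1) < 1e-12))

  f2 <- tempfile(fileext = ".pfm")
  writeLines(c("A [ 1 2 ]", "C [ 1 2 ]", "G [ 1 2 ]"), f2)
  expect_error(read_jaspar_pfm(f2), "missing base row")
  f3 <- tempfile(fileext = ".pfm")
  writeLines(c("A [ 1 -2 ]", "C [ 1 2 ]", "G [ 1 2 ]", "T [ 0 1 ]"), f3)
  expect_error(read_jaspar_pfm(f3), "negative")
})

test_that("PSSM log-odds are bits against background; consensus is maximal", {
  # probabilities equal to background -> all log-odds zero
  bg <- c(0.25, 0.25, 0.25, 0.25)
  counts <- matrix(1, 3, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  pm <- build_pssm(position_matrix(counts, pseudocount = 0), background = bg)
  expect_true(all(abs(pm$log_odds) < 1e-12))

  # P(A) = 0.5 vs background 0.25 -> exactly 1 bit
  counts2 <- matrix(c(2, 2 / 3, 2 / 3, 2 / 3), 1, 4,
                    dimnames = list(NULL, c("A", "C", "G", "T")))
  pm2 <- build_pssm(position_matrix(counts2, pseudocount = 0), background = bg)
  expect_equal(unname(pm2$log_odds[1, "A"]), 1)

  expect_error(build_pssm(position_matrix(counts), background = c(0, .5, .25, .25)),
               "strictly positive")

  # consensus maximality by brute force over all 4^W strings, W = 4
  pm3 <- build_pssm(fixture_motifs(1)[[1]])
  pm4 <- build_pssm(position_matrix(pm3$counts[1:4, ]))
  all4 <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), 4))
  strs <- apply(all4, 1, paste0, collapse = "")
  scores <- vapply(strs, function(s) scan_best_hit(s, pm4)$score, 0)
  expect_equal(max(scores), scan_best_hit(consensus(pm4), pm4)$score)
})

test_that("similarity filter enforces pairwise Hamming distance greedily", {
  expect_equal(similarity_filter(c("AAAA", "AAAA", "AAAA"), 1), "AAAA")

  a <- "AAAAAAAAAA"
  b <- "TTTAAAAAAA"                     # Hamming distance 3
  expect_equal(similarity_filter(c(a, b), 4), a)
  expect_equal(similarity_filter(c(a, b), 3), c(a, b))

  # two 50-mers differing at exactly 15 sites both survive at min 15
  s1 <- strrep("A", 50)
  s2 <- paste0(strrep("T", 15), strrep("A", 35))
  expect_equal(length(similarity_filter(c(s1, s2), 15)), 2L)

  expect_warning(similarity_filter(c("ACGT", "TTTT"), 5), "exceeds")

  # property: output of a random batch is pairwise >= m apart
  set.seed(42)
  pool <- random_acgt(60, 12)
  kept <- similarity_filter(pool, 4)
  D <- utils::adist(kept)               # Hamming == edit here? check pairwise
  ham <- outer(seq_along(kept), seq_along(kept), Vectorize(function(i, j) {
    sum(strsplit(kept[i], "")[[1]] != strsplit(kept[j], "")[[1]])
  }))
  diag(ham) <- NA
  expect_true(all(ham >= 4, na.rm = TRUE))
})
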