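test_that("motif instance sampling follows the PFM", {
  # deterministic PFM -> consensus always
  pm <- consensus_pfm("TTGACA", strength = 1e9)
  expect_equal(unique(sample_motif_instance(pm, 50, seed = 1)), "TTGACA")
  expect_equal(nchar(sample_motif_instance(fixture_motifs(1)[[1]], 1, seed = 2)),
               6L)

  # uniform PFM: per-column base frequencies ~ 0.25
  unif <- position_matrix(matrix(1, 4, 4), pseudocount = 0)
  draws <- sample_motif_instance(unif, 10000, seed = 3)
  chars <- do.call(rbind, strsplit(draws, ""))
  freq <- prop.table(table(chars[, 2]))
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("pair sequences splice X + 13bp gap + Y into a random template", {
  m1 <- consensus_pfm("TGACTC", strength = 1e9)   # deterministic instances
  m2 <- consensus_pfm("CACGTG", strength = 1e9)
  rec <- make_pair_sequence(m1, m2, seed = 11)
  expect_equal(nchar(rec$sequence), 50L)
  expect_equal(rec$y_start - rec$x_end, 13L)
  expect_equal(rec$x_end - rec$x_start, 6L)
  # planted coordinates reconstruct the emitted subsequences
  expect_equal(substr(rec$sequence, rec$x_start + 1, rec$x_end), "TGACTC")
  expect_equal(substr(rec$sequence, rec$y_start + 1, rec$y_end), "CACGTG")
  # fixed seed -> identical output
  expect_identical(make_pair_sequence(m1, m2, seed = 11), rec)
  expect_error(make_pair_sequence(m1, m2, gap_length = 45), "exceeds")

  # widths 6+13+6 = 25 in L = 50: offsets 0..25 all occur
  offs <- vapply(1:2000, function(i) {
    make_pair_sequence(m1, m2, seed = i)$x_start
  }, 0)
  expect_setequal(sort(unique(offs)), 0:25)
})

test_that("pair dataset counts are exact functions of pairs x per_pair", {
  motifs <- fixture_motifs(2)
  ds <- build_pair_dataset(motifs, per_pair = 10, seed = 5, strict = FALSE)
  expect_equal(nrow(ds), 2^2 * 10)
  expect_equal(length(unique(ds$pair_id)), 4L)
  expect_true(all(nchar(ds$sequence) == 50L))
  expect_true(all(ds$y_start - ds$x_end == 13L))
  # splice identity on every row
  i <- sample(nrow(ds), 10)
  w <- ds$x_end[i] - ds$x_start[i]
  expect_equal(nchar(substr(ds$sequence[i], ds$x_start[i] + 1, ds$x_end[i])), w)
  expect_warning(build_pair_dataset(fixture_motifs(2), per_pair = 1),
                 "6 motifs")
})

test_that("PSSM control and random sequences match their compositions", {
  probs <- matrix(c(1, 0, 0, 0), 5, 4, byrow = TRUE,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
  pm <- position_matrix(probs * 100, pseudocount = 0)
  expect_equal(unique(sample_pssm_control(pm, 20, seed = 1)), "AAAAA")
  expect_equal(sample_pssm_control(pm, 0), character(0))

  expect_equal(random_sequences(0, 10), character(0))
  allgc <- random_sequences(20, 30, gc = 1, seed = 2)
  expect_true(all(grepl("^[GC]+$", allgc)))
  mid <- random_sequences(2000, 50, gc = 0.5, seed = 3)
  expect_lt(abs(mean(gc_content(mid)) - 0.5), 0.01)
  expect_identical(random_sequences(5, 10, seed = 4),
                   random_sequences(5, 10, seed = 4))
})

test_that("synthetic promoter benchmark plants boxes, spacers and labels", {
  bench <- synth_promoter_benchmark(2000, seed = 8)
  expect_length(bench$sequences, 2000)
  expect_true(all(nchar(bench$sequences) == 50))

  # spacer histogram mode at 17
  tab <- table(bench$truth$spacer)
  expect_equal(as.integer(names(tab)[which.max(tab)]), 17L)
  expect_true(all(bench$truth$spacer >= 15 & bench$truth$spacer <= 19))

  # planted -10 region is TATAAT-enriched at the planted offset
  at10 <- substr(bench$sequences, bench$truth$box10_start + 1,
                 bench$truth$box10_start + 6)
  expect_gt(mean(substr(at10, 1, 1) == "T"), 0.7)
  expect_gt(mean(at10 == "TATAAT"), 0.3)

  # labels correlate with the noiseless signal (r >= 0.95 by construction)
  expect_gt(pearson(bench$expression, bench$truth$signal), 0.95)
})
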