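tiny_cnn_args <- list(conv_channels = c(8, 12, 6), kernel = 5, padding = 2,
                      batch_size = 16, lr = 1e-3, patience = 5)

test_that("pearson matches hand computations and guards edge cases", {
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson(c(1, 2, 3), -c(1, 2, 3)), -1)
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 4)), 0.9819805, tolerance = 1e-6)
  expect_error(pearson(c(1, 2), c(1, 2, 3)), "length mismatch")
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("CNN layer shapes follow the configured architecture", {
  p <- promdiff:::cnn_init_params(c(100, 200, 200, 10), 5, seed = 1)
  expect_equal(dim(p$conv1.W), c(4 * 5, 100))
  expect_equal(dim(p$conv2.W), c(100 * 5, 200))
  expect_equal(dim(p$conv3.W), c(200 * 5, 200))
  expect_equal(dim(p$conv4.W), c(200 * 5, 10))
  expect_length(p$bn4.g, 10)
  expect_equal(dim(p$fc.W), c(10, 1))
  # parameter count of the default architecture
  n_par <- sum(vapply(p, length, 0))
  expect_equal(n_par, 4 * 5 * 100 + 100 + 100 * 5 * 200 + 200 +
                      200 * 5 * 200 + 200 + 200 * 5 * 10 + 10 +
                      2 * (100 + 200 + 200 + 10) + 10 + 1)
})

test_that("CNN gradients match central differences", {
  set.seed(2)
  N <- 6; L <- 12
  cfg <- list(L = L, conv_channels = c(3, 4), kernel = 3, padding = 1,
              stride = 1L)
  p <- promdiff:::cnn_init_params(cfg$conv_channels, cfg$kernel, seed = 3)
  running <- promdiff:::cnn_init_running(cfg$conv_channels)
  X <- matrix(encode_onehot(random_acgt(N, L)), N * L, 4)
  y <- rnorm(N)
  lossfun <- function(params) {
    fw <- promdiff:::cnn_fwd(params, running, X, N, L, cfg, train = TRUE)
    mean((fw$pred - y)^2)
  }
  fw <- promdiff:::cnn_fwd(p, running, X, N, L, cfg, train = TRUE)
  gr <- promdiff:::cnn_bwd(p, fw, 2 * (fw$pred - y) / N, N, L, cfg)
  h <- 1e-5
  for (nm in names(p)) {
    for (j in sample(length(p[[nm]]), min(3, length(p[[nm]])))) {
      pp <- p; pp[[nm]][j] <- pp[[nm]][j] + h
      f1 <- lossfun(pp)
      pp <- p; pp[[nm]][j] <- pp[[nm]][j] - h
      f2 <- lossfun(pp)
      num <- (f1 - f2) / (2 * h)
      expect_lt(abs(num - gr[[nm]][j]),
                1e-6 + 1e-3 * (abs(num) + abs(gr[[nm]][j])))
    }
  }
})

test_that("training logs, early stopping and prediction determinism behave", {
  set.seed(4)
  n <- 120
  seqs <- random_acgt(n, 20)
  y <- gc_content(seqs) + rnorm(n, 0, 0.02)

  fit1 <- do.call(expr_cnn, c(list(x = seqs, y = y, epochs = 1, seed = 7),
                              tiny_cnn_args[names(tiny_cnn_args) != "patience"],
                              list(patience = 1)))
  expect_equal(nrow(fit1$log), 1L)

  fit <- do.call(expr_cnn, c(list(x = seqs, y = y, epochs = 25, seed = 7),
                             tiny_cnn_args))
  # early stopping: no more than best_epoch + patience epochs run
  expect_lte(nrow(fit$log), fit$best_epoch + tiny_cnn_args$patience)

  # duplicates predict identically; batching does not change predictions
  p1 <- predict(fit, c(seqs[1], seqs[1], seqs[2]))
  expect_identical(p1[1], p1[2])
  expect_length(p1, 3)
  p_all <- predict(fit, seqs[1:30])
  p_one <- vapply(seqs[1:30], function(s) predict(fit, s), 0,
                  USE.NAMES = FALSE)
  expect_equal(p_all, p_one, tolerance = 1e-10)

  expect_error(predict(fit, "ACGT"), "length mismatch")
  expect_error(expr_cnn(seqs, rep(1, n)), "constant")
  expect_error(do.call(expr_cnn, c(list(x = seqs, y = y, epochs = 3,
                                        patience = 10), tiny_cnn_args[-5])),
               "patience")
})

test_that("CNN recovers a planted motif-strength signal on a small corpus", {
  bench <- synth_promoter_benchmark(800, seed = 21)
  fit <- expr_cnn(bench$sequences, bench$expression,
                  conv_channels = c(24, 48, 10), batch_size = 16,
                  epochs = 60, lr = 2e-3, patience = 60, seed = 8)
  expect_gt(fit$test_pearson, 0.6)
})
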