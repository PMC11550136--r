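test_that("noise schedules satisfy their invariants", {
  s1 <- build_schedule(1)
  expect_equal(s1$alpha_bar[1], s1$alpha[1])   # product of one term

  for (kind in c("cosine", "linear")) {
    s <- build_schedule(100, kind)
    expect_true(all(diff(s$alpha_bar) < 0))    # strictly decreasing
    expect_equal(s$alpha_bar, cumprod(1 - s$beta))
    expect_true(all(s$beta > 0 & s$beta <= 1))
  }
  expect_lt(build_schedule(100, "cosine")$alpha_bar[100], 1e-3)
  expect_error(build_schedule(0), "positive integer")

  # terminal marginal is indistinguishable from uniform for the default
  s <- build_schedule(100)
  x0 <- encode_onehot("ACGTACGTAC")
  qT <- marginal_probs(x0, 100, s)
  kl <- sum(qT * log(qT / 0.25)) / 10     # per position, nats
  expect_lt(kl, 1e-3)
})

test_that("forward step and marginal follow the categorical corruption", {
  s <- build_schedule(10, "linear")
  x0 <- encode_onehot(c("AACG", "TGCA"))

  # beta = 0.2 acting on one-hot A gives (0.85, 0.05, 0.05, 0.05)
  s2 <- s; s2$beta[3] <- 0.2
  out <- forward_step_probs(encode_onehot("A"), 3, s2)
  expect_equal(as.vector(out[1, 1, ]), c(0.85, 0.05, 0.05, 0.05))

  # beta = 1 -> uniform; beta -> 0 -> identity
  s3 <- s; s3$beta[2] <- 1
  expect_true(all(abs(forward_step_probs(x0, 2, s3) - 0.25) < 1e-12))
  s4 <- s; s4$beta[2] <- 0
  expect_equal(forward_step_probs(x0, 2, s4), x0, ignore_attr = TRUE)

  # marginal endpoints
  s5 <- s; s5$alpha_bar[4] <- 1
  expect_equal(marginal_probs(x0, 4, s5), x0, ignore_attr = TRUE)
  s6 <- s; s6$alpha_bar[4] <- 0
  expect_true(all(abs(marginal_probs(x0, 4, s6) - 0.25) < 1e-12))

  expect_error(forward_step_probs(x0, 11, s), "out of range")
  expect_error(marginal_probs(x0, 0, s), "out of range")
})

test_that("composed one-step transitions telescope to the marginal", {
  for (kind in c("cosine", "linear")) {
    s <- build_schedule(100, kind)
    M <- diag(4)
    for (t in seq_len(s$T)) {
      M <- M %*% ((1 - s$beta[t]) * diag(4) + s$beta[t] / 4)
    }
    M_marginal <- s$alpha_bar[s$T] * diag(4) + (1 - s$alpha_bar[s$T]) / 4
    expect_lt(max(abs(M - M_marginal)), 1e-10)
    # and at intermediate steps too
    M <- diag(4)
    for (t in 1:37) M <- M %*% ((1 - s$beta[t]) * diag(4) + s$beta[t] / 4)
    expect_lt(max(abs(M - (s$alpha_bar[37] * diag(4) +
                           (1 - s$alpha_bar[37]) / 4))), 1e-10)
  }
})

test_that("categorical posterior agrees with 4-way Bayes enumeration", {
  s <- build_schedule(100)
  set.seed(3)
  worst <- 0
  for (i in 1:1000) {
    t <- sample(2:100, 1)
    k0 <- sample(4, 1)
    kt <- sample(4, 1)
    x0 <- array(0, c(1, 1, 4)); x0[1, 1, k0] <- 1
    xt <- array(0, c(1, 1, 4)); xt[1, 1, kt] <- 1
    post <- posterior_probs(xt, x0, t, s)[1, 1, ]
    bayes <- vapply(1:4, function(c) {
      q_step <- (1 - s$beta[t]) * (c == kt) + s$beta[t] / 4
      q_marg <- s$alpha_bar[t - 1] * (c == k0) + (1 - s$alpha_bar[t - 1]) / 4
      q_step * q_marg
    }, 0)
    worst <- max(worst, max(abs(post - bayes / sum(bayes))))
  }
  expect_lt(worst, 1e-12)

  # soft xhat0 also agrees with enumeration
  set.seed(4)
  p0 <- stats::runif(4); p0 <- p0 / sum(p0)
  x0s <- array(p0, c(1, 1, 4))
  xt <- array(c(1, 0, 0, 0), c(1, 1, 4))
  t <- 17
  post <- posterior_probs(xt, x0s, t, s)[1, 1, ]
  bayes <- vapply(1:4, function(c) {
    ((1 - s$beta[t]) * (c == 1) + s$beta[t] / 4) *
      (s$alpha_bar[t - 1] * p0[c] + (1 - s$alpha_bar[t - 1]) / 4)
  }, 0)
  expect_lt(max(abs(post - bayes / sum(bayes))), 1e-12)

  # alpha_t = 1 -> point mass at x_t
  s2 <- s; s2$alpha[9] <- 1; s2$beta[9] <- 0
  post <- posterior_probs(xt, x0s, 9, s2)[1, 1, ]
  expect_gt(post[1], 1 - 1e-6)
})

test_that("step loss vanishes for the oracle denoiser and matches L0", {
  s <- build_schedule(20, "linear")
  x0 <- encode_onehot(c("ACGTACGTAC", "TTGACATATA"))
  set.seed(5)
  for (t in 2:20) {
    xt <- encode_onehot(random_acgt(2, 10))
    expect_equal(step_loss(x0, xt, t, xhat0 = x0, s = s), 0, tolerance = 1e-9)
  }
  # L0 with uniform xhat0 = L * log 4 nats regardless of x0
  unif <- array(0.25, c(2, 10, 4))
  expect_equal(step_loss(x0, x0, 1, xhat0 = unif, s = s), 10 * log(4))
  # KL nonnegativity for random soft predictions
  set.seed(6)
  for (i in 1:20) {
    p <- array(stats::runif(2 * 10 * 4), c(2, 10, 4))
    p <- p / array(rep(apply(p, c(1, 2), sum), 4), c(2, 10, 4))
    t <- sample(2:20, 1)
    xt <- encode_onehot(random_acgt(2, 10))
    expect_gte(step_loss(x0, xt, t, xhat0 = p, s = s), 0)
  }
})
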