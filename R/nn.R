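# Minimal neural-network layer library: explicit forward/backward passes on
# base matrix algebra, plus an Adam optimiser. Parameters, gradients and
# optimiser moments share one structure: a flat named list of numeric
# arrays. Gradient correctness is pinned by central-difference tests.

## ---- parameter utilities ----------------------------------------------

# zero structure matching params: plain vectors stay vectors
nn_zeros_like <- function(params) {
  lapply(params, function(p) {
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim = dim(p))
  })
}

adam_init <- function(params) {
  list(m = nn_zeros_like(params), v = nn_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = st)
}

## ---- primitive layers --------------------------------------------------

# linear: X (R x in) %*% W (in x out) + b
# column-broadcast helpers: rep(v, each = R) matches column-major layout
add_cols <- function(Y, b) Y + rep(b, each = nrow(Y))
mul_cols <- function(Y, g) Y * rep(g, each = nrow(Y))

linear_fwd <- function(X, W, b = NULL) {
  Y <- X %*% W
  if (!is.null(b)) Y <- add_cols(Y, b)
  Y
}

linear_bwd <- function(X, W, dY) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

# row-wise layer norm with affine (g, b length d)
layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- add_cols(mul_cols(xhat, g), b)
  list(Y = Y, xhat = xhat, inv = inv)
}

layernorm_bwd <- function(cache, g, dY) {
  xhat <- cache$xhat
  dxh <- mul_cols(dY, g)
  dX <- cache$inv * (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat))
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

softmax_rows <- function(Z) {
  m <- Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  E <- exp(Z - m)
  E / rowSums(E)
}

# d(loss)/d(logits) given probs P and d(loss)/d(probs) G
softmax_bwd_rows <- function(P, G) P * (G - rowSums(P * G))

relu_fwd <- function(X) X * (X > 0)

## ---- block-local multi-head self-attention -----------------------------

# blocks: list of integer row-index vectors (one per attention window);
# rows of H covered exactly once. heads partition the embedding columns.
attention_fwd <- function(H, p, prefix, blocks, heads) {
  rel <- p[[paste0(prefix, "rel")]]
  d <- ncol(H)
  dh <- d %/% heads
  Q <- H %*% p[[paste0(prefix, "Wq")]]
  K <- H %*% p[[paste0(prefix, "Wk")]]
  V <- H %*% p[[paste0(prefix, "Wv")]]
  O <- matrix(0, nrow(H), d)
  scale <- 1 / sqrt(dh)
  A_all <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    idx <- blocks[[bi]]
    Qb <- Q[idx, , drop = FALSE]
    Kb <- K[idx, , drop = FALSE]
    Vb <- V[idx, , drop = FALSE]
    Ob <- matrix(0, length(idx), d)
    Ab <- vector("list", heads)
    B <- length(idx)
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Qb[, cols, drop = FALSE],
                      Kb[, cols, drop = FALSE]) * scale
      for (i in seq_len(B)) {
        S[i, ] <- S[i, ] + rel[h, (B - i + 1L):(2L * B - i)]
      }
      A <- softmax_rows(S)
      Ob[, cols] <- A %*% Vb[, cols, drop = FALSE]
      Ab[[h]] <- A
    }
    O[idx, ] <- Ob
    A_all[[bi]] <- Ab
  }
  Y <- O %*% p[[paste0(prefix, "Wo")]]
  list(Y = Y, Q = Q, K = K, V = V, O = O, A = A_all)
}

attention_bwd <- function(H, p, prefix, blocks, heads, cache, dY) {
  d <- ncol(H)
  dh <- d %/% heads
  scale <- 1 / sqrt(dh)
  dO <- dY %*% t(p[[paste0(prefix, "Wo")]])
  dWo <- crossprod(cache$O, dY)
  dQ <- matrix(0, nrow(H), d)
  dK <- matrix(0, nrow(H), d)
  dV <- matrix(0, nrow(H), d)
  for (bi in seq_along(blocks)) {
    idx <- blocks[[bi]]
    Qb <- cache$Q[idx, , drop = FALSE]
    Kb <- cache$K[idx, , drop = FALSE]
    Vb <- cache$V[idx, , drop = FALSE]
    dOb <- dO[idx, , drop = FALSE]
    dQb <- matrix(0, length(idx), d)
    dKb <- dQb
    dVb <- dQb
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cache$A[[bi]][[h]]
      dA <- tcrossprod(dOb[, cols, drop = FALSE], Vb[, cols, drop = FALSE])
      dVb[, cols] <- crossprod(A, dOb[, cols, drop = FALSE])
      dS <- softmax_bwd_rows(A, dA) * scale
      dQb[, cols] <- dS %*% Kb[, cols, drop = FALSE]
      dKb[, cols] <- crossprod(dS, Qb[, cols, drop = FALSE])
    }
    dQ[idx, ] <- dQb
    dK[idx, ] <- dKb
    dV[idx, ] <- dVb
  }
  list(dH = dQ %*% t(p[[paste0(prefix, "Wq")]]) +
             dK %*% t(p[[paste0(prefix, "Wk")]]) +
             dV %*% t(p[[paste0(prefix, "Wv")]]),
       dWq = crossprod(H, dQ), dWk = crossprod(H, dK),
       dWv = crossprod(H, dV), dWo = dWo)
}

## ---- 1D convolution (im2col) ------------------------------------------

# X: (N*L) x C matrix, row r = n + (l-1)*N; zero padding `pad` each side.
# W: (C*ker) x Cout, b: length Cout.
conv1d_fwd <- function(X, W, b, N, L, ker, pad) {
  C <- ncol(X)
  Lp <- L + 2L * pad
  Xp <- matrix(0, N * Lp, C)
  Xp[N * pad + seq_len(N * L), ] <- X
  Xcol <- matrix(0, N * L, C * ker)
  for (k in seq_len(ker)) {
    rows <- (k - 1L) * N + seq_len(N * L)
    Xcol[, (k - 1L) * C + seq_len(C)] <- Xp[rows, , drop = FALSE]
  }
  Y <- add_cols(Xcol %*% W, b)
  list(Y = Y, Xcol = Xcol)
}

conv1d_bwd <- function(cache, W, dY, N, L, ker, pad, C) {
  dW <- crossprod(cache$Xcol, dY)
  db <- colSums(dY)
  dXcol <- dY %*% t(W)
  Lp <- L + 2L * pad
  dXp <- matrix(0, N * Lp, C)
  for (k in seq_len(ker)) {
    rows <- (k - 1L) * N + seq_len(N * L)
    dXp[rows, ] <- dXp[rows, ] + dXcol[, (k - 1L) * C + seq_len(C)]
  }
  list(dX = dXp[N * pad + seq_len(N * L), , drop = FALSE], dW = dW, db = db)
}

## ---- batch norm over channels ------------------------------------------

# X: (N*L) x C; normalise each channel over all rows (batch x position).
batchnorm_fwd <- function(X, g, b, running, train = TRUE, momentum = 0.1,
                          eps = 1e-5) {
  if (train) {
    mu <- colMeans(X)
    xc <- add_cols(X, -mu)
    v <- colMeans(xc * xc)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
    xc <- add_cols(X, -mu)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- mul_cols(xc, inv)
  Y <- add_cols(mul_cols(xhat, g), b)
  list(Y = Y, xhat = xhat, inv = inv, running = running)
}

batchnorm_bwd <- function(cache, g, dY) {
  xhat <- cache$xhat
  R <- nrow(xhat)
  dxh <- mul_cols(dY, g)
  dX <- mul_cols(dxh - rep(colMeans(dxh), each = R) -
                 xhat * rep(colMeans(dxh * xhat), each = R), cache$inv)
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

## ---- misc ---------------------------------------------------------------

# sinusoidal embedding matrix for steps 1..T, dimension d (even)
sinusoidal_embedding <- function(T_steps, d) {
  pos <- seq_len(T_steps)
  half <- d %/% 2
  freqs <- 1 / (10000^((seq_len(half) - 1) / half))
  ang <- outer(pos, freqs)
  cbind(sin(ang), cos(ang))[, seq_len(d), drop = FALSE]
}

# evaluate an RNG-consuming expression under a temporary seed, restoring
# the caller's RNG state afterwards
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
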