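# Transformer denoiser for the multinomial diffusion model.
#
# Architecture (pre-norm transformer):
#   h0 = onehot(x_t) %*% W_emb + positional embedding (learned, per
#        position), i.e. the token embedding m(.)
#   per layer: h <- h + n(t)                        (sinusoidal step embedding)
#              h <- h + Attn(LN(h))                 (block-local multi-head)
#              h <- h + FFN(LN(h))                  (ReLU, width ff_dim)
#   xhat0 = softmax(LN(h) %*% W_out + b_out) per position
#
# Self-attention is chunked ("block-local"): position l attends only to
# positions in its block of `local_size` consecutive positions, which must
# divide L. local_size = L gives full attention.

#' Initialise a transformer denoiser
#'
#' @param L sequence length.
#' @param T_steps number of diffusion steps the model is conditioned on.
#' @param layers number of transformer layers (default 12).
#' @param heads attention heads per layer (default 16); must divide
#'   \code{embed_dim}.
#' @param embed_dim embedding width (default 128).
#' @param ff_dim feed-forward hidden width (default \code{2 * embed_dim}).
#' @param local_size attention block length; must divide \code{L}
#'   (default 25 when \code{L} is a multiple of 25, else \code{L}).
#' @param emb_kernel width of the convolutional token embedding (odd;
#'   default 7). Each position is embedded from its one-hot window of
#'   this many bases, which makes local motif context directly visible
#'   to the first layer.
#' @param seed RNG seed for weight initialisation.
#' @return object of class \code{mdm_denoiser}: list with \code{cfg},
#'   \code{params}, and precomputed step embeddings.
#' @export
denoiser_init <- function(L, T_steps, layers = 12, heads = 16,
                          embed_dim = 128, ff_dim = 2 * embed_dim,
                          local_size = if (L %% 25 == 0) 25 else L,
                          emb_kernel = 7, seed = 0) {
  if (emb_kernel %% 2 != 1) stop("emb_kernel must be odd")
  if (L %% local_size != 0) stop("local_size must divide L")
  if (embed_dim %% heads != 0) stop("heads must divide embed_dim")
  if (embed_dim %% 2 != 0) stop("embed_dim must be even")
  d <- embed_dim
  cfg <- list(L = L, T = T_steps, layers = layers, heads = heads,
              embed_dim = d, ff_dim = ff_dim, local_size = local_size,
              emb_kernel = emb_kernel, seed = seed)
  params <- with_seed(seed, {
    rn <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
    xavier <- function(nr, nc) rn(nr, nc, sd = sqrt(2 / (nr + nc)))
    # token embedding at O(1) scale so the noised input is not drowned by
    # the positional/time embeddings; interior projections at Xavier scale
    # so attention carries usable cross-position signal from the start;
    # time projection and output head start near zero
    p <- list(W_emb = rn(4 * emb_kernel, d, sd = 0.5 / sqrt(emb_kernel)),
              P_pos = rn(L, d, sd = 0.1),
              W_t = rn(d, d), b_t = rep(0, d))
    for (l in seq_len(layers)) {
      pre <- sprintf("L%d.", l)
      p[[paste0(pre, "ln1.g")]] <- rep(1, d)
      p[[paste0(pre, "ln1.b")]] <- rep(0, d)
      p[[paste0(pre, "Wq")]] <- xavier(d, d)
      p[[paste0(pre, "Wk")]] <- xavier(d, d)
      p[[paste0(pre, "Wv")]] <- xavier(d, d)
      p[[paste0(pre, "Wo")]] <- xavier(d, d)
      p[[paste0(pre, "rel")]] <- matrix(0, heads, 2 * local_size - 1)
      p[[paste0(pre, "ln2.g")]] <- rep(1, d)
      p[[paste0(pre, "ln2.b")]] <- rep(0, d)
      p[[paste0(pre, "W1")]] <- xavier(d, ff_dim)
      p[[paste0(pre, "b1")]] <- rep(0, ff_dim)
      p[[paste0(pre, "W2")]] <- xavier(ff_dim, d)
      p[[paste0(pre, "b2")]] <- rep(0, d)
    }
    p$lnf.g <- rep(1, d)
    p$lnf.b <- rep(0, d)
    p$W_out <- rn(d, 4)
    p$b_out <- rep(0, 4)
    p
  })
  structure(list(cfg = cfg, params = params,
                 t_emb = sinusoidal_embedding(T_steps, d)),
            class = "mdm_denoiser")
}

# Internally the denoiser works in sequence-major row order
# (r = (n-1)*L + l), so attention blocks are contiguous row ranges; the
# public field layout is batch-major (r = n + (l-1)*N), and the two
# permutations below convert at the boundary.

# block row-index list in sequence-major order: contiguous ranges
make_blocks <- function(N, L, B) {
  nb <- L %/% B
  out <- vector("list", N * nb)
  i <- 0L
  for (n in seq_len(N)) {
    for (j in seq_len(nb)) {
      i <- i + 1L
      out[[i]] <- ((n - 1L) * L + (j - 1L) * B + 1L):((n - 1L) * L + j * B)
    }
  }
  out
}

# permutation taking batch-major rows to sequence-major rows, and inverse
bm_to_sm <- function(N, L) as.vector(t(matrix(seq_len(N * L), N, L)))
sm_to_bm <- function(N, L) as.vector(t(matrix(seq_len(N * L), L, N)))

# forward pass on matrices. xtm: (N*L) x 4 one-hot (batch-major); tv:
# length N (or 1). Returns logits, probs (batch-major) and the cache for
# backward. Dispatches to the compiled kernel; denoiser_fwd_ref below is
# the pure-R reference used to cross-check it.
denoiser_fwd <- function(model, xtm, tv, N, L, keep_cache = TRUE) {
  cfg <- model$cfg
  if (length(tv) == 1L) tv <- rep(tv, N)
  perm <- bm_to_sm(N, L)
  out <- .cpp_denoiser_fwd(model$params, xtm[perm, , drop = FALSE],
                           model$t_emb, as.integer(tv), N, L, cfg$layers,
                           cfg$heads, cfg$local_size, keep_cache)
  inv <- sm_to_bm(N, L)
  res <- list(logits = out$logits[inv, , drop = FALSE],
              probs = out$probs[inv, , drop = FALSE],
              cache = if (keep_cache) out$cache else NULL,
              N = N, L = L)
  res
}

# backward pass; dlogits: (N*L) x 4 batch-major. Gradient list matches
# the parameter list in names and shapes.
denoiser_bwd <- function(model, fw, dlogits) {
  cfg <- model$cfg
  g <- .cpp_denoiser_bwd(model$params, fw$cache,
                         dlogits[bm_to_sm(fw$N, fw$L), , drop = FALSE],
                         fw$N, fw$L, cfg$layers, cfg$heads, cfg$local_size)
  # C++ returns 1 x d matrices for vector parameters; restore shapes
  for (nm in names(model$params)) {
    if (length(dim(model$params[[nm]])) < 2L) g[[nm]] <- as.vector(g[[nm]])
  }
  g[names(model$params)]
}

denoiser_fwd_ref <- function(model, xtm, tv, N, L, keep_cache = TRUE) {
  cfg <- model$cfg
  p <- model$params
  if (length(tv) == 1L) tv <- rep(tv, N)
  blocks <- make_blocks(N, L, cfg$local_size)
  perm <- bm_to_sm(N, L)
  xtm <- xtm[perm, , drop = FALSE]           # sequence-major from here on
  TErows <- linear_fwd(model$t_emb[rep(tv, each = L), , drop = FALSE],
                       p$W_t, p$b_t)
  k <- nrow(p$W_emb) %/% 4L
  half <- (k - 1L) %/% 2L
  H <- matrix(0, N * L, ncol(p$W_emb))
  for (o in -half:half) {
    Wo <- p$W_emb[((o + half) * 4L + 1L):((o + half) * 4L + 4L), , drop = FALSE]
    for (n in seq_len(N)) {
      lo <- max(0L, -o); hi <- min(L - 1L, L - 1L - o)
      if (lo > hi) next
      rows <- (n - 1L) * L + (lo:hi) + 1L
      H[rows, ] <- H[rows, ] + xtm[rows + o, , drop = FALSE] %*% Wo
    }
  }
  H <- H + p$P_pos[rep(seq_len(L), times = N), , drop = FALSE]
  caches <- list()
  for (l in seq_len(cfg$layers)) {
    pre <- sprintf("L%d.", l)
    H <- H + TErows
    ln1 <- layernorm_fwd(H, p[[paste0(pre, "ln1.g")]], p[[paste0(pre, "ln1.b")]])
    att <- attention_fwd(ln1$Y, p, pre, blocks, cfg$heads)
    H2 <- H + att$Y
    ln2 <- layernorm_fwd(H2, p[[paste0(pre, "ln2.g")]], p[[paste0(pre, "ln2.b")]])
    Z1 <- linear_fwd(ln2$Y, p[[paste0(pre, "W1")]], p[[paste0(pre, "b1")]])
    A1 <- relu_fwd(Z1)
    F2 <- linear_fwd(A1, p[[paste0(pre, "W2")]], p[[paste0(pre, "b2")]])
    Hout <- H2 + F2
    if (keep_cache) {
      caches[[l]] <- list(Hin = H, ln1 = ln1, att = att, H2 = H2, ln2 = ln2,
                          Z1 = Z1, A1 = A1)
    }
    H <- Hout
  }
  lnf <- layernorm_fwd(H, p$lnf.g, p$lnf.b)
  logits <- linear_fwd(lnf$Y, p$W_out, p$b_out)
  probs <- softmax_rows(logits)
  inv <- sm_to_bm(N, L)
  list(logits = logits[inv, , drop = FALSE],      # back to batch-major
       probs = probs[inv, , drop = FALSE],
       cache = if (keep_cache) list(layers = caches, lnf = lnf, Hfin = H,
                                    xtm = xtm, blocks = blocks, N = N, L = L)
               else NULL)
}

denoiser_bwd_ref <- function(model, fw, dlogits) {
  cfg <- model$cfg
  p <- model$params
  cc <- fw$cache
  dlogits <- dlogits[bm_to_sm(cc$N, cc$L), , drop = FALSE]  # sequence-major
  g <- list()
  lb <- linear_bwd(cc$lnf$Y, p$W_out, dlogits)
  g$W_out <- lb$dW
  g$b_out <- lb$db
  lnb <- layernorm_bwd(cc$lnf, p$lnf.g, lb$dX)
  g$lnf.g <- lnb$dg
  g$lnf.b <- lnb$db
  dH <- lnb$dX
  for (l in rev(seq_len(cfg$layers))) {
    pre <- sprintf("L%d.", l)
    cl <- cc$layers[[l]]
    # FFN branch
    dF2 <- dH
    lb2 <- linear_bwd(cl$A1, p[[paste0(pre, "W2")]], dF2)
    g[[paste0(pre, "W2")]] <- lb2$dW
    g[[paste0(pre, "b2")]] <- lb2$db
    dZ1 <- lb2$dX * (cl$Z1 > 0)
    lb1 <- linear_bwd(cl$ln2$Y, p[[paste0(pre, "W1")]], dZ1)
    g[[paste0(pre, "W1")]] <- lb1$dW
    g[[paste0(pre, "b1")]] <- lb1$db
    ln2b <- layernorm_bwd(cl$ln2, p[[paste0(pre, "ln2.g")]], lb1$dX)
    g[[paste0(pre, "ln2.g")]] <- ln2b$dg
    g[[paste0(pre, "ln2.b")]] <- ln2b$db
    dH2 <- dH + ln2b$dX
    # attention branch
    ab <- attention_bwd(cl$ln1$Y, p, pre, cc$blocks, cfg$heads, cl$att, dH2)
    g[[paste0(pre, "Wq")]] <- ab$dWq
    g[[paste0(pre, "Wk")]] <- ab$dWk
    g[[paste0(pre, "Wv")]] <- ab$dWv
    g[[paste0(pre, "Wo")]] <- ab$dWo
    ln1b <- layernorm_bwd(cl$ln1, p[[paste0(pre, "ln1.g")]], ab$dH)
    g[[paste0(pre, "ln1.g")]] <- ln1b$dg
    g[[paste0(pre, "ln1.b")]] <- ln1b$db
    dH <- dH2 + ln1b$dX
    # n(t) is a fixed sinusoidal embedding: no parameter gradient
  }
  g$W_emb <- crossprod(cc$xtm, dH)
  g$P_pos <- rowsum(dH, group = rep(seq_len(cc$L), times = cc$N))
  g
}

#' Predict the clean sequence distribution from a noised state
#'
#' Runs the denoiser on a one-hot batch \eqn{x_t} at step t, returning the
#' per-position distribution \eqn{\hat x_0 = \mu(x_t, t)} (softmax over the
#' 4 bases). Deterministic given weights and inputs.
#'
#' @param xt N x L x 4 one-hot batch.
#' @param t step index, scalar or length N, in 1..T.
#' @param model an [denoiser_init()] object (or a fitted [mdm()] model's
#'   \code{$denoiser}).
#' @return N x L x 4 probability field.
#' @export
denoise_predict <- function(xt, t, model) {
  if (inherits(model, "mdm")) model <- model$denoiser
  stopifnot(inherits(model, "mdm_denoiser"))
  f <- as_field_mat(xt)
  if (f$L != model$cfg$L) stop("sequence length mismatch with model config")
  if (any(t < 1) || any(t > model$cfg$T)) stop("t outside [1, T]")
  fw <- denoiser_fwd(model, f$mat, as.integer(t), f$N, f$L, keep_cache = FALSE)
  field_array(fw$probs, f$N, f$L)
}
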