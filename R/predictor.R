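# 1D-CNN sequence-to-expression regressor.
#
# Architecture: four conv1d blocks (kernel 5, stride 1, padding 2; output
# channels 100, 200, 200, 10 by default), each followed by batch
# normalisation and ReLU; a global max-pool over positions per channel;
# and a single linear head to one output. Trained with MSE under Adam;
# early stopping monitors the Pearson correlation on the validation split.

cnn_init_params <- function(channels, kernel, seed) {
  with_seed(seed, {
    p <- list()
    cin <- 4L
    for (i in seq_along(channels)) {
      cout <- channels[i]
      p[[sprintf("conv%d.W", i)]] <-
        matrix(stats::rnorm(cin * kernel * cout, sd = sqrt(2 / (cin * kernel))),
               cin * kernel, cout)
      p[[sprintf("conv%d.b", i)]] <- rep(0, cout)
      p[[sprintf("bn%d.g", i)]] <- rep(1, cout)
      p[[sprintf("bn%d.b", i)]] <- rep(0, cout)
      cin <- cout
    }
    p$fc.W <- matrix(stats::rnorm(channels[length(channels)], sd = 0.1),
                     channels[length(channels)], 1)
    p$fc.b <- 0
    p
  })
}

cnn_init_running <- function(channels) {
  lapply(channels, function(c) list(mean = rep(0, c), var = rep(1, c)))
}

# forward pass. X: (N*L) x 4. Returns prediction vector and caches.
cnn_fwd <- function(p, running, X, N, L, cfg, train = TRUE) {
  caches <- list()
  H <- X
  cin <- 4L
  for (i in seq_along(cfg$conv_channels)) {
    cv <- conv1d_fwd(H, p[[sprintf("conv%d.W", i)]], p[[sprintf("conv%d.b", i)]],
                     N, L, cfg$kernel, cfg$padding)
    bn <- batchnorm_fwd(cv$Y, p[[sprintf("bn%d.g", i)]], p[[sprintf("bn%d.b", i)]],
                        running[[i]], train = train)
    running[[i]] <- bn$running
    A <- relu_fwd(bn$Y)
    caches[[i]] <- list(Hin = H, conv = cv, bn = bn, Z = bn$Y, cin = cin)
    H <- A
    cin <- cfg$conv_channels[i]
  }
  # global max pool over positions per channel
  C <- cfg$conv_channels[length(cfg$conv_channels)]
  arr <- array(H, c(N, L, C))
  pooled <- matrix(0, N, C)
  argm <- matrix(0L, N, C)
  for (c in seq_len(C)) {
    M <- arr[, , c, drop = TRUE]
    if (N == 1L) M <- matrix(M, 1L, L)
    j <- max.col(M, ties.method = "first")
    argm[, c] <- j
    pooled[, c] <- M[cbind(seq_len(N), j)]
  }
  pred <- as.vector(pooled %*% p$fc.W + p$fc.b)
  list(pred = pred, pooled = pooled, argm = argm, caches = caches,
       running = running)
}

cnn_bwd <- function(p, fw, dpred, N, L, cfg) {
  g <- list()
  C <- cfg$conv_channels[length(cfg$conv_channels)]
  g$fc.W <- crossprod(fw$pooled, matrix(dpred, N, 1))
  g$fc.b <- sum(dpred)
  dpool <- matrix(dpred, N, 1) %*% t(p$fc.W)      # N x C
  dH <- matrix(0, N * L, C)
  rows <- (fw$argm - 1L) * N + seq_len(N)          # N x C row indices
  for (c in seq_len(C)) dH[rows[, c], c] <- dpool[, c]
  for (i in rev(seq_along(cfg$conv_channels))) {
    cl <- fw$caches[[i]]
    dZ <- dH * (cl$Z > 0)
    bnb <- batchnorm_bwd(cl$bn, p[[sprintf("bn%d.g", i)]], dZ)
    g[[sprintf("bn%d.g", i)]] <- bnb$dg
    g[[sprintf("bn%d.b", i)]] <- bnb$db
    cvb <- conv1d_bwd(cl$conv, p[[sprintf("conv%d.W", i)]], bnb$dX,
                      N, L, cfg$kernel, cfg$padding, cl$cin)
    g[[sprintf("conv%d.W", i)]] <- cvb$dW
    g[[sprintf("conv%d.b", i)]] <- cvb$db
    dH <- cvb$dX
  }
  g
}

#' Pearson correlation coefficient
#'
#' Standard Pearson r with explicit guards: both vectors must have the
#' same length (>= 2) and neither may be constant (the correlation is
#' undefined there, and silent NA propagation would mask real failures in
#' early-stopping logic).
#'
#' @param pred,truth numeric vectors of equal length.
#' @return scalar in [-1, 1].
#' @export
pearson <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (length(pred) < 2) stop("need at least 2 observations")
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0) {
    stop("Pearson correlation undefined for a constant vector")
  }
  stats::cor(pred, truth)
}

#' Fit a convolutional sequence-to-expression regressor
#'
#' Trains the 1D-CNN described above on (sequence, expression) pairs.
#' Data are shuffled once and partitioned train/validation/test by
#' \code{split} (default 0.56 / 0.24 / 0.20); the weights achieving the
#' best validation Pearson are retained, training stops early after
#' \code{patience} epochs without improvement, and the untouched test
#' split is scored once at the end.
#'
#' @param x character vector of equal-length DNA sequences.
#' @param y numeric expression values, one per sequence (log scale
#'   recommended).
#' @param conv_channels output channels of the four (or fewer) conv
#'   blocks; default \code{c(100, 200, 200, 10)}.
#' @param kernel,padding convolution kernel size and zero padding
#'   (defaults 5 and 2; stride is 1).
#' @param batch_size minibatch size (default 64).
#' @param epochs maximum training epochs (default 200).
#' @param lr Adam learning rate (default 1e-5).
#' @param patience early-stopping patience in epochs (default 50).
#' @param checkpoint_every if \code{checkpoint_dir} is given, weights are
#'   saved there every this many epochs (default 20).
#' @param checkpoint_dir optional directory for periodic weight dumps.
#' @param split length-3 proportions (train, validation, test) summing
#'   to 1.
#' @param seed integer seed for the split, initialisation and batching.
#' @param verbose print per-epoch progress.
#' @return object of class \code{expr_cnn}: list with \code{params} (best
#'   weights), \code{running} (batch-norm statistics), \code{config},
#'   \code{log} (epoch, train_loss, val_pearson), \code{best_epoch},
#'   \code{test_pearson}, \code{split_id}.
#' @seealso [predict.expr_cnn()], [pearson()]
#' @export
expr_cnn <- function(x, y, conv_channels = c(100, 200, 200, 10),
                     kernel = 5, padding = 2, batch_size = 64,
                     epochs = 200, lr = 1e-5, patience = 50,
                     checkpoint_every = 20, checkpoint_dir = NULL,
                     split = c(0.56, 0.24, 0.20), seed = 0,
                     verbose = FALSE) {
  stopifnot(is.character(x), is.numeric(y), length(x) == length(y))
  if (abs(sum(split) - 1) > 1e-8 || length(split) != 3) {
    stop("split must be three proportions summing to 1")
  }
  if (patience > epochs) stop("patience must not exceed epochs")
  if (stats::sd(y) == 0) stop("expression values are constant; Pearson undefined")
  L <- unique(nchar(x))
  if (length(L) != 1L) stop("all sequences must have the same length")
  N_all <- length(x)
  cfg <- list(L = L, conv_channels = conv_channels, kernel = kernel,
              stride = 1L, padding = padding, batch_size = batch_size,
              epochs = epochs, lr = lr, patience = patience,
              checkpoint_every = checkpoint_every, split = split,
              seed = seed)
  Xall <- matrix(encode_onehot(x), N_all * L, 4L)
  # train on the standardised target (scale-free optimisation); the
  # centring constants are stored and predictions de-standardised
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  y <- (y - y_center) / y_scale

  fit <- with_seed(seed, {
    ord <- sample.int(N_all)
    n_tr <- round(split[1] * N_all)
    n_va <- round(split[2] * N_all)
    id_tr <- ord[seq_len(n_tr)]
    id_va <- ord[n_tr + seq_len(n_va)]
    id_te <- ord[(n_tr + n_va + 1L):N_all]
    p <- cnn_init_params(conv_channels, kernel, seed)
    running <- cnn_init_running(conv_channels)
    opt <- adam_init(p)
    log_df <- data.frame(epoch = integer(), train_loss = numeric(),
                         val_pearson = numeric())
    best <- list(r = -Inf, params = p, running = running, epoch = 0L)
    since_best <- 0L
    for (ep in seq_len(epochs)) {
      bord <- sample(id_tr)
      nb <- max(1L, length(bord) %/% batch_size)
      losses <- numeric(0)
      for (b in seq_len(nb)) {
        take <- bord[((b - 1L) * batch_size + 1L):min(b * batch_size, length(bord))]
        Nb <- length(take)
        rows <- as.vector(outer(take, (seq_len(L) - 1L) * N_all, "+"))
        fw <- cnn_fwd(p, running, Xall[rows, , drop = FALSE], Nb, L, cfg,
                      train = TRUE)
        running <- fw$running
        err <- fw$pred - y[take]
        losses <- c(losses, mean(err^2))
        grads <- cnn_bwd(p, fw, 2 * err / Nb, Nb, L, cfg)
        up <- adam_step(p, grads, opt, lr)
        p <- up$params
        opt <- up$state
      }
      val_pred <- cnn_predict_mat(p, running, Xall, N_all, L, cfg, id_va)
      vr <- pearson(val_pred, y[id_va])
      log_df[nrow(log_df) + 1L, ] <- list(ep, mean(losses), vr)
      if (verbose) message(sprintf("epoch %3d  mse %.4f  val r %.3f",
                                   ep, mean(losses), vr))
      if (vr > best$r) {
        best <- list(r = vr, params = p, running = running, epoch = ep)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
      if (!is.null(checkpoint_dir) && ep %% checkpoint_every == 0L) {
        dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
        saveRDS(list(params = p, running = running, epoch = ep),
                file.path(checkpoint_dir, sprintf("epoch_%04d.rds", ep)))
      }
      if (since_best >= patience) break
    }
    te_pred <- cnn_predict_mat(best$params, best$running, Xall, N_all, L,
                               cfg, id_te)
    list(params = best$params, running = best$running,
         best_epoch = best$epoch, log = log_df,
         test_pearson = pearson(te_pred, y[id_te]),
         split_id = list(train = id_tr, val = id_va, test = id_te))
  })

  structure(c(fit, list(config = cfg, y_center = y_center,
                        y_scale = y_scale, call = match.call())),
            class = "expr_cnn")
}

# eval-mode predictions for a subset of sequences held in a big one-hot
# matrix (rows r = n + (l-1)*N_all), batched to bound memory
cnn_predict_mat <- function(p, running, Xall, N_all, L, cfg, ids,
                            batch = 250L) {
  out <- numeric(length(ids))
  for (start in seq(1L, length(ids), by = batch)) {
    take <- ids[start:min(start + batch - 1L, length(ids))]
    Nb <- length(take)
    rows <- as.vector(outer(take, (seq_len(L) - 1L) * N_all, "+"))
    fw <- cnn_fwd(p, running, Xall[rows, , drop = FALSE], Nb, L, cfg,
                  train = FALSE)
    out[start:(start + Nb - 1L)] <- fw$pred
  }
  out
}

#' Predict expression for new sequences
#'
#' Runs the trained CNN in evaluation mode (frozen batch-norm statistics),
#' so predictions are deterministic and invariant to how the input is
#' batched.
#'
#' @param object a fitted [expr_cnn()] model.
#' @param newdata character vector of sequences of the training length.
#' @param ... unused.
#' @return numeric vector of predicted expression values.
#' @export
predict.expr_cnn <- function(object, newdata, ...) {
  stopifnot(is.character(newdata), length(newdata) >= 1)
  L <- object$config$L
  if (any(nchar(newdata) != L)) {
    stop("sequence length mismatch: model was trained on length ", L)
  }
  N <- length(newdata)
  Xall <- matrix(encode_onehot(newdata), N * L, 4L)
  raw <- cnn_predict_mat(object$params, object$running, Xall, N, L,
                         object$config, seq_len(N))
  raw * object$y_scale + object$y_center
}

#' @export
print.expr_cnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0(
    "CNN expression predictor (L = %d)\n",
    "  conv channels %s, kernel %d, pad %d; global max pool; linear head\n",
    "  trained %d epochs (best validation epoch %d, val r = %.3f)\n",
    "  test Pearson r = %.3f\n"),
    cfg$L, paste(cfg$conv_channels, collapse = "-"), cfg$kernel,
    cfg$padding, nrow(x$log), x$best_epoch, max(x$log$val_pearson),
    x$test_pearson))
  invisible(x)
}

#' @export
plot.expr_cnn <- function(x, ...) {
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(x$log$epoch, x$log$train_loss, type = "l",
                 xlab = "epoch", ylab = "training MSE", ...)
  graphics::plot(x$log$epoch, x$log$val_pearson, type = "l",
                 xlab = "epoch", ylab = "validation Pearson r", ...)
  invisible(x)
}
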