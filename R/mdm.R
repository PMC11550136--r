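#' Fit a multinomial diffusion model to fixed-length DNA sequences
#'
#' Trains a categorical diffusion generative model on a corpus of
#' equal-length sequences. The forward process corrupts each one-hot base
#' towards the uniform distribution under a noise schedule; a block-local
#' transformer is trained to predict the clean sequence \eqn{\hat x_0}
#' from a noised state \eqn{x_t} and its step t, minimising the
#' variational bound
#' \deqn{L = E_q\{-\log p_\theta(x_0|x_1) +
#'       \sum_{t\ge2} KL[q(x_{t-1}|x_t,x_0)\,\|\,q(x_{t-1}|x_t,\hat x_0)]\}}
#' with one uniformly drawn step per example per update (Adam optimiser).
#' By default the variational term is complemented by an auxiliary
#' denoising cross-entropy \eqn{-\sum_k x_{0,k}\log\hat x_{0,k}} at the
#' sampled step (weight \code{aux_ce}), the standard hybrid objective for
#' discrete diffusion: the per-step KL alone carries very weak gradient
#' towards conditioning on \eqn{x_t} (its \eqn{x_t}-factor dominates both
#' posteriors), so pure-bound training needs far more updates than a
#' desk-scale budget provides. \code{aux_ce = 0} recovers the pure bound.
#' A held-out fraction of sequences is scored each epoch; the logged
#' losses are the variational terms only, so they are comparable across
#' \code{aux_ce} settings.
#'
#' @param x character vector of equal-length \{A,C,G,T\} sequences.
#' @param T_steps diffusion steps (default 100).
#' @param schedule \code{"cosine"} (default) or \code{"linear"}.
#' @param layers,heads,embed_dim,ff_dim,local_size,emb_kernel denoiser architecture;
#'   see [denoiser_init()]. Defaults: 12 layers, 16 heads, width 128,
#'   block 25 (or L when 25 does not divide L).
#' @param epochs training epochs (default 100).
#' @param batch_size minibatch size (default 64).
#' @param lr Adam learning rate (default 1e-4).
#' @param clip_norm global gradient-norm clip (default 1; \code{Inf}
#'   disables). The variational loss has log-barrier cliffs where the
#'   model posterior underweights the true one; clipping keeps Adam
#'   stable there.
#' @param warmup linear learning-rate warmup steps (default 100).
#' @param aux_ce weight of the auxiliary denoising cross-entropy added to
#'   the variational step loss during training (default 1; 0 disables).
#' @param eval_fraction held-out fraction for the per-epoch evaluation
#'   loss (default 0.10, i.e. 90/10 train/eval).
#' @param max_steps optional cap on total optimiser steps (for small
#'   calibration runs); training stops once reached.
#' @param t_mode \code{"stochastic"} (one uniform t per example, default)
#'   or \code{"full"} (sum the loss over every t = 1..T per batch; only
#'   sensible for desk-scale T).
#' @param seed integer seed governing the split, initialisation, noise
#'   draws and batch order.
#' @param verbose print per-epoch losses.
#' @return object of class \code{mdm}: list with \code{denoiser},
#'   \code{schedule}, \code{config}, \code{log} (data.frame: epoch,
#'   train_loss, eval_loss), \code{n_train}, \code{n_eval}.
#' @seealso [simulate.mdm()], [mdm_save()], [step_loss()]
#' @examples
#' \donttest{
#' fit <- mdm(rep("ACGTACGTACGTACGTACGT", 128), T_steps = 10, layers = 1,
#'            heads = 2, embed_dim = 16, epochs = 1, seed = 1)
#' simulate(fit, nsim = 3, seed = 1)
#' }
#' @export
mdm <- function(x, T_steps = 100, schedule = c("cosine", "linear"),
                layers = 12, heads = 16, embed_dim = 128,
                ff_dim = 2 * embed_dim,
                local_size = NULL, epochs = 100, batch_size = 64,
                emb_kernel = 7,
                lr = 1e-4, clip_norm = 1, warmup = 100, aux_ce = 1,
                eval_fraction = 0.10, max_steps = Inf,
                t_mode = c("stochastic", "full"), seed = 0,
                verbose = FALSE) {
  schedule <- match.arg(schedule)
  t_mode <- match.arg(t_mode)
  stopifnot(is.character(x), length(x) >= 1)
  if (!(eval_fraction > 0 && eval_fraction < 1)) {
    stop("eval_fraction must be in (0, 1)")
  }
  L <- unique(nchar(x))
  if (length(L) != 1L) stop("all sequences must have the same length")
  if (is.null(local_size)) local_size <- if (L %% 25 == 0) 25 else L
  if (epochs > 0 && length(x) < batch_size) {
    stop("need at least batch_size sequences")
  }

  s <- build_schedule(T_steps, schedule)
  model <- denoiser_init(L, T_steps, layers = layers, heads = heads,
                         embed_dim = embed_dim, ff_dim = ff_dim,
                         local_size = local_size, emb_kernel = emb_kernel,
                         seed = seed)
  idxmat <- seq_to_index(x)      # N x L categories
  N_all <- nrow(idxmat)

  log_df <- data.frame(epoch = integer(), train_loss = numeric(),
                       eval_loss = numeric())
  n_eval <- max(1L, round(eval_fraction * N_all))
  out <- with_seed(seed, {
    eval_id <- sample.int(N_all, n_eval)
    train_id <- setdiff(seq_len(N_all), eval_id)
    opt <- adam_init(model$params)
    steps_done <- 0L
    for (ep in seq_len(epochs)) {
      if (steps_done >= max_steps) break
      ord <- sample(train_id)
      nb <- max(1L, length(ord) %/% batch_size)
      ep_losses <- numeric(0)
      for (b in seq_len(nb)) {
        if (steps_done >= max_steps) break
        take <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, length(ord))]
        res <- mdm_train_step(model, idxmat[take, , drop = FALSE], s,
                              t_mode, aux_ce)
        if (!is.finite(res$loss)) {
          stop(sprintf("non-finite loss at epoch %d step %d; aborting", ep, b))
        }
        grads <- res$grads
        if (is.finite(clip_norm)) {
          nrm <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
          if (nrm > clip_norm) {
            grads <- lapply(grads, function(g) g * clip_norm / nrm)
          }
        }
        lr_t <- lr * min(1, (steps_done + 1L) / max(1L, warmup))
        up <- adam_step(model$params, grads, opt, lr_t)
        model$params <- up$params
        opt <- up$state
        ep_losses <- c(ep_losses, res$loss)
        steps_done <- steps_done + 1L
      }
      ev <- mdm_eval_loss(model, idxmat[eval_id, , drop = FALSE], s, t_mode)
      log_df[nrow(log_df) + 1L, ] <- list(ep, mean(ep_losses), ev)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  eval %.4f",
                        ep, mean(ep_losses), ev))
      }
    }
    list(model = model, log = log_df, n_train = length(train_id),
         n_eval = n_eval)
  })

  structure(list(denoiser = out$model, schedule = s,
                 config = list(L = L, T_steps = T_steps, schedule = schedule,
                               layers = layers, heads = heads,
                               embed_dim = embed_dim, ff_dim = ff_dim,
                               local_size = local_size,
                               emb_kernel = emb_kernel, epochs = epochs,
                               batch_size = batch_size, lr = lr,
                               clip_norm = clip_norm, warmup = warmup,
                               aux_ce = aux_ce,
                               eval_fraction = eval_fraction, seed = seed,
                               t_mode = t_mode),
                 log = out$log, n_train = out$n_train, n_eval = out$n_eval,
                 call = match.call()),
            class = "mdm")
}

# one optimisation step: sample t and x_t, compute loss and gradients.
# The reported loss is the variational term; gradients additionally carry
# aux_ce times the denoising cross-entropy (whose logit gradient is the
# numerically benign probs - x0).
mdm_train_step <- function(model, idx_batch, s, t_mode, aux_ce = 0) {
  N <- nrow(idx_batch)
  L <- ncol(idx_batch)
  x0m <- onehot_rows(as.vector(idx_batch), N * L)
  if (t_mode == "stochastic") {
    tv_list <- list(sample.int(s$T, N, replace = TRUE))
  } else {
    tv_list <- lapply(seq_len(s$T), function(t) rep(t, N))
  }
  total <- 0
  grads <- NULL
  for (tv in tv_list) {
    ab <- rep(s$alpha_bar[tv], times = L)
    qt <- ab * x0m + (1 - ab) / s$K
    xtm <- onehot_rows(sample_categorical_rows(qt), N * L)
    fw <- denoiser_fwd(model, xtm, tv, N, L)
    lg <- step_loss_core(x0m, xtm, fw$probs, tv, s, N, L, grad = TRUE)
    dlogits <- softmax_bwd_rows(fw$probs, lg$grad)
    if (aux_ce > 0) {
      dlogits <- dlogits + aux_ce * (fw$probs - x0m) / N
    }
    g <- denoiser_bwd(model, fw, dlogits)
    total <- total + lg$loss
    grads <- if (is.null(grads)) g else mapply(`+`, grads, g, SIMPLIFY = FALSE)
  }
  list(loss = total, grads = grads)
}

mdm_eval_loss <- function(model, idx_eval, s, t_mode) {
  N <- nrow(idx_eval)
  L <- ncol(idx_eval)
  x0m <- onehot_rows(as.vector(idx_eval), N * L)
  tv <- if (t_mode == "full") NULL else sample.int(s$T, N, replace = TRUE)
  if (is.null(tv)) {
    tot <- 0
    for (t in seq_len(s$T)) {
      tvv <- rep(t, N)
      ab <- rep(s$alpha_bar[tvv], times = L)
      xtm <- onehot_rows(sample_categorical_rows(ab * x0m + (1 - ab) / s$K), N * L)
      fw <- denoiser_fwd(model, xtm, tvv, N, L, keep_cache = FALSE)
      tot <- tot + step_loss_core(x0m, xtm, fw$probs, tvv, s, N, L)$loss
    }
    tot
  } else {
    ab <- rep(s$alpha_bar[tv], times = L)
    xtm <- onehot_rows(sample_categorical_rows(ab * x0m + (1 - ab) / s$K), N * L)
    fw <- denoiser_fwd(model, xtm, tv, N, L, keep_cache = FALSE)
    step_loss_core(x0m, xtm, fw$probs, tv, s, N, L)$loss
  }
}

#' Sample novel sequences from a fitted diffusion model
#'
#' Ancestral sampling: each position starts i.i.d. uniform over the four
#' bases (\eqn{x_T} from a 0-order Markov chain); for t = T..2 the
#' denoiser predicts \eqn{\hat x_0} and \eqn{x_{t-1}} is drawn from the
#' categorical posterior \eqn{q(x_{t-1}|x_t,\hat x_0)}; at t = 1 the
#' clean sequence is drawn from \eqn{C(\hat x_0)} (or taken as its argmax
#' with \code{argmax_final = TRUE}). Deterministic given (model, nsim,
#' seed).
#'
#' @param object a fitted [mdm()] model.
#' @param nsim number of sequences to generate.
#' @param seed integer seed (required for reproducibility; default 0).
#' @param argmax_final take the argmax of \eqn{\hat x_0} at the last step
#'   instead of sampling.
#' @param batch internal batching of the reverse process (default 500).
#' @param ... unused.
#' @return character vector of \code{nsim} sequences of the trained
#'   length.
#' @export
simulate.mdm <- function(object, nsim = 1, seed = 0, argmax_final = FALSE,
                         batch = 500, ...) {
  stopifnot(nsim >= 1)
  model <- object$denoiser
  s <- object$schedule
  L <- object$config$L
  with_seed(seed, {
    res <- character(0)
    remaining <- nsim
    while (remaining > 0) {
      N <- min(batch, remaining)
      k <- sample.int(4L, N * L, replace = TRUE)
      xtm <- onehot_rows(k, N * L)
      for (t in seq(s$T, 2L)) {
        fw <- denoiser_fwd(model, xtm, rep(t, N), N, L, keep_cache = FALSE)
        tv <- rep(t, N * L)
        a <- s$alpha[tv]
        ab_prev <- c(1, s$alpha_bar)[tv]
        theta <- (a * xtm + (1 - a) / s$K) *
                 (ab_prev * fw$probs + (1 - ab_prev) / s$K) + EPS_LOG
        xtm <- onehot_rows(sample_categorical_rows(theta), N * L)
      }
      fw <- denoiser_fwd(model, xtm, rep(1L, N), N, L, keep_cache = FALSE)
      k0 <- if (argmax_final) max.col(fw$probs, ties.method = "first")
            else sample_categorical_rows(fw$probs)
      res <- c(res, decode_onehot(field_array(onehot_rows(k0, N * L), N, L)))
      remaining <- remaining - N
    }
    res
  })
}

#' @export
print.mdm <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0(
    "Multinomial diffusion model (L = %d, T = %d, %s schedule)\n",
    "  denoiser: %d-layer transformer, %d heads, width %d, block %d\n",
    "  trained:  %d epochs on %d sequences (%d held out)\n"),
    cfg$L, cfg$T_steps, cfg$schedule, cfg$layers, cfg$heads, cfg$embed_dim,
    cfg$local_size, nrow(x$log), x$n_train, x$n_eval))
  if (nrow(x$log) > 0) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  final losses: train %.4f, eval %.4f (nats/sequence)\n",
                last$train_loss, last$eval_loss))
  }
  invisible(x)
}

#' @export
summary.mdm <- function(object, ...) {
  print(object)
  if (nrow(object$log) > 0) {
    cat("\nTraining log (last 5 epochs):\n")
    print(utils::tail(object$log, 5), row.names = FALSE)
  }
  invisible(object$log)
}

#' @export
plot.mdm <- function(x, ...) {
  if (nrow(x$log) == 0) stop("no training log to plot")
  graphics::matplot(x$log$epoch, cbind(x$log$train_loss, x$log$eval_loss),
                    type = "l", lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "variational loss (nats/seq)", ...)
  graphics::legend("topright", c("train", "eval"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Save / load a fitted diffusion model checkpoint
#'
#' Writes a checkpoint directory holding the denoiser weights
#' (\code{weights.rds}), the configuration (\code{config.json}) and the
#' per-epoch training log (\code{log.tsv}). A reloaded checkpoint samples
#' bit-identically under the same seed.
#'
#' @param object a fitted [mdm()] model.
#' @param dir checkpoint directory (created if missing).
#' @return \code{mdm_save}: invisibly, \code{dir}; \code{mdm_load}: the
#'   restored \code{mdm} object.
#' @export
mdm_save <- function(object, dir) {
  stopifnot(inherits(object, "mdm"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(object$denoiser$params, file.path(dir, "weights.rds"))
  jsonlite::write_json(object$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(object$log, file.path(dir, "log.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname mdm_save
#' @export
mdm_load <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  model <- denoiser_init(cfg$L, cfg$T_steps, layers = cfg$layers,
                         heads = cfg$heads, embed_dim = cfg$embed_dim,
                         ff_dim = cfg$ff_dim, local_size = cfg$local_size,
                         emb_kernel = if (is.null(cfg$emb_kernel)) 7 else cfg$emb_kernel,
                         seed = cfg$seed)
  model$params <- readRDS(file.path(dir, "weights.rds"))
  log_df <- utils::read.table(file.path(dir, "log.tsv"), sep = "\t",
                              header = TRUE)
  structure(list(denoiser = model, schedule = build_schedule(cfg$T_steps,
                                                             cfg$schedule),
                 config = cfg, log = log_df,
                 n_train = NA_integer_, n_eval = NA_integer_,
                 call = NULL),
            class = "mdm")
}
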