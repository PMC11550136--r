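# Categorical (multinomial) diffusion over DNA bases, K = 4.
#
# All public functions take and return N x L x 4 arrays ("fields"): a
# one-hot batch is a field whose rows are vertices of the simplex, a
# probability field has rows on the simplex. Internally fields are handled
# as (N*L) x 4 matrices with row index r = n + (l-1)*N (column-major over
# the first two array dimensions), so reshaping is free.

EPS_LOG <- 1e-12

as_field_mat <- function(x) {
  stopifnot(is.array(x), length(dim(x)) == 3L, dim(x)[3] == 4L)
  list(mat = matrix(x, dim(x)[1] * dim(x)[2], 4L), N = dim(x)[1], L = dim(x)[2])
}

field_array <- function(mat, N, L) array(mat, dim = c(N, L, 4L))

# expand per-example values (length N or 1) to one value per (n,l) row
per_row <- function(v, N, L) {
  if (length(v) == 1L) rep(v, N * L) else rep(v, times = L)
}

#' One forward diffusion step: q(x_t | x_{t-1})
#'
#' Given the categorical parameters of the previous state, returns the
#' parameters of the next noised state:
#' \eqn{(1-\beta_t)\,x_{t-1} + \beta_t/K}. With probability
#' \eqn{\beta_t} the base is resampled uniformly, otherwise kept.
#'
#' @param prev N x L x 4 field (one-hot or soft) for \eqn{x_{t-1}}.
#' @param t step index, scalar or one per sequence (length N), in 1..T.
#' @param s a [build_schedule()] object.
#' @return N x L x 4 probability field.
#' @export
forward_step_probs <- function(prev, t, s) {
  t <- check_t(t, s)
  f <- as_field_mat(prev)
  b <- per_row(s$beta[t], f$N, f$L)
  field_array((1 - b) * f$mat + b / s$K, f$N, f$L)
}

#' Closed-form marginal: q(x_t | x_0)
#'
#' The t-step corruption collapses to
#' \eqn{\bar\alpha_t\,x_0 + (1-\bar\alpha_t)/K}: the original base survives
#' with probability \eqn{\bar\alpha_t}, otherwise the position is uniform.
#'
#' @param x0 N x L x 4 one-hot batch of clean sequences.
#' @inheritParams forward_step_probs
#' @return N x L x 4 probability field.
#' @export
marginal_probs <- function(x0, t, s) {
  t <- check_t(t, s)
  f <- as_field_mat(x0)
  ab <- per_row(s$alpha_bar[t], f$N, f$L)
  field_array(ab * f$mat + (1 - ab) / s$K, f$N, f$L)
}

#' Categorical posterior: q(x_{t-1} | x_t, x_0)
#'
#' The exact reverse-step distribution given the current noised state and
#' the clean datum (or a soft prediction \eqn{\hat x_0} of it):
#' \deqn{\tilde\theta \propto [\alpha_t x_t + (1-\alpha_t)/K] \odot
#'       [\bar\alpha_{t-1} x_0 + (1-\bar\alpha_{t-1})/K]}
#' normalised over the K = 4 bases. For t = 1, \eqn{\bar\alpha_0 = 1}.
#'
#' @param xt N x L x 4 one-hot batch of the state at step t.
#' @param x0 N x L x 4 field: the clean one-hot batch or a soft
#'   \eqn{\hat x_0} prediction.
#' @inheritParams forward_step_probs
#' @return N x L x 4 probability field.
#' @export
posterior_probs <- function(xt, x0, t, s) {
  t <- check_t(t, s)
  ft <- as_field_mat(xt)
  f0 <- as_field_mat(x0)
  stopifnot(ft$N == f0$N, ft$L == f0$L)
  a <- per_row(s$alpha[t], ft$N, ft$L)
  ab_prev <- per_row(c(1, s$alpha_bar)[t], ft$N, ft$L)
  theta <- (a * ft$mat + (1 - a) / s$K) *
           (ab_prev * f0$mat + (1 - ab_prev) / s$K)
  z <- rowSums(theta)
  if (any(z <= 0)) {       # unreachable while beta_t < 1; guard regardless
    theta[z <= 0, ] <- theta[z <= 0, ] + EPS_LOG
    z <- rowSums(theta)
  }
  field_array(theta / z, ft$N, ft$L)
}

# internal core: variational step loss and its gradient wrt xhat0.
# x0m, xtm, p0m: (N*L) x 4 matrices; tv: length-N (or scalar) step vector.
# For t >= 2 the per-position term is KL[q(x_{t-1}|x_t,x0) || q(.|x_t,xhat0)];
# for t = 1 it is the reconstruction term -sum_k x0_k log xhat0_k.
# Loss = mean over sequences of the position-summed terms.
step_loss_core <- function(x0m, xtm, p0m, tv, s, N, L, grad = FALSE) {
  tv <- check_t(tv, s)
  a <- per_row(s$alpha[tv], N, L)
  ab_prev <- per_row(c(1, s$alpha_bar)[tv], N, L)
  t1 <- per_row(tv, N, L) == 1L

  p0c <- pmax(p0m, EPS_LOG)
  # posterior under true x0
  fac_t <- a * xtm + (1 - a) / s$K
  th_q <- fac_t * (ab_prev * x0m + (1 - ab_prev) / s$K) + EPS_LOG
  q <- th_q / rowSums(th_q)
  # posterior under predicted xhat0
  u <- ab_prev * p0c + (1 - ab_prev) / s$K
  th_p <- fac_t * u + EPS_LOG
  Z <- rowSums(th_p)
  p <- th_p / Z

  kl_rows <- rowSums(q * (log(pmax(q, EPS_LOG)) - log(pmax(p, EPS_LOG))))
  l0_rows <- -rowSums(x0m * log(p0c))
  rows <- ifelse(t1, l0_rows, kl_rows)
  loss <- sum(rows) / N

  out <- list(loss = loss)
  if (grad) {
    # d KL / d xhat0 = ab_prev * fac_t * (1 - q/p) / Z   (via theta, Z chain)
    g_kl <- ab_prev * fac_t * (1 - q / p) / Z
    g_l0 <- -x0m / p0c
    g <- ifelse(matrix(t1, nrow(p0m), 4L), g_l0, g_kl) / N
    g[p0m <= EPS_LOG & g < 0] <- 0   # clamped entries do not propagate
    out$grad <- g
  }
  out
}

#' Variational step loss L_{t-1}
#'
#' For \code{t >= 2}, the per-position KL divergence between the true
#' posterior \eqn{q(x_{t-1}|x_t,x_0)} and the model posterior
#' \eqn{q(x_{t-1}|x_t,\hat x_0)}, summed over positions and averaged over
#' the batch. For \code{t = 1}, the reconstruction term
#' \eqn{L_0 = -\sum_k x_{0,k}\log \hat x_{0,k}} (equal to
#' \eqn{KL[C(x_0)\,\|\,\hat x_0]} since \eqn{x_0} is one-hot).
#'
#' @param x0 true clean one-hot batch, N x L x 4.
#' @param xt noised one-hot batch at step t.
#' @param t step index, scalar or length N.
#' @param xhat0 the denoiser's prediction of \eqn{x_0}: an N x L x 4
#'   probability field. Alternatively pass \code{model} to compute it.
#' @param s a [build_schedule()] object.
#' @param model optional denoiser (see [denoiser_init()]); used to compute
#'   \code{xhat0} from \code{xt} and \code{t} when \code{xhat0} is missing.
#' @return scalar loss (nats).
#' @export
step_loss <- function(x0, xt, t, xhat0 = NULL, s, model = NULL) {
  f0 <- as_field_mat(x0)
  ft <- as_field_mat(xt)
  stopifnot(f0$N == ft$N, f0$L == ft$L)
  if (is.null(xhat0)) {
    if (is.null(model)) stop("supply either xhat0 or model")
    xhat0 <- denoise_predict(xt, t, model)
  }
  fp <- as_field_mat(xhat0)
  step_loss_core(f0$mat, ft$mat, fp$mat, t, s, f0$N, f0$L)$loss
}

# internal: one categorical draw per row of a probability matrix
sample_categorical_rows <- function(pm) {
  pm <- pm / rowSums(pm)
  u <- stats::runif(nrow(pm))
  c1 <- pm[, 1]; c2 <- c1 + pm[, 2]; c3 <- c2 + pm[, 3]
  1L + (u > c1) + (u > c2) + (u > c3)
}

# internal: one-hot (N*L) x 4 matrix from row categories
onehot_rows <- function(k, nrow) {
  m <- matrix(0, nrow, 4L)
  m[cbind(seq_len(nrow), k)] <- 1
  m
}
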