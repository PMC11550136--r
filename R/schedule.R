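#' Build a diffusion noise schedule
#'
#' Constructs the per-step resampling probabilities \eqn{\beta_t} and the
#' derived quantities \eqn{\alpha_t = 1 - \beta_t},
#' \eqn{\bar\alpha_t = \prod_{\tau \le t} \alpha_\tau} for a categorical
#' diffusion over K = 4 bases. \eqn{\bar\alpha_t} is the fraction of the
#' original base identity surviving at step t; it decreases strictly to
#' (approximately) zero at \code{t = T}, where the marginal is uniform.
#'
#' Two schedule shapes are provided:
#' \describe{
#'   \item{\code{"cosine"} (default)}{the squared-cosine \eqn{\bar\alpha}
#'     schedule with offset s = 0.008, \eqn{\bar\alpha_t = f(t)/f(0)},
#'     \eqn{f(t) = \cos^2(\pi/2 \cdot (t/T + s)/(1 + s))}; \eqn{\beta_t}
#'     is recovered as \eqn{1 - \bar\alpha_t/\bar\alpha_{t-1}} and capped
#'     at 0.999 so every \eqn{\alpha_t > 0}.}
#'   \item{\code{"linear"}}{\eqn{\beta_t = 1/(T - t + 1)}, giving exactly
#'     linear decay \eqn{\bar\alpha_t = 1 - t/T} (note \eqn{\beta_T = 1}:
#'     the terminal state is exactly uniform).}
#' }
#'
#' @param T_steps number of diffusion steps (>= 1).
#' @param kind \code{"cosine"} or \code{"linear"}.
#' @return object of class \code{noise_schedule}: list with \code{T},
#'   \code{kind}, \code{beta}, \code{alpha}, \code{alpha_bar}, \code{K}.
#' @examples
#' s <- build_schedule(100)
#' s$alpha_bar[100]   # essentially zero: terminal state is uniform
#' @export
build_schedule <- function(T_steps, kind = c("cosine", "linear")) {
  kind <- match.arg(kind)
  if (!is.numeric(T_steps) || T_steps < 1 || T_steps != round(T_steps)) {
    stop("T_steps must be a positive integer")
  }
  T_steps <- as.integer(T_steps)
  if (kind == "cosine") {
    s <- 0.008
    f <- function(t) cos((t / T_steps + s) / (1 + s) * pi / 2)^2
    ab <- f(seq_len(T_steps)) / f(0)
    beta <- 1 - ab / c(1, ab[-T_steps])
    beta <- pmin(pmax(beta, 1e-8), 0.999)
  } else {
    beta <- 1 / (T_steps - seq_len(T_steps) + 1)
  }
  alpha <- 1 - beta
  alpha_bar <- cumprod(alpha)
  structure(list(T = T_steps, kind = kind, beta = beta, alpha = alpha,
                 alpha_bar = alpha_bar, K = 4L),
            class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("noise_schedule: %s, T = %d, alpha_bar[T] = %.3g\n",
              x$kind, x$T, x$alpha_bar[x$T]))
  invisible(x)
}

# internal: validate a step index (scalar or vector) against a schedule
check_t <- function(t, s, lo = 1L) {
  if (any(t < lo) || any(t > s$T)) {
    stop(sprintf("diffusion step t out of range [%d, %d]", lo, s$T))
  }
  as.integer(t)
}
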