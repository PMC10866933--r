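#' Derive a stage-specific RNG seed from a master seed
#'
#' All stochastic stages of the pipeline draw their seed from one master seed
#' through this deterministic map, so each stage is independently reproducible
#' while a single `--seed` controls the whole run. The map is a fixed affine
#' hash reduced modulo a Mersenne prime, keeping results inside the 32-bit
#' integer range R requires.
#'
#' @param seed master seed (integer).
#' @param stage integer stage code (any small integer; stages use distinct
#'   codes).
#' @param index optional sub-index (e.g. ROI number) for per-item streams.
#' @return a positive integer seed `< 2^31`.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  p <- 2147483629
  v <- (as.numeric(seed) %% p) * 48271 + as.numeric(stage) * 16807 +
    as.numeric(index) * 69621 + 1
  as.integer(v %% p) + 1L
}

#' Truncated-at-zero normal deviates
#'
#' Draws from a normal distribution conditioned on being non-negative, via
#' inverse-CDF sampling. Used for marker intensities, which cannot be
#' negative.
#'
#' @param n number of draws.
#' @param mean,sd normal parameters (vectorised).
#' @return numeric vector of non-negative deviates.
#' @keywords internal
rtrunc0 <- function(n, mean, sd) {
  sd <- rep_len(sd, n)
  mean <- rep_len(mean, n)
  out <- numeric(n)
  pos <- sd > 0
  if (any(pos)) {
    lo <- stats::pnorm(0, mean[pos], sd[pos])
    u <- stats::runif(sum(pos), lo, 1)
    out[pos] <- stats::qnorm(u, mean[pos], sd[pos])
  }
  if (any(!pos)) out[!pos] <- pmax(mean[!pos], 0)
  # guard against qnorm(1 - eps) overshoot
  pmax(out, 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
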