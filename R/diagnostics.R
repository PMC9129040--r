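#' Gelman-Rubin potential scale reduction factor
#'
#' Between/within-chain variance ratio for one parameter:
#' `Rhat = sqrt((W + var(chain means)) / W)` with `W` the mean within-chain
#' variance. This variant equals the classic pooled-variance PSRF up to
#' `O(1/n)`, is exactly 1 when the chains are identical copies, and is
#' always >= 1. Values near 1 indicate that between- and within-chain
#' variability agree (the reference convergence threshold is 1.05).
#'
#' @param chains a matrix with one column per chain (equal lengths), or a
#'   list of equal-length numeric vectors.
#' @return The scale reduction factor (scalar >= 1).
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) {
    if (length(unique(lengths(chains))) != 1)
      stop("chains must have equal retained lengths")
    chains <- do.call(cbind, chains)
  }
  if (!is.matrix(chains) || ncol(chains) < 2)
    stop("need at least 2 chains for the Gelman-Rubin diagnostic")
  W <- mean(apply(chains, 2, stats::var))
  B_over_n <- stats::var(colMeans(chains))
  if (W == 0) return(if (B_over_n == 0) 1 else Inf)
  sqrt((W + B_over_n) / W)
}

#' Geweke within-chain stationarity diagnostic
#'
#' Z-score comparing the means of an early and a late chain window,
#' `z = (mean_first - mean_last) / sqrt(se1^2 + se2^2)`, with squared
#' standard errors taken from each window's spectral density at frequency
#' zero (estimated from an AIC-selected autoregressive fit), so
#' autocorrelation inflates the standard errors. For a stationary chain `z` is
#' approximately standard normal; values outside (-2, 2) indicate
#' non-stationarity. A constant chain returns 0 with a warning (0/0
#' guarded).
#'
#' @param chain numeric vector of draws.
#' @param first_frac,last_frac fractions of the chain forming the early and
#'   late windows (defaults 10% and 50%; they must not overlap).
#' @return The z-score (scalar).
#' @export
geweke <- function(chain, first_frac = 0.1, last_frac = 0.5) {
  n <- length(chain)
  if (first_frac <= 0 || last_frac <= 0 || first_frac + last_frac > 1)
    stop("windows overlap: first_frac + last_frac must be <= 1")
  n1 <- floor(n * first_frac)
  n2 <- floor(n * last_frac)
  if (n1 < 8 || n2 < 8) stop("chain too short for the requested windows")
  w1 <- chain[seq_len(n1)]
  w2 <- chain[(n - n2 + 1):n]
  if (stats::sd(chain) == 0) {
    warning("constant chain; Geweke z set to 0")
    return(0)
  }
  se2_1 <- spectrum0(w1) / n1
  se2_2 <- spectrum0(w2) / n2
  (mean(w1) - mean(w2)) / sqrt(se2_1 + se2_2)
}

# Spectral density at frequency zero from an AIC-selected autoregressive
# fit: S(0) = sigma^2_innov / (1 - sum(phi))^2, so var(mean(x)) ~ S(0)/n.
# Unbiased for white noise (order 0 selected) and robust for the positively
# autocorrelated chains MCMC produces. (Internal.)
spectrum0 <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(0)
  fit <- tryCatch(
    stats::ar(x, aic = TRUE, order.max = min(n - 1, floor(10 * log10(n)))),
    error = function(e) NULL)
  if (is.null(fit)) return(stats::var(x))
  if (fit$order == 0) return(stats::var(x))
  fit$var.pred / (1 - sum(fit$ar))^2
}
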