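#' Observation-model log-likelihood
#'
#' Total log-likelihood of observed counts under the Poisson family,
#' `y ~ Poisson(mu)`, or the negative binomial family parameterised by its
#' dispersion `r` through the success probability `P_N = r / (r + mu)`
#' (`y ~ NegBin(P_N, r)`, variance `mu + mu^2 / r`). A cell with expected
#' count 0 but a positive observation yields `-Inf` with a warning rather
#' than an error, so samplers can reject such states.
#'
#' @param counts non-negative integer counts (vector, matrix or `sgrid`).
#' @param expected non-negative expected counts, same shape.
#' @param family `"poisson"` or `"negbin"`.
#' @param r negative binomial dispersion (> 0); scalar or per-cell.
#' @return Total log-likelihood (scalar).
#' @export
#' @examples
#' log_likelihood(0, 1, "poisson")  # -1
log_likelihood <- function(counts, expected, family = c("poisson", "negbin"),
                           r = NULL) {
  family <- match.arg(family)
  y <- as.vector(if (is_sgrid(counts)) counts$values[!counts$mask]
                 else counts)
  mu <- as.vector(if (is_sgrid(expected)) expected$values[!expected$mask]
                  else expected)
  if (length(y) != length(mu)) stop("counts and expected differ in length")
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("counts must be non-negative integers")
  if (any(mu < 0)) stop("expected counts must be >= 0")
  if (any(mu == 0 & y > 0)) {
    warning("expected count 0 where observed > 0; log-likelihood is -Inf")
    return(-Inf)
  }
  if (family == "poisson")
    return(sum(stats::dpois(y, mu, log = TRUE)))
  if (is.null(r) || any(r <= 0))
    stop("negative binomial likelihood requires dispersion r > 0")
  sum(stats::dnbinom(y, size = r, mu = mu, log = TRUE))
}
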