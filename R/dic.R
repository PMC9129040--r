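#' Deviance information criterion
#'
#' Computes `pD = mean(D) - D(theta_hat)` (the effective number of
#' parameters) and `DIC = mean(D) + pD` from the recorded per-iteration
#' deviance trace and a plug-in deviance. The plug-in point `theta_hat` is
#' the component-wise posterior median: for the near-Gaussian posteriors of
#' well-identified models it coincides with the mean, while for the skewed,
#' ridge-coupled posteriors of weakly identified shape parameters (the
#' refuge and saturation constants) the mean falls off the ridge and makes
#' the plug-in — and hence pD — meaningless. For CAR models the plug-in
#' uses the posterior-median spatial field as well.
#'
#' @param samples a [sample_posterior()] result with a deviance trace.
#' @param model the `spill_model` that produced it (supplies the plug-in
#'   deviance callable).
#' @return List with elements `DIC`, `pD`, `Dbar` (mean deviance) and
#'   `Dhat` (plug-in deviance).
#' @export
compute_dic <- function(samples, model) {
  stopifnot(inherits(samples, "posterior_samples"),
            inherits(model, "spill_model"))
  dev <- unlist(samples$deviance)
  if (!length(dev) || all(is.na(dev)))
    stop("no deviance trace recorded; the model must define `deviance`")
  Dbar <- mean(dev)
  draws <- do.call(rbind, samples$chains)
  theta_hat <- apply(draws, 2, stats::median)[model$par_names]
  if (!is.null(model$from_report)) theta_hat <- model$from_report(theta_hat)
  rho_hat <- if (!is.null(samples$rho))
    apply(do.call(rbind, samples$rho), 2, stats::median) else NULL
  Dhat <- model$deviance(theta_hat, rho_hat)
  if (!is.finite(Dhat)) stop("plug-in deviance is not finite")
  pD <- Dbar - Dhat
  list(DIC = Dbar + pD, pD = pD, Dbar = Dbar, Dhat = Dhat)
}
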