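#' Prior specification for the hierarchical models
#'
#' The reference analysis prints only the dispersion prior, `r ~ unif(0,
#' 50)`; every other prior is a package default, chosen as follows and fully
#' overridable. Species contact-rate scales `B_s` get a half-normal prior
#' (positivity is implied by their multiplicative role); land-cover
#' coefficients `b0, b1, b2` get wide zero-centred normals; envenoming
#' effects and intercepts get wide normals; the CAR precision `tau` a
#' gamma(1, 0.01). The refuge fractions `q_h` and `q_s` are fraction-like
#' order-one quantities and get a log-normal(0, 1.5); the half-saturation
#' constant `c_half` is a population scale of unknown magnitude and gets a
#' wide log-normal(0, 5); power exponents a normal centred at 1; and the
#' asymptotic mixing weight `epsilon` its uniform(0, 1) support.
#'
#' Because `B_s` and the adjustment intercepts `b0_l` trade off exactly
#' (scaling every `B_s` by `k` while subtracting `log(k)` from every `b0_l`
#' leaves predictions unchanged), the prior set carries a gauge anchor: a
#' tight normal prior on the mean of the `b0_l`, which pins the scale
#' without touching identifiable combinations. Reported `B_s` are therefore
#' defined in the gauge where the intercepts average zero; the anchor must
#' be tight, because along the unidentified ridge a prior that is flat in
#' `B_s` near zero exerts a systematic volume pull of order
#' `n_species * gauge_sd^2` on `log B_s`.
#'
#' @param B_scale half-normal scale for `B_s`.
#' @param coef_sd normal sd for adjustment coefficients.
#' @param gauge_sd sd of the gauge anchor on `mean(b0_l)`; `Inf` disables it.
#' @param r_max upper bound of the uniform dispersion prior.
#' @param tau_shape,tau_rate gamma hyperparameters for the CAR precision.
#' @param env_B_sd,env_BLC_sd normal sds for envenoming species effects and
#'   land-cover intercepts.
#' @param shape_log_sd sd of the log-normal prior on the half-saturation
#'   constant (its magnitude is unknown over orders of magnitude).
#' @param refuge_log_sd sd of the log-normal prior on the refuge fractions
#'   `q_h`, `q_s` (order-one quantities).
#' @param exponent_sd sd of the normal(1, .) prior on power exponents.
#' @param warm optional named list `param -> c(mean, sd)` of normal priors
#'   (as produced by [warm_start()]) overriding the defaults for those
#'   parameters.
#' @return An object of class `prior_set`.
#' @export
prior_set <- function(B_scale = 5, coef_sd = 10, gauge_sd = 0.1, r_max = 50,
                      tau_shape = 1, tau_rate = 0.01, env_B_sd = 10,
                      env_BLC_sd = 10, shape_log_sd = 5,
                      refuge_log_sd = 1.5, exponent_sd = 1, warm = NULL) {
  stopifnot(B_scale > 0, coef_sd > 0, gauge_sd > 0, r_max > 0,
            tau_shape > 0, tau_rate > 0, env_B_sd > 0, env_BLC_sd > 0,
            shape_log_sd > 0, refuge_log_sd > 0, exponent_sd > 0)
  structure(list(B_scale = B_scale, coef_sd = coef_sd, gauge_sd = gauge_sd,
                 r_max = r_max, tau_shape = tau_shape, tau_rate = tau_rate,
                 env_B_sd = env_B_sd, env_BLC_sd = env_BLC_sd,
                 shape_log_sd = shape_log_sd, refuge_log_sd = refuge_log_sd,
                 exponent_sd = exponent_sd, warm = warm),
            class = "prior_set")
}

# Log prior density for one named parameter (internal). `kind` tags the
# parameter's role; warm-start normals take precedence for B_s/b0/b1.
prior_logdensity <- function(priors, name, value, kind) {
  w <- priors$warm[[name]]
  if (!is.null(w)) return(stats::dnorm(value, w[1], w[2], log = TRUE))
  switch(kind,
    B = if (value < 0) -Inf else
      stats::dnorm(value, 0, priors$B_scale, log = TRUE) + log(2),
    coef = stats::dnorm(value, 0, priors$coef_sd, log = TRUE),
    r = if (value <= 0 || value > priors$r_max) -Inf else
      -log(priors$r_max),
    env_B = stats::dnorm(value, 0, priors$env_B_sd, log = TRUE),
    env_BLC = stats::dnorm(value, 0, priors$env_BLC_sd, log = TRUE),
    shape_pos = if (value <= 0) -Inf else
      stats::dlnorm(value, 0, priors$shape_log_sd, log = TRUE),
    refuge_frac = if (value <= 0) -Inf else
      stats::dlnorm(value, 0, priors$refuge_log_sd, log = TRUE),
    exponent = stats::dnorm(value, 1, priors$exponent_sd, log = TRUE),
    epsilon = if (value < 0 || value > 1) -Inf else 0,
    stop("unknown prior kind: ", kind))
}

#' Warm-start priors from a previous fit
#'
#' Converts a converged non-spatial fit into priors for the spatial refit:
#' normal priors centred on the posterior means with the posterior standard
#' deviations, for the main effects `b0`, `b1` and `B_s` only. Other
#' parameters keep their defaults. Degenerate (constant) chains get their sd
#' floored; a non-converged input (max R-hat above `rhat_warn`) attaches a
#' warning rather than failing.
#'
#' @param samples a [sample_posterior()] result.
#' @param base the [prior_set()] whose defaults are kept for everything else.
#' @param min_sd floor for posterior sds.
#' @param rhat_warn R-hat threshold above which a warning is attached.
#' @return A `prior_set` with `warm` entries filled in.
#' @export
warm_start <- function(samples, base = prior_set(), min_sd = 1e-8,
                       rhat_warn = 1.1) {
  stopifnot(inherits(samples, "posterior_samples"))
  sm <- summary(samples)
  keep <- grepl("^(B_|b0\\[|b1\\[)", sm$parameter)
  warm <- lapply(which(keep), function(i)
    c(sm$mean[i], max(sm$sd[i], min_sd)))
  names(warm) <- sm$parameter[keep]
  out <- base
  out$warm <- warm
  rh <- suppressWarnings(max(sm$rhat, na.rm = TRUE))
  if (is.finite(rh) && rh > rhat_warn)
    warning(sprintf("warm_start from a possibly non-converged fit (max R-hat %.3f)",
                    rh))
  out
}
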