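#' Contact functional-relationship specification
#'
#' Describes one human-snake contact model: the functional relationship, its
#' shape parameters, the species trait table, an optional human-impact
#' [abundance_adjustment()], and the observation family. The six discrete
#' annual-probability forms (with `H` humans and `S` effective snakes per
#' cell, `beta` the contact-rate scale) are
#'
#' * `mass_action`:          `1 - exp(-beta * S)`
#' * `power`:                `1 - exp(-beta * H^(p-1) * S^q)`
#' * `refuge_on_S`:          `1 - exp(-beta * (S/H - 1/q_h))`
#' * `refuge_on_H`:          `1 - exp(-beta * S * (1 - S/(q_s * H)))`
#' * `separate_asymptotic`:  `1 - exp(-beta * S / (1 - eps + eps * X))`
#' * `asymptotic`:           `1 - exp(-beta * S * c / (c + X))`
#'
#' where `X` is `S` or `H` according to `asymptote_on`. With `eps = 0` the
#' separate-asymptotic form reduces exactly to mass action; `c` is the value
#' of `X` at which half the asymptotic contacts occur. The refuge forms can
#' produce negative continuous contact rates (more refuge than snakes or
#' humans); the rate is floored at zero so the annual probability stays in
#' `[0, 1]`, and both forms evaluate to probability 0 in unpopulated cells.
#'
#' @param relationship one of the six names above.
#' @param beta global contact-rate scale (> 0 unless an adjustment supplies
#'   the scale, in which case leave it at 1 to keep the model identified).
#' @param p,q power-form exponents.
#' @param q_h,q_s refuge fractions (> 0).
#' @param epsilon separate-asymptotic mixing weight in `[0, 1]`.
#' @param c_half asymptotic half-saturation constant (> 0).
#' @param asymptote_on `"S"` or `"H"`: which population saturates in the
#'   asymptotic variants.
#' @param traits optional [species_traits()] used by forward passes.
#' @param adjustment optional [abundance_adjustment()].
#' @param family observation family, `"poisson"` or `"negbin"`.
#' @param r negative-binomial dispersion; a scalar, or a named vector keyed
#'   by land-cover class for a class-stratified dispersion.
#' @param stage `"snakebite"` or `"envenoming"` (selects trait weighting).
#' @return An object of class `contact_spec`.
#' @export
contact_model_spec <- function(relationship = c("mass_action", "power",
                                                "refuge_on_S", "refuge_on_H",
                                                "separate_asymptotic",
                                                "asymptotic"),
                               beta = 1, p = NULL, q = NULL,
                               q_h = NULL, q_s = NULL, epsilon = NULL,
                               c_half = NULL, asymptote_on = c("S", "H"),
                               traits = NULL, adjustment = NULL,
                               family = c("poisson", "negbin"), r = NULL,
                               stage = c("snakebite", "envenoming")) {
  relationship <- match.arg(relationship)
  family <- match.arg(family)
  stage <- match.arg(stage)
  asymptote_on <- match.arg(asymptote_on)
  if (!is.finite(beta) || beta < 0) stop("`beta` must be >= 0")
  given <- c(p = !is.null(p), q = !is.null(q), q_h = !is.null(q_h),
             q_s = !is.null(q_s), epsilon = !is.null(epsilon),
             c_half = !is.null(c_half))
  need <- switch(relationship,
    mass_action = character(),
    power = c("p", "q"),
    refuge_on_S = "q_h",
    refuge_on_H = "q_s",
    separate_asymptotic = "epsilon",
    asymptotic = "c_half")
  if (!all(given[need]))
    stop("relationship `", relationship, "` requires parameter(s): ",
         paste(need[!given[need]], collapse = ", "))
  extra <- names(given)[given & !names(given) %in% need]
  if (length(extra))
    stop("parameter(s) not used by `", relationship, "`: ",
         paste(extra, collapse = ", "))
  # shape parameters may be NA, meaning "free, to be estimated"
  chk <- function(x) !is.null(x) && !is.na(x)
  if (chk(q_h) && q_h <= 0) stop("`q_h` must be > 0")
  if (chk(q_s) && q_s <= 0) stop("`q_s` must be > 0")
  if (chk(epsilon) && (epsilon < 0 || epsilon > 1))
    stop("`epsilon` must lie in [0, 1]")
  if (chk(c_half) && c_half <= 0) stop("`c_half` must be > 0")
  if (family == "negbin" && !is.null(r) && any(r <= 0))
    stop("`r` must be > 0")
  if (!is.null(traits)) stopifnot(inherits(traits, "species_traits"))
  if (!is.null(adjustment))
    stopifnot(inherits(adjustment, "abundance_adjustment"))
  structure(list(relationship = relationship, beta = beta, p = p, q = q,
                 q_h = q_h, q_s = q_s, epsilon = epsilon, c_half = c_half,
                 asymptote_on = asymptote_on, traits = traits,
                 adjustment = adjustment, family = family, r = r,
                 stage = stage),
            class = "contact_spec")
}

#' @export
print.contact_spec <- function(x, ...) {
  pars <- c("beta", "p", "q", "q_h", "q_s", "epsilon", "c_half")
  set <- pars[!vapply(x[pars], is.null, logical(1))]
  cat(sprintf("<contact_spec> %s (%s stage, %s family)\n",
              x$relationship, x$stage, x$family))
  cat(" ", paste(sprintf("%s = %g", set, unlist(x[set])), collapse = ", "),
      "\n")
  if (!is.null(x$adjustment))
    cat("  adjustment:", x$adjustment$form,
        if (x$adjustment$stratified) "(stratified)" else "(global)", "\n")
  invisible(x)
}

#' Discrete-time annual contact probability function
#'
#' Maps a continuous-time contact term to its discrete annual-probability
#' form (the exponential one-step solution of the susceptible-bitten
#' dynamics, e.g. `beta*H*S -> 1 - exp(-beta*S)`) and returns it as an
#' evaluable function of `(H, S)`.
#'
#' @param relationship one of the six relationship names.
#' @param parameters named list of the shape parameters the relationship
#'   needs (`beta` plus any of `p`, `q`, `q_h`, `q_s`, `epsilon`, `c_half`,
#'   `asymptote_on`).
#' @return `function(H, S, S_raw = S)` returning per-cell probabilities in
#'   `[0, 1]`. `S` is the (species-weighted, adjusted) abundance entering
#'   the linear contact term; `S_raw` is the abundance entering the refuge
#'   and saturation brackets, which compare snake numbers with human
#'   numbers and therefore take the total (unweighted) abundance when the
#'   contact rate is species-decomposed. With scalar use the two coincide.
#' @export
#' @examples
#' f <- discretise("mass_action", list(beta = 1))
#' f(H = 100, S = 0.5)  # 1 - exp(-0.5)
discretise <- function(relationship, parameters = list()) {
  pr <- parameters
  beta <- pr$beta %||% 1
  on_H <- identical(pr$asymptote_on, "H")
  rate_fun <- switch(relationship,
    mass_action = function(H, S, S_raw) beta * S,
    power = function(H, S, S_raw) {
      if (is.null(pr$p) || is.null(pr$q)) stop("power form needs `p` and `q`")
      beta * H^(pr$p - 1) * S^pr$q
    },
    refuge_on_S = function(H, S, S_raw) {
      if (is.null(pr$q_h)) stop("refuge_on_S needs `q_h`")
      ifelse(H > 0, pmax(beta * (S / H) * (1 - H / (pr$q_h * S_raw)), 0), 0)
    },
    refuge_on_H = function(H, S, S_raw) {
      if (is.null(pr$q_s)) stop("refuge_on_H needs `q_s`")
      ifelse(H > 0, pmax(beta * S * (1 - S_raw / (pr$q_s * H)), 0), 0)
    },
    separate_asymptotic = function(H, S, S_raw) {
      if (is.null(pr$epsilon)) stop("separate_asymptotic needs `epsilon`")
      X <- if (on_H) H else S_raw
      beta * S / (1 - pr$epsilon + pr$epsilon * X)
    },
    asymptotic = function(H, S, S_raw) {
      if (is.null(pr$c_half)) stop("asymptotic needs `c_half`")
      X <- if (on_H) H else S_raw
      beta * S * pr$c_half / (pr$c_half + X)
    },
    stop("unknown relationship: ", relationship))
  function(H, S, S_raw = S) {
    rate <- rate_fun(H, S, S_raw)
    rate[S == 0] <- 0  # no snakes, no contacts, whatever the form
    -expm1(-rate)
  }
}

#' Per-cell annual contact probability
#'
#' Evaluates the discrete form of `spec` at human density `H` and effective
#' (already adjusted) snake abundance `S_eff`.
#'
#' @param spec a [contact_model_spec()].
#' @param H human density per cell (>= 0), any shape.
#' @param S_eff effective snake abundance per cell (>= 0), same shape.
#' @param S_raw total (unweighted) snake abundance for the refuge and
#'   saturation brackets; defaults to `S_eff`.
#' @return Probabilities in `[0, 1]` with the shape of the inputs.
#' @export
contact_probability <- function(spec, H, S_eff, S_raw = NULL) {
  stopifnot(inherits(spec, "contact_spec"))
  Hv <- if (is_sgrid(H)) H$values else H
  Sv <- if (is_sgrid(S_eff)) S_eff$values else S_eff
  Rv <- if (is.null(S_raw)) Sv
        else if (is_sgrid(S_raw)) S_raw$values else S_raw
  if (any(Hv < 0, na.rm = TRUE) || any(Sv < 0, na.rm = TRUE))
    stop("H and S_eff must be >= 0")
  f <- discretise(spec$relationship,
                  spec[c("beta", "p", "q", "q_h", "q_s", "epsilon", "c_half",
                         "asymptote_on")])
  P <- f(Hv, Sv, Rv)
  if (is_sgrid(H)) grid_like(H, P, mask = H$mask) else P
}

#' Expected number of bitten humans per cell
#'
#' @param H_s susceptible humans per cell (>= 0).
#' @param P annual contact probability per cell, in `[0, 1]`.
#' @return `H_s * P`, bounded by `H_s` cellwise.
#' @export
expected_bites <- function(H_s, P) {
  Hv <- if (is_sgrid(H_s)) H_s$values else H_s
  Pv <- if (is_sgrid(P)) P$values else P
  if (any(Hv < 0, na.rm = TRUE)) stop("H_s must be >= 0")
  if (any(Pv < 0 | Pv > 1, na.rm = TRUE)) stop("P must lie in [0, 1]")
  out <- Hv * Pv
  if (is_sgrid(H_s)) grid_like(H_s, out, mask = H_s$mask) else out
}
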