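#' Envenoming-probability model
#'
#' Second-stage logistic model for the probability that a snakebite delivers
#' a clinically significant envenoming. The log-odds are a linear function of
#' the adjusted per-species abundances, weighted by each species' statistical
#' effect `B_s` (unconstrained reals) and envenoming-severity index `E_s`,
#' with an optional random intercept per land-cover class:
#'
#'   `logit(P_env) = B_LC(l) + sum_s B_s * E_s * S'_s`
#'
#' Without `B_LC` the intercept term is omitted (the unstratified variant).
#'
#' @param B_s named numeric vector of species effects (any sign).
#' @param E_s named numeric vector of envenoming-severity indices in (0, 1];
#'   must cover the same species as `B_s`.
#' @param B_LC optional named numeric vector of land-cover intercepts keyed
#'   by class label; supplying it selects the random-intercept variant.
#' @return An object of class `envenoming_model`.
#' @export
envenoming_model <- function(B_s, E_s, B_LC = NULL) {
  if (is.null(names(B_s)) || is.null(names(E_s)))
    stop("B_s and E_s must be named by species")
  if (!setequal(names(B_s), names(E_s)))
    stop("B_s and E_s must cover the same species")
  E_s <- E_s[names(B_s)]
  if (any(E_s <= 0 | E_s > 1)) stop("E_s must lie in (0, 1]")
  if (!is.null(B_LC) && is.null(names(B_LC)))
    stop("B_LC must be named by land-cover class")
  structure(list(B_s = B_s, E_s = E_s, B_LC = B_LC),
            class = "envenoming_model")
}

#' Per-cell probability that a bite results in envenoming
#'
#' @param S_prime named list (by species) of adjusted abundances `S'_s =
#'   beta(H, l) * S_s`, as matrices or `sgrid`s.
#' @param model an [envenoming_model()].
#' @param land_cover land-cover labels per cell (or categorical `sgrid`);
#'   required iff the model carries class intercepts.
#' @return Probabilities in (0, 1) with the shape of the inputs.
#' @export
envenoming_probability <- function(S_prime, model, land_cover = NULL) {
  stopifnot(inherits(model, "envenoming_model"))
  sp <- names(model$B_s)
  if (!all(sp %in% names(S_prime)))
    stop("adjusted abundance missing for species: ",
         paste(setdiff(sp, names(S_prime)), collapse = ", "))
  as_mat <- function(g) if (is_sgrid(g)) g$values else g
  first <- S_prime[[sp[1]]]
  eta <- 0
  for (s in sp) eta <- eta + model$B_s[[s]] * model$E_s[[s]] *
    as_mat(S_prime[[s]])
  if (!is.null(model$B_LC)) {
    if (is.null(land_cover))
      stop("this model has land-cover intercepts; supply `land_cover`")
    lc <- if (is_sgrid(land_cover)) land_cover$labels[land_cover$values]
          else land_cover
    idx <- match(lc, names(model$B_LC))
    if (any(is.na(idx) & !is.na(lc)))
      stop("missing land-cover intercept for class: ",
           paste(unique(lc[is.na(idx) & !is.na(lc)]), collapse = ", "))
    eta <- eta + as.numeric(model$B_LC[idx])  # column-major recycling
  }
  P <- stats::plogis(eta)
  if (is_sgrid(first)) grid_like(first, matrix(P, nrow(first$values),
                                               ncol(first$values)),
                                 mask = first$mask)
  else P
}

#' Expected envenomed humans per cell
#'
#' @param H_b expected (or observed) bitten humans per cell (>= 0).
#' @param P_env envenoming probability per cell in `[0, 1]`.
#' @return `H_b * P_env`, bounded by `H_b` cellwise.
#' @export
expected_envenomings <- function(H_b, P_env) {
  Hv <- if (is_sgrid(H_b)) H_b$values else H_b
  Pv <- if (is_sgrid(P_env)) P_env$values else P_env
  if (any(Hv < 0, na.rm = TRUE)) stop("H_b must be >= 0")
  if (any(Pv < 0 | Pv > 1, na.rm = TRUE)) stop("P_env must lie in [0, 1]")
  out <- Hv * Pv
  if (is_sgrid(H_b)) grid_like(H_b, out, mask = H_b$mask) else out
}
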