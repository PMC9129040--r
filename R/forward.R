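#' Forward pass: expected snakebites on a landscape
#'
#' Runs the full snakebite stage: species-decomposed effective abundance,
#' human-impact adjustment (`S' = beta(H, l) * S_t`, the one canonical place
#' the multiplier applies), discrete contact probability, and expected bitten
#' humans `H_b = H * P`.
#'
#' @param landscape a [grid_landscape()].
#' @param spec a [contact_model_spec()] carrying `traits` (and optionally an
#'   `adjustment`).
#' @return List of aligned `sgrid`s: `S_eff` (trait-weighted abundance),
#'   `multiplier`, `S_prime` (adjusted abundance), `P` (annual contact
#'   probability) and `expected` (expected bites per cell).
#' @export
predict_bites <- function(landscape, spec) {
  stopifnot(inherits(landscape, "landscape"), inherits(spec, "contact_spec"))
  if (is.null(spec$traits)) stop("`spec` must carry species traits")
  S_t <- effective_abundance(landscape$snake_abundance, spec$traits,
                             stage = "snakebite")
  H <- landscape$human_density
  if (!is.null(spec$adjustment)) {
    m <- abundance_multiplier(H, landscape$land_cover, spec$adjustment)
    sv <- S_t$values
    # Inf * 0 guard: an unbounded multiplier on an empty cell is still empty
    pv <- m$values * sv
    pv[sv == 0] <- 0
    S_prime <- grid_like(S_t, pv, mask = S_t$mask | m$mask)
  } else {
    m <- grid_like(H, matrix(1, nrow(H$values), ncol(H$values)),
                   mask = H$mask)
    S_prime <- S_t
  }
  # total raw abundance (all species, unweighted) feeds the refuge and
  # saturation brackets, which compare snake with human numbers
  S_tot <- Reduce(`+`, lapply(landscape$snake_abundance, `[[`, "values"))
  rawv <- m$values * S_tot
  rawv[S_tot == 0] <- 0
  S_raw <- grid_like(S_t, rawv, mask = S_t$mask | m$mask)
  P <- contact_probability(spec, H, S_prime, S_raw)
  expected <- expected_bites(H, P)
  list(S_eff = S_t, multiplier = m, S_prime = S_prime, S_raw = S_raw,
       P = P, expected = expected)
}

#' Forward pass: expected envenomings on a landscape
#'
#' Envenoming is modelled as a subset of bites: each species' abundance is
#' adjusted by the same human-impact multiplier (`S'_s = beta(H, l) * S_s`),
#' the logistic envenoming probability is evaluated, and expected envenomings
#' are `H_env = H_b * P_env`.
#'
#' @param landscape a [grid_landscape()].
#' @param spec the snakebite-stage [contact_model_spec()] (supplies the
#'   adjustment and, if `expected_bites` is missing, the bite forward pass).
#' @param model an [envenoming_model()].
#' @param expected_bites optional `sgrid` of expected bites (e.g. a posterior
#'   mean); defaults to the forward pass of `spec`.
#' @return List of `sgrid`s: `P_env` and `expected`.
#' @export
predict_envenomings <- function(landscape, spec, model,
                                expected_bites = NULL) {
  stopifnot(inherits(landscape, "landscape"),
            inherits(model, "envenoming_model"))
  if (is.null(expected_bites))
    expected_bites <- predict_bites(landscape, spec)$expected
  S_prime <- landscape$snake_abundance
  if (!is.null(spec$adjustment)) {
    m <- abundance_multiplier(landscape$human_density, landscape$land_cover,
                              spec$adjustment)
    S_prime <- lapply(S_prime, function(g) {
      pv <- m$values * g$values
      pv[g$values == 0] <- 0
      grid_like(g, pv, mask = g$mask | m$mask)
    })
  }
  P_env <- envenoming_probability(S_prime, model, landscape$land_cover)
  expected <- expected_envenomings(expected_bites, P_env)
  list(P_env = P_env, expected = expected)
}
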