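#' Bare MCMC model graph
#'
#' The minimal contract [sample_posterior()] needs: a parameter registry, an
#' initial state, a log-posterior callable (gradient-free), update blocks,
#' and optionally a deviance callable, a gauge move and a CAR field. Used
#' directly for toy targets in tests; [build_model()] and
#' [build_envenoming_model()] produce fully wired instances.
#'
#' @param par_names character registry of parameter names.
#' @param init named initial values (length of `par_names`).
#' @param log_posterior `function(theta)` (or `function(theta, rho)` when a
#'   CAR field is attached) returning the joint log density.
#' @param blocks named list of integer index vectors partitioning the
#'   parameters into update blocks.
#' @param deviance optional `function(theta)` (or `function(theta, rho)`).
#' @param log_scale logical per parameter: propose multiplicatively.
#' @param gauge optional `list(scale = idx, offset = idx)` enabling the
#'   joint move `theta[scale] * e^g`, `theta[offset] - g` along a known
#'   scale ridge.
#' @param to_report,from_report optional inverse pair of linear
#'   reparameterisations between the sampler's internal coordinates and the
#'   reported parameters (used to decorrelate regression blocks by
#'   covariate centring); `log_posterior`, `deviance` and `mu_fn` take
#'   internal coordinates, stored samples are reported coordinates.
#' @param car optional CAR block: `list(adjacency, loglik_cell =
#'   function(idx, logmu_cell), tau_shape, tau_rate, intercept_idx)`.
#' @param mu_fn optional `function(theta)` returning per-cell expected
#'   counts (used by CAR updates and predictions).
#' @return An object of class `spill_model`.
#' @export
mcmc_model <- function(par_names, init, log_posterior, blocks,
                       deviance = NULL, log_scale = NULL, gauge = NULL,
                       car = NULL, mu_fn = NULL, to_report = NULL,
                       from_report = NULL) {
  stopifnot(length(init) == length(par_names))
  if (is.null(log_scale)) log_scale <- rep(FALSE, length(par_names))
  structure(list(par_names = par_names, init = stats::setNames(init, par_names),
                 log_posterior = log_posterior, blocks = blocks,
                 deviance = deviance, log_scale = log_scale, gauge = gauge,
                 car = car, mu_fn = mu_fn, to_report = to_report,
                 from_report = from_report),
            class = "spill_model")
}

#' @export
print.spill_model <- function(x, ...) {
  cat(sprintf("<spill_model> %d parameters in %d blocks\n",
              length(x$par_names), length(x$blocks)))
  for (b in names(x$blocks))
    cat(sprintf("  %s: %s\n", b,
                paste(x$par_names[x$blocks[[b]]], collapse = ", ")))
  if (!is.null(x$gauge)) cat("  gauge move: on\n")
  if (!is.null(x$car)) cat("  CAR field: on\n")
  invisible(x)
}

#' Build the snakebite-stage model graph
#'
#' Wires a landscape and a contact specification into a log-posterior over
#' the free parameters: one contact-rate scale `B_s` per species, the
#' adjustment coefficients per realised land-cover class (if the spec
#' carries an adjustment), any free shape parameters of the functional
#' relationship (those set to `NA` in the spec), the negative binomial
#' dispersion (if the family is `"negbin"` and `r` is not fixed), and — with
#' `car = TRUE` — a cellwise CAR random intercept `rho` entering the mean as
#' `exp(rho)` plus its precision `tau`. When both `B_s` and adjustment
#' intercepts are free, the model exposes the exact scale ridge between them
#' as a gauge move and pins it with the prior set's gauge anchor.
#'
#' @param landscape a [grid_landscape()] with `bite_counts` (or, for
#'   `stage = "envenoming"` treated as a direct contact process,
#'   `envenoming_counts`).
#' @param spec a [contact_model_spec()] carrying `traits` and optionally an
#'   `adjustment`. Shape parameters set to `NA` are estimated.
#' @param priors a [prior_set()].
#' @param car add the intrinsic CAR spatial random intercept.
#' @param r_by_class estimate one dispersion per land-cover class rather
#'   than a single `r` (negative binomial only).
#' @return A `spill_model` with fields `info` (cell data) attached.
#' @export
build_model <- function(landscape, spec, priors = prior_set(), car = FALSE,
                        r_by_class = FALSE) {
  stopifnot(inherits(landscape, "landscape"), inherits(spec, "contact_spec"),
            inherits(priors, "prior_set"))
  if (is.null(spec$traits)) stop("`spec` must carry species traits")
  counts_layer <- if (spec$stage == "snakebite") landscape$bite_counts
                  else landscape$envenoming_counts
  if (is.null(counts_layer))
    stop("landscape lacks the observed counts for stage ", spec$stage)

  mask <- landscape$human_density$mask | landscape$land_cover$mask |
    counts_layer$mask
  for (g in landscape$snake_abundance) mask <- mask | g$mask
  cells <- which(!mask)
  if (!length(cells)) stop("no usable cells")
  H <- landscape$human_density$values[cells]
  y <- counts_layer$values[cells]
  sp <- landscape_species(landscape)
  S_raw <- vapply(landscape$snake_abundance,
                  function(g) g$values[cells], numeric(length(cells)))
  S_raw <- matrix(S_raw, nrow = length(cells),
                  dimnames = list(NULL, sp))
  tr <- spec$traits
  A_w <- species_weights(
    structure(transform(tr, B_s = 1), class = class(tr)), spec$stage)[sp]
  lc_lab <- landscape$land_cover$labels[landscape$land_cover$values[cells]]
  classes <- LAND_COVER_CLASSES[LAND_COVER_CLASSES %in% unique(lc_lab)]
  lc_idx <- match(lc_lab, classes)

  has_adj <- !is.null(spec$adjustment)
  adj_form <- if (has_adj) spec$adjustment$form else NULL
  # adjustment covariates per form (x2 only for H_plus_H2)
  x1 <- if (has_adj) switch(adj_form, linear_H = H, H_squared = H^2,
                            H_plus_H2 = H, log_H_squared = log1p(H)^2)
        else NULL
  x2 <- if (has_adj && adj_form == "H_plus_H2") H^2 else NULL

  # ---- registry ----------------------------------------------------------
  par_names <- paste0("B_", sp)
  kinds <- rep("B", length(sp))
  log_scale <- rep(TRUE, length(sp))
  blocks <- list(species = seq_along(sp))
  if (has_adj) {
    nm0 <- paste0("b0[", classes, "]"); nm1 <- paste0("b1[", classes, "]")
    coef_names <- c(nm0, nm1)
    if (!is.null(x2)) coef_names <- c(coef_names, paste0("b2[", classes, "]"))
    blocks$coefficients <- length(par_names) + seq_along(coef_names)
    par_names <- c(par_names, coef_names)
    kinds <- c(kinds, rep("coef", length(coef_names)))
    log_scale <- c(log_scale, rep(FALSE, length(coef_names)))
  }
  shape_free <- character()
  shape_need <- switch(spec$relationship,
    mass_action = character(), power = c("p", "q"), refuge_on_S = "q_h",
    refuge_on_H = "q_s", separate_asymptotic = "epsilon",
    asymptotic = "c_half")
  for (s in shape_need) if (is.na(spec[[s]])) shape_free <- c(shape_free, s)
  if (length(shape_free)) {
    blocks$shape <- length(par_names) + seq_along(shape_free)
    par_names <- c(par_names, shape_free)
    kinds <- c(kinds, vapply(shape_free, function(s) switch(s,
      p = "exponent", q = "exponent", epsilon = "epsilon",
      q_h = "refuge_frac", q_s = "refuge_frac", c_half = "shape_pos"),
      character(1)))
    log_scale <- c(log_scale, shape_free %in% c("q_h", "q_s", "c_half"))
  }
  r_free <- spec$family == "negbin" && is.null(spec$r)
  if (r_free) {
    r_names <- if (r_by_class) paste0("r[", classes, "]") else "r"
    blocks$dispersion <- length(par_names) + seq_along(r_names)
    par_names <- c(par_names, r_names)
    kinds <- c(kinds, rep("r", length(r_names)))
    log_scale <- c(log_scale, rep(TRUE, length(r_names)))
  }
  names(kinds) <- par_names

  i_B <- blocks$species
  i_b0 <- if (has_adj) blocks$coefficients[seq_along(classes)] else integer()
  i_shape <- blocks$shape %||% integer()
  i_r <- blocks$dispersion %||% integer()

  # ---- expected counts ---------------------------------------------------
  # The sampler works with per-class covariate-centred intercepts (b0c =
  # b0 + b1*mean(x1) + ...), which decorrelates the coefficient block; the
  # reported/stored parameters are the model's own b0. The map is linear
  # and unit-Jacobian.
  n_cl <- length(classes)
  i_b1 <- if (has_adj) blocks$coefficients[n_cl + seq_len(n_cl)] else integer()
  i_b2 <- if (has_adj && !is.null(x2))
    blocks$coefficients[2 * n_cl + seq_len(n_cl)] else integer()
  x1bar <- if (has_adj) as.vector(tapply(x1, lc_idx, mean))[seq_len(n_cl)]
           else NULL
  x2bar <- if (length(i_b2)) as.vector(tapply(x2, lc_idx, mean)) else NULL
  to_report <- function(theta) {
    if (!has_adj) return(theta)
    theta[i_b0] <- theta[i_b0] - theta[i_b1] * x1bar -
      (if (length(i_b2)) theta[i_b2] * x2bar else 0)
    theta
  }
  from_report <- function(theta) {
    if (!has_adj) return(theta)
    theta[i_b0] <- theta[i_b0] + theta[i_b1] * x1bar +
      (if (length(i_b2)) theta[i_b2] * x2bar else 0)
    theta
  }
  S_tot <- rowSums(S_raw)  # unweighted total abundance for the brackets
  # centred covariates, hoisted out of the per-iteration path
  x1c <- if (has_adj) x1 - x1bar[lc_idx] else NULL
  x2c <- if (length(i_b2)) x2 - x2bar[lc_idx] else NULL
  rel <- spec$relationship
  beta_fix <- spec$beta
  on_H <- identical(spec$asymptote_on, "H")
  Hpos <- H > 0
  shape_val <- function(theta, nm)
    if (nm %in% shape_free) theta[[nm]] else spec[[nm]]
  mu_fn <- function(theta) {
    S_eff <- as.vector(S_raw %*% (theta[i_B] * A_w))
    if (has_adj) {
      eta <- theta[i_b0][lc_idx] + theta[i_b1][lc_idx] * x1c
      if (length(i_b2)) eta <- eta + theta[i_b2][lc_idx] * x2c
      mult <- exp(eta)
      S_prime <- mult * S_eff
      S_prime[S_eff == 0] <- 0
      S_rawadj <- mult * S_tot
      S_rawadj[S_tot == 0] <- 0
    } else { S_prime <- S_eff; S_rawadj <- S_tot }
    rate <- switch(rel,
      mass_action = beta_fix * S_prime,
      power = beta_fix * H^(shape_val(theta, "p") - 1) *
        S_prime^shape_val(theta, "q"),
      refuge_on_S = {
        r <- beta_fix * (S_prime / H) *
          (1 - H / (shape_val(theta, "q_h") * S_rawadj))
        r[!Hpos] <- 0; r[is.na(r)] <- 0; r[r < 0] <- 0
        r
      },
      refuge_on_H = {
        r <- beta_fix * S_prime *
          (1 - S_rawadj / (shape_val(theta, "q_s") * H))
        r[!Hpos] <- 0; r[is.na(r)] <- 0; r[r < 0] <- 0
        r
      },
      separate_asymptotic = {
        eps <- shape_val(theta, "epsilon")
        beta_fix * S_prime / (1 - eps + eps * (if (on_H) H else S_rawadj))
      },
      asymptotic = {
        ch <- shape_val(theta, "c_half")
        beta_fix * S_prime * ch / (ch + (if (on_H) H else S_rawadj))
      })
    P <- -expm1(-rate)
    P[S_prime == 0] <- 0
    H * P
  }

  r_cells <- function(theta) {
    if (spec$family != "negbin") return(NULL)
    if (!r_free) {
      if (length(spec$r) > 1 || !is.null(names(spec$r)))
        return(as.numeric(spec$r[classes][lc_idx]))
      return(rep(as.numeric(spec$r), length(H)))
    }
    rv <- theta[i_r]
    if (r_by_class) rv[lc_idx] else rep(rv, length(H))
  }

  ypos <- which(y > 0)
  lgam_const <- sum(lgamma(y + 1))
  loglik <- function(theta, rho = NULL) {
    mu <- mu_fn(theta)
    if (!is.null(rho)) mu <- mu * exp(rho)
    if (any(!is.finite(mu)) || any(mu < 0)) return(-Inf)
    if (any(mu[ypos] == 0)) return(-Inf)
    if (spec$family == "poisson")
      sum(y[ypos] * log(mu[ypos])) - sum(mu) - lgam_const
    else sum(stats::dnbinom(y, size = r_cells(theta), mu = mu, log = TRUE))
  }

  # vectorised prior evaluation (this sits on the sampler's hot path):
  # warm-started parameters take their normal overrides, the rest are
  # grouped by kind
  warm_mean <- warm_sd <- rep(NA_real_, length(par_names))
  for (nm in names(priors$warm %||% list())) {
    i <- match(nm, par_names)
    if (!is.na(i)) {
      warm_mean[i] <- priors$warm[[nm]][1]
      warm_sd[i] <- priors$warm[[nm]][2]
    }
  }
  wmask <- !is.na(warm_mean)
  g_B <- which(kinds == "B" & !wmask)
  g_coef <- which(kinds == "coef" & !wmask)
  g_r <- which(kinds == "r")
  g_other <- which(!wmask & !(kinds %in% c("B", "coef", "r")))
  B_scale <- priors$B_scale; coef_sd <- priors$coef_sd
  r_max <- priors$r_max; gauge_sd <- priors$gauge_sd
  use_anchor <- has_adj && length(i_B) && is.finite(gauge_sd)
  log2c <- log(2)
  log_prior <- function(theta) {
    tr <- to_report(theta)  # priors are placed on the reported parameters
    if (any(tr[g_B] < 0)) return(-Inf)
    rv <- tr[g_r]
    if (length(rv) && (any(rv <= 0) || any(rv > r_max))) return(-Inf)
    lp <- sum(stats::dnorm(tr[g_B], 0, B_scale, log = TRUE)) +
      length(g_B) * log2c +
      sum(stats::dnorm(tr[g_coef], 0, coef_sd, log = TRUE)) -
      length(g_r) * log(r_max)
    if (any(wmask))
      lp <- lp + sum(stats::dnorm(tr[wmask], warm_mean[wmask],
                                  warm_sd[wmask], log = TRUE))
    for (i in g_other) {
      lp <- lp + prior_logdensity(priors, par_names[i], tr[[i]], kinds[i])
      if (!is.finite(lp)) return(-Inf)
    }
    if (use_anchor)
      lp <- lp + stats::dnorm(mean(tr[i_b0]), 0, gauge_sd, log = TRUE)
    lp
  }

  log_posterior <- function(theta, rho = NULL) {
    lp <- log_prior(theta)
    if (!is.finite(lp)) return(-Inf)
    lp + loglik(theta, rho)
  }

  init <- numeric(length(par_names))
  # start B_s at the scale matching observed totals (initial mu ~ data
  # scale); a large start saturates P at 1, a flat plateau RW cannot leave
  denom <- sum(H * as.vector(S_raw %*% A_w))
  init[i_B] <- max(sum(y), 1) / max(denom, .Machine$double.eps)
  if (has_adj) init[blocks$coefficients] <- 0
  # refuge forms put cells beyond the refuge capacity at probability 0, so
  # the refuge fractions must start large enough that every observed count
  # has positive likelihood
  pos <- y > 0 & H > 0
  q_s0 <- if (any(pos)) max(1, 2 * max(S_tot[pos] / H[pos])) else 1
  q_h0 <- if (any(pos))
    max(1, 2 * max(H[pos] / pmax(S_tot[pos], 1e-12))) else 1
  for (s in shape_free) init[match(s, par_names)] <-
    switch(s, p = 1, q = 1, epsilon = 0.5, q_h = q_h0, q_s = q_s0,
           c_half = 1)
  if (r_free) init[i_r] <- priors$r_max / 2

  gauge <- if (has_adj && length(i_B))
    list(scale = i_B, offset = i_b0) else NULL

  car_blk <- NULL
  if (car) {
    d <- dim(landscape$human_density)
    if (any(mask)) stop("CAR variant currently requires a fully unmasked grid")
    adjc <- car_adjacency(d[1], d[2])
    llcell <- function(idx, mu_cell, theta) {
      if (spec$family == "poisson") stats::dpois(y[idx], mu_cell, log = TRUE)
      else stats::dnbinom(y[idx], size = r_cells(theta)[idx], mu = mu_cell,
                          log = TRUE)
    }
    car_blk <- list(adjacency = adjc, loglik_cell = llcell,
                    tau_shape = priors$tau_shape, tau_rate = priors$tau_rate,
                    intercept_idx = i_b0)
  }

  m <- mcmc_model(par_names, init, log_posterior, blocks,
                  deviance = function(theta, rho = NULL)
                    -2 * loglik(theta, rho),
                  log_scale = log_scale, gauge = gauge, car = car_blk,
                  mu_fn = mu_fn, to_report = to_report,
                  from_report = from_report)
  m$log_prior <- log_prior
  # chain-start jitter scales (internal coords; log-scale params get a
  # log-sd): slopes of wide covariates jitter far less than intercepts
  jit <- rep(0.3, length(par_names))
  if (has_adj) {
    sdx1 <- as.vector(tapply(x1, lc_idx, stats::sd))
    jit[i_b1] <- 0.3 / pmax(sdx1, 1e-6)
    if (length(i_b2))
      jit[i_b2] <- 0.3 / pmax(as.vector(tapply(x2, lc_idx, stats::sd)), 1e-6)
  }
  m$init_jitter <- jit
  m$info <- list(cells = cells, y = y, H = H, classes = classes,
                 lc_idx = lc_idx, spec = spec, kinds = kinds,
                 dim = dim(landscape$human_density))
  m
}

#' Build the envenoming-stage model graph
#'
#' Second stage of the two-stage workflow: conditional on the snakebite
#' stage's expected bites (typically the posterior-mean surface), the number
#' of envenomings is `Poisson`/`NegBin` with mean `H_b * P_env`, where
#' `logit(P_env)` is linear in the adjusted species abundances with species
#' effects `B_s` (free reals) and, if `intercepts = TRUE`, a land-cover
#' random intercept `B_LC` per realised class.
#'
#' @param landscape a [grid_landscape()] with `envenoming_counts`.
#' @param spec the snakebite-stage spec (supplies the adjustment with fixed
#'   coefficient values and the trait `E_s` indices).
#' @param expected_bites `sgrid` of expected bites conditioning the stage.
#' @param priors a [prior_set()].
#' @param intercepts include the land-cover random intercept (the variant
#'   selected in the reference analysis).
#' @param family observation family for the envenoming counts.
#' @param r fixed dispersion; `NULL` with `family = "negbin"` estimates it.
#' @param car add the CAR random intercept.
#' @return A `spill_model`.
#' @export
build_envenoming_model <- function(landscape, spec, expected_bites,
                                   priors = prior_set(), intercepts = TRUE,
                                   family = c("poisson", "negbin"), r = NULL,
                                   car = FALSE) {
  family <- match.arg(family)
  stopifnot(inherits(landscape, "landscape"), inherits(spec, "contact_spec"),
            is_sgrid(expected_bites))
  if (is.null(landscape$envenoming_counts))
    stop("landscape lacks envenoming counts")
  mask <- landscape$human_density$mask | landscape$land_cover$mask |
    landscape$envenoming_counts$mask | expected_bites$mask
  for (g in landscape$snake_abundance) mask <- mask | g$mask
  cells <- which(!mask)
  y <- landscape$envenoming_counts$values[cells]
  Hb <- expected_bites$values[cells]
  sp <- landscape_species(landscape)
  lc_lab <- landscape$land_cover$labels[landscape$land_cover$values[cells]]
  classes <- LAND_COVER_CLASSES[LAND_COVER_CLASSES %in% unique(lc_lab)]
  lc_idx <- match(lc_lab, classes)
  # fixed adjusted abundances S'_s = beta(H, l) * S_s
  mult <- if (!is.null(spec$adjustment))
    abundance_multiplier(landscape$human_density$values[cells], lc_lab,
                         spec$adjustment) else 1
  E_s <- stats::setNames(spec$traits$E_s, spec$traits$species_id)[sp]
  Xs <- vapply(sp, function(s)
    mult * landscape$snake_abundance[[s]]$values[cells] * E_s[[s]],
    numeric(length(cells)))
  Xs <- matrix(Xs, nrow = length(cells), dimnames = list(NULL, sp))

  par_names <- paste0("B_", sp)
  kinds <- rep("env_B", length(sp))
  blocks <- list(species = seq_along(sp))
  if (intercepts) {
    blocks$intercepts <- length(par_names) + seq_along(classes)
    par_names <- c(par_names, paste0("B_LC[", classes, "]"))
    kinds <- c(kinds, rep("env_BLC", length(classes)))
  }
  r_free <- family == "negbin" && is.null(r)
  if (r_free) {
    blocks$dispersion <- length(par_names) + 1L
    par_names <- c(par_names, "r")
    kinds <- c(kinds, "r")
  }
  names(kinds) <- par_names
  log_scale <- kinds == "r"

  mu_fn <- function(theta) {
    eta <- as.vector(Xs %*% theta[blocks$species])
    if (intercepts) eta <- eta + theta[blocks$intercepts][lc_idx]
    Hb * stats::plogis(eta)
  }
  loglik <- function(theta, rho = NULL) {
    mu <- mu_fn(theta)
    if (!is.null(rho)) mu <- mu * exp(rho)
    if (any(mu == 0 & y > 0)) return(-Inf)
    if (family == "poisson") sum(stats::dpois(y, mu, log = TRUE))
    else sum(stats::dnbinom(y, size = if (r_free) theta[["r"]] else r,
                            mu = mu, log = TRUE))
  }
  log_prior <- function(theta) {
    lp <- 0
    for (i in seq_along(theta)) {
      lp <- lp + prior_logdensity(priors, par_names[i], theta[[i]], kinds[i])
      if (!is.finite(lp)) return(-Inf)
    }
    lp
  }
  log_posterior <- function(theta, rho = NULL) {
    lp <- log_prior(theta)
    if (!is.finite(lp)) return(-Inf)
    lp + loglik(theta, rho)
  }
  init <- numeric(length(par_names))
  if (r_free) init[blocks$dispersion] <- priors$r_max / 2

  car_blk <- NULL
  if (car) {
    d <- dim(landscape$human_density)
    if (any(mask)) stop("CAR variant currently requires a fully unmasked grid")
    adjc <- car_adjacency(d[1], d[2])
    llcell <- function(idx, mu_cell, theta) {
      if (family == "poisson") stats::dpois(y[idx], mu_cell, log = TRUE)
      else stats::dnbinom(y[idx], size = if (r_free) theta[["r"]] else r,
                          mu = mu_cell, log = TRUE)
    }
    car_blk <- list(adjacency = adjc, loglik_cell = llcell,
                    tau_shape = priors$tau_shape, tau_rate = priors$tau_rate,
                    intercept_idx = if (intercepts) blocks$intercepts
                                    else integer())
  }
  m <- mcmc_model(par_names, init, log_posterior, blocks,
                  deviance = function(theta, rho = NULL)
                    -2 * loglik(theta, rho),
                  log_scale = log_scale, car = car_blk, mu_fn = mu_fn)
  m$log_prior <- log_prior
  m$info <- list(cells = cells, y = y, Hb = Hb, classes = classes,
                 lc_idx = lc_idx, kinds = kinds,
                 dim = dim(landscape$human_density))
  m
}
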