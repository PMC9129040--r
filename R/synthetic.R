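#' Stationary Gaussian random field on a grid
#'
#' Simulates a zero-mean Gaussian random field with exponential covariance
#' `sill * exp(-d / range)` (distance in cell units) by circulant embedding
#' on a doubled torus: exact up to clamping of the (typically negligible)
#' negative embedding eigenvalues. `range = 0` degenerates to white noise.
#'
#' @param nr,nc grid dimensions.
#' @param range correlation length in cells (>= 0).
#' @param sill marginal variance.
#' @return An `nr` x `nc` numeric matrix.
#' @export
gaussian_random_field <- function(nr, nc, range, sill = 1) {
  if (nr < 1 || nc < 1) stop("grid dimensions must be positive")
  if (range < 0 || sill < 0) stop("`range` and `sill` must be >= 0")
  if (range < 1e-12)
    return(matrix(stats::rnorm(nr * nc, sd = sqrt(sill)), nr, nc))
  M1 <- 2^ceiling(log2(max(2 * nr, 4)))
  M2 <- 2^ceiling(log2(max(2 * nc, 4)))
  d1 <- pmin(0:(M1 - 1), M1 - (0:(M1 - 1)))
  d2 <- pmin(0:(M2 - 1), M2 - (0:(M2 - 1)))
  D <- sqrt(outer(d1^2, d2^2, "+"))
  lambda <- Re(stats::fft(sill * exp(-D / range)))
  lambda[lambda < 0] <- 0  # embedding defect; tiny for the exponential model
  eps <- matrix(complex(real = stats::rnorm(M1 * M2),
                        imaginary = stats::rnorm(M1 * M2)), M1, M2)
  Z <- Re(stats::fft(sqrt(lambda / (M1 * M2)) * eps))
  Z[seq_len(nr), seq_len(nc), drop = FALSE]
}

# Derived per-layer RNG stream so adding a layer leaves the others unchanged.
derive_seed <- function(master, offset) {
  s <- (as.numeric(master) * 10007 + 131 * offset) %% 2147483629
  as.integer(s) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Synthetic-scenario configuration
#'
#' Describes one synthetic study system: grid shape, species set and traits,
#' marginal distributions and correlation lengths of the abundance and human
#' fields, blocky land-cover composition, the true contact and envenoming
#' models, the observation family and optional CAR spatial heterogeneity.
#' Defaults emulate the reference system: seven species with log-Gaussian
#' spatially autocorrelated abundances, a right-skewed human density field
#' with a few urban hotspots, five land-cover classes in realistic
#' proportions, a mass-action contact process with a land-cover-stratified
#' `log_H_squared` human-impact adjustment, and per-cell populations of a few
#' thousand people per 25 km^2 cell.
#'
#' @param nrow,ncol grid shape (each >= 2).
#' @param traits true [species_traits()].
#' @param abundance_meanlog,abundance_sdlog log-Gaussian abundance marginals,
#'   recycled over species.
#' @param abundance_range abundance-field correlation length (cells).
#' @param human_meanlog,human_sdlog,human_range log-Gaussian human field.
#' @param hotspots,hotspot_amp,hotspot_width number, relative amplitude and
#'   width (cells) of multiplicative population hotspots.
#' @param lc_props named class proportions over [LAND_COVER_CLASSES]
#'   (must sum to 1).
#' @param lc_patch land-cover patch size in cells (blocky patches).
#' @param spec true [contact_model_spec()] (carries the observation family
#'   and, for `"negbin"`, the dispersion `r`).
#' @param env_model true [envenoming_model()], or `NULL` to skip the
#'   envenoming stage.
#' @param car_on simulate a CAR heterogeneity field multiplying the expected
#'   counts by `exp(rho)`.
#' @param tau CAR precision.
#' @param seed master RNG seed; all layers draw from streams derived from it.
#' @return An object of class `scenario`.
#' @export
scenario_config <- function(nrow = 50, ncol = 50,
                            traits = default_traits(),
                            abundance_meanlog = log(400),
                            abundance_sdlog = 0.6,
                            abundance_range = 4,
                            human_meanlog = log(2000), human_sdlog = 1,
                            human_range = 6,
                            hotspots = 3, hotspot_amp = 3, hotspot_width = 4,
                            lc_props = c(agriculture = 0.35, degraded = 0.2,
                                         forest = 0.25, tea = 0.1,
                                         urban = 0.1),
                            lc_patch = 5,
                            spec = default_contact_spec(traits),
                            env_model = default_envenoming_model(traits),
                            car_on = FALSE, tau = 10, seed = 1) {
  if (nrow < 2 || ncol < 2) stop("degenerate grid shape: need at least 2 x 2")
  stopifnot(inherits(traits, "species_traits"),
            inherits(spec, "contact_spec"))
  if (!setequal(names(lc_props), LAND_COVER_CLASSES))
    stop("`lc_props` must be named over the canonical land-cover classes")
  lc_props <- lc_props[LAND_COVER_CLASSES]
  if (abs(sum(lc_props) - 1) > 1e-8) stop("`lc_props` must sum to 1")
  if (any(lc_props < 0)) stop("`lc_props` must be >= 0")
  stopifnot(abundance_sdlog > 0, human_sdlog > 0, abundance_range >= 0,
            human_range >= 0, lc_patch >= 1, tau > 0)
  n_sp <- nrow(traits)
  structure(list(
    nrow = nrow, ncol = ncol, traits = traits,
    abundance_meanlog = rep_len(abundance_meanlog, n_sp),
    abundance_sdlog = rep_len(abundance_sdlog, n_sp),
    abundance_range = abundance_range,
    human_meanlog = human_meanlog, human_sdlog = human_sdlog,
    human_range = human_range, hotspots = hotspots,
    hotspot_amp = hotspot_amp, hotspot_width = hotspot_width,
    lc_props = lc_props, lc_patch = lc_patch,
    spec = spec, env_model = env_model,
    car_on = car_on, tau = tau, seed = seed), class = "scenario")
}

#' Synthetic placeholder traits for the seven reference species
#'
#' Illustrative index values in (0, 1] and small contact-rate scales; these
#' are package placeholders for simulation, not field estimates.
#'
#' @param species which species to include.
#' @return A [species_traits()] table.
#' @export
default_traits <- function(species = SNAKE_SPECIES) {
  all <- species_traits(
    SNAKE_SPECIES,
    B_s = c(2.5e-05, 3.5e-05, 1.0e-05, 2.0e-05, 3.0e-06, 5.0e-05, 5.0e-06),
    A_s = c(0.80, 0.70, 0.60, 0.65, 0.40, 0.90, 0.30),
    E_s = c(0.95, 0.85, 0.90, 0.80, 0.35, 0.90, 0.25))
  out <- all[match(species, all$species_id), ]
  rownames(out) <- NULL
  structure(out, class = c("species_traits", "data.frame"))
}

# Default stratified log_H_squared adjustment over the 5 classes: strongest
# human impact on snakes in urban/tea, weakest in agriculture.
default_adjustment <- function(classes = LAND_COVER_CLASSES) {
  co <- data.frame(
    class = LAND_COVER_CLASSES,
    b0 = c(0.0, 0.2, 0.4, -0.2, -0.4),  # mean 0: the anchored gauge
    b1 = c(-0.010, -0.015, -0.005, -0.020, -0.030))
  abundance_adjustment("log_H_squared", co[co$class %in% classes, ])
}

default_contact_spec <- function(traits = default_traits()) {
  contact_model_spec("mass_action", beta = 1, traits = traits,
                     adjustment = default_adjustment(), family = "poisson")
}

default_envenoming_model <- function(traits = default_traits()) {
  # scaled to adjusted abundances of order 10^2 per cell so the logistic
  # stays away from its saturated tails
  B_s <- stats::setNames(
    c(0.0030, -0.0005, -0.0010, 0.0005, -0.0002, -0.0025, 0.0001)[
      match(traits$species_id, SNAKE_SPECIES)],
    traits$species_id)
  envenoming_model(B_s, stats::setNames(traits$E_s, traits$species_id),
                   B_LC = c(agriculture = 0.25, degraded = -0.4,
                            forest = 0.05, tea = -0.7, urban = 0.6))
}

#' Generate a synthetic landscape
#'
#' Draws the input layers of one scenario: per-species log-Gaussian
#' spatially autocorrelated abundance fields, a right-skewed human density
#' field with optional hotspots, and blocky categorical land cover. Counts
#' are not drawn here (see [simulate_counts()]). Deterministic given the
#' scenario seed; each layer uses its own derived stream, so adding a
#' species leaves the human field unchanged.
#'
#' @param cfg a [scenario_config()].
#' @return A [grid_landscape()] without observed counts.
#' @export
generate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "scenario"))
  nr <- cfg$nrow; nc <- cfg$ncol
  human <- with_seed(derive_seed(cfg$seed, 1), {
    z <- gaussian_random_field(nr, nc, cfg$human_range)
    H <- exp(cfg$human_meanlog + cfg$human_sdlog * z)
    if (cfg$hotspots > 0) {
      ci <- cbind(stats::runif(cfg$hotspots, 1, nr),
                  stats::runif(cfg$hotspots, 1, nc))
      rows <- matrix(seq_len(nr), nr, nc)
      cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      for (k in seq_len(cfg$hotspots)) {
        d2 <- (rows - ci[k, 1])^2 + (cols - ci[k, 2])^2
        H <- H * (1 + cfg$hotspot_amp * exp(-d2 / (2 * cfg$hotspot_width^2)))
      }
    }
    H
  })
  lc <- with_seed(derive_seed(cfg$seed, 2), {
    pr <- ceiling(nr / cfg$lc_patch); pc <- ceiling(nc / cfg$lc_patch)
    patch <- matrix(sample.int(length(cfg$lc_props), pr * pc, replace = TRUE,
                               prob = cfg$lc_props), pr, pc)
    full <- patch[rep(seq_len(pr), each = cfg$lc_patch),
                  rep(seq_len(pc), each = cfg$lc_patch), drop = FALSE]
    full[seq_len(nr), seq_len(nc), drop = FALSE]
  })
  snakes <- list()
  for (s in seq_len(nrow(cfg$traits))) {
    snakes[[cfg$traits$species_id[s]]] <- with_seed(
      derive_seed(cfg$seed, 10 + s), {
        z <- gaussian_random_field(nr, nc, cfg$abundance_range)
        sgrid(exp(cfg$abundance_meanlog[s] + cfg$abundance_sdlog[s] * z))
      })
  }
  grid_landscape(
    human_density = sgrid(human),
    snake_abundance = snakes,
    land_cover = sgrid(lc, kind = "categorical",
                       labels = LAND_COVER_CLASSES))
}

#' Simulate observed counts on a landscape
#'
#' Draws bite counts per cell from the scenario's observation family with
#' mean `H * P` (times `exp(rho)` if a CAR heterogeneity field is on), and
#' envenoming counts by binomial thinning of the bites with the envenoming
#' probability — enforcing envenomings <= bites <= population cellwise.
#'
#' @param landscape a [grid_landscape()].
#' @param spec the true [contact_model_spec()]; for `family = "negbin"` its
#'   `r` (scalar or named per land-cover class) is required.
#' @param env_model optional [envenoming_model()]; if `NULL` no envenoming
#'   counts are drawn.
#' @param seed RNG seed for the observation draws.
#' @param car_on,tau simulate multiplicative CAR heterogeneity `exp(rho)`.
#' @return The landscape with `bite_counts` (and possibly
#'   `envenoming_counts`) filled in, plus attributes `expected` (the
#'   noise-free mean grids) and `car_field`.
#' @export
simulate_counts <- function(landscape, spec, env_model = NULL, seed = 1,
                            car_on = FALSE, tau = 10) {
  stopifnot(inherits(landscape, "landscape"), inherits(spec, "contact_spec"))
  if (spec$family == "negbin" && is.null(spec$r))
    stop("negative binomial simulation requires the dispersion `r`")
  fw <- predict_bites(landscape, spec)
  mu <- fw$expected$values
  rho <- NULL
  if (car_on) {
    rho <- with_seed(derive_seed(seed, 600), {
      simulate_car(car_adjacency(nrow(mu), ncol(mu)), tau)
    })
    mu <- mu * exp(rho)
  }
  n <- length(mu)
  bites <- with_seed(derive_seed(seed, 500), {
    if (spec$family == "poisson") stats::rpois(n, mu)
    else {
      r_cell <- dispersion_per_cell(spec$r, landscape)
      stats::rnbinom(n, size = r_cell, mu = mu)
    }
  })
  # the two-stage logic requires envenomings <= bites <= population; the
  # count families are unbounded above, so cap at the cell population
  # (vanishingly rare at realistic scales, but the subset relation is hard)
  bites <- pmin(bites, floor(landscape$human_density$values))
  bites <- matrix(bites, nrow(mu), ncol(mu))
  out <- landscape
  out$bite_counts <- grid_like(fw$expected, bites, mask = fw$expected$mask)
  expected <- list(bites = grid_like(fw$expected, mu))
  if (!is.null(env_model)) {
    ev <- predict_envenomings(landscape, spec, env_model,
                              expected_bites = out$bite_counts)
    env <- with_seed(derive_seed(seed, 501), {
      stats::rbinom(n, size = as.vector(bites), prob = as.vector(
        ev$P_env$values))
    })
    out$envenoming_counts <- grid_like(fw$expected,
                                       matrix(env, nrow(mu), ncol(mu)))
    expected$P_env <- ev$P_env
  }
  attr(out, "expected") <- expected
  attr(out, "car_field") <- rho
  out
}

# Map a scalar or per-class dispersion to cells (internal).
dispersion_per_cell <- function(r, landscape) {
  if (length(r) == 1 && is.null(names(r)))
    return(rep(as.numeric(r), length(landscape$human_density$values)))
  lc <- landscape$land_cover$labels[landscape$land_cover$values]
  out <- as.numeric(r[lc])
  if (any(is.na(out) & !is.na(lc)))
    stop("dispersion `r` missing for class: ",
         paste(unique(lc[is.na(out)]), collapse = ", "))
  out
}

#' Canned synthetic fixtures with known truth
#'
#' Small registered scenarios for regression and recovery tests:
#'
#' * `"minimal"`: 10 x 10, 2 species, Poisson, mass action with a stratified
#'   `log_H_squared` adjustment over 2 realised land-cover classes, no CAR.
#' * `"paper-like"`: 30 x 30, 7 species, negative binomial with per-class
#'   dispersion, CAR heterogeneity on.
#'
#' @param name fixture name.
#' @param seed master seed (layers and counts derive from it).
#' @return List with `landscape` (counts filled in), `truth` (the generating
#'   `spec`, `env_model`, CAR settings) and `expected` (noise-free means).
#' @export
make_fixture <- function(name = c("minimal", "paper-like"), seed = 1) {
  name <- match.arg(name)
  if (name == "minimal") {
    traits <- default_traits(c("N_naja", "D_russelii"))
    adj <- abundance_adjustment("log_H_squared", data.frame(
      class = c("agriculture", "forest"),
      b0 = c(-0.2, 0.2), b1 = c(-0.010, -0.030)))
    spec <- contact_model_spec("mass_action", beta = 1, traits = traits,
                               adjustment = adj, family = "poisson")
    cfg <- scenario_config(
      nrow = 10, ncol = 10, traits = traits, spec = spec, env_model = NULL,
      lc_props = c(agriculture = 0.5, degraded = 0, forest = 0.5, tea = 0,
                   urban = 0),
      lc_patch = 3, hotspots = 1, seed = seed)
    ls <- generate_landscape(cfg)
    sim <- simulate_counts(ls, spec, env_model = NULL, seed = seed)
    truth <- list(spec = spec, env_model = NULL, car_on = FALSE, tau = NULL)
  } else {
    traits <- default_traits()
    spec <- contact_model_spec(
      "mass_action", beta = 1, traits = traits,
      adjustment = default_adjustment(), family = "negbin",
      r = c(agriculture = 20, degraded = 15, forest = 10, tea = 8,
            urban = 12))
    env <- default_envenoming_model(traits)
    cfg <- scenario_config(nrow = 30, ncol = 30, traits = traits,
                           spec = spec, env_model = env, seed = seed)
    ls <- generate_landscape(cfg)
    sim <- simulate_counts(ls, spec, env_model = env, seed = seed,
                           car_on = TRUE, tau = 10)
    truth <- list(spec = spec, env_model = env, car_on = TRUE, tau = 10)
  }
  list(landscape = sim, truth = truth, expected = attr(sim, "expected"),
       car_field = attr(sim, "car_field"))
}
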