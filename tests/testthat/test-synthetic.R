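test_that("landscape generation is deterministic given the seed", {
  cfg <- scenario_config(nrow = 12, ncol = 12, seed = 5)
  a <- generate_landscape(cfg)
  b <- generate_landscape(cfg)
  expect_identical(a$human_density$values, b$human_density$values)
  expect_identical(a$land_cover$values, b$land_cover$values)
  for (sp in landscape_species(a))
    expect_identical(a$snake_abundance[[sp]]$values,
                     b$snake_abundance[[sp]]$values)
  c2 <- generate_landscape(scenario_config(nrow = 12, ncol = 12, seed = 6))
  expect_false(identical(a$human_density$values, c2$human_density$values))
  expect_error(scenario_config(nrow = 1, ncol = 5), "degenerate")
})

test_that("per-layer seed streams: adding a species keeps the human field", {
  tr2 <- default_traits(c("N_naja", "D_russelii"))
  tr3 <- default_traits(c("N_naja", "D_russelii", "Hypnale_spp"))
  a <- generate_landscape(scenario_config(nrow = 10, ncol = 10, traits = tr2,
                                          seed = 3))
  b <- generate_landscape(scenario_config(nrow = 10, ncol = 10, traits = tr3,
                                          seed = 3))
  expect_identical(a$human_density$values, b$human_density$values)
  expect_identical(a$snake_abundance$N_naja$values,
                   b$snake_abundance$N_naja$values)
})

test_that("zero correlation length gives uncorrelated neighbours", {
  set.seed(77)
  f <- gaussian_random_field(50, 50, range = 0)
  rho <- cor(as.vector(f[-1, ]), as.vector(f[-50, ]))
  expect_lt(abs(rho), 0.05)
})

test_that("a positive correlation length induces the exponential decay", {
  set.seed(78)
  f <- gaussian_random_field(120, 120, range = 5)
  rho1 <- cor(as.vector(f[-1, ]), as.vector(f[-120, ]))
  expect_equal(rho1, exp(-1 / 5), tolerance = 0.08)
  expect_equal(var(as.vector(f)), 1, tolerance = 0.15)
})

test_that("land-cover class proportions are realised within tolerance", {
  props <- c(agriculture = 0.4, degraded = 0.2, forest = 0.2, tea = 0.1,
             urban = 0.1)
  cfg <- scenario_config(nrow = 100, ncol = 100, lc_props = props,
                         lc_patch = 2, seed = 9)
  ls <- generate_landscape(cfg)
  real <- table(factor(grid_values(ls$land_cover),
                       levels = LAND_COVER_CLASSES)) / 1e4
  expect_true(all(abs(as.numeric(real) - as.numeric(props)) < 0.05))
})

test_that("count simulation hits the requested observation family", {
  # Poisson: replicate draws at a fixed mean match it within MC error
  cfg <- scenario_config(nrow = 10, ncol = 10, seed = 4,
                         traits = default_traits(c("N_naja", "D_russelii")),
                         spec = contact_model_spec(
                           "mass_action", beta = 1,
                           traits = default_traits(c("N_naja", "D_russelii")),
                           adjustment = tiny_adjustment(),
                           family = "poisson"),
                         env_model = NULL,
                         lc_props = c(agriculture = 0.5, degraded = 0,
                                      forest = 0.5, tea = 0, urban = 0))
  ls <- generate_landscape(cfg)
  mus <- numeric(0); draws <- numeric(0)
  for (k in 1:60) {
    sim <- simulate_counts(ls, cfg$spec, seed = 1000 + k)
    mus <- c(mus, attr(sim, "expected")$bites$values)
    draws <- c(draws, sim$bite_counts$values)
  }
  n <- length(draws)
  expect_lt(abs(mean(draws - mus)), 3 * sqrt(sum(mus)) / n)
  # Poisson dispersion: variance of standardised residuals ~ 1
  z2 <- (draws - mus)^2 / pmax(mus, 1e-12)
  expect_equal(mean(z2[mus > 0]), 1, tolerance = 0.1)
})

test_that("negative binomial simulation shows the r-governed overdispersion", {
  tr <- default_traits(c("N_naja", "D_russelii"))
  spec <- contact_model_spec("mass_action", beta = 1, traits = tr,
                             adjustment = tiny_adjustment(),
                             family = "negbin", r = 2)
  cfg <- scenario_config(nrow = 10, ncol = 10, seed = 4, traits = tr,
                         spec = spec, env_model = NULL,
                         lc_props = c(agriculture = 0.5, degraded = 0,
                                      forest = 0.5, tea = 0, urban = 0))
  ls <- generate_landscape(cfg)
  mus <- numeric(0); draws <- numeric(0)
  for (k in 1:60) {
    sim <- simulate_counts(ls, spec, seed = 2000 + k)
    mus <- c(mus, attr(sim, "expected")$bites$values)
    draws <- c(draws, sim$bite_counts$values)
  }
  # var/mean ratio ~ 1 + mu/r cellwise; pool standardised squared residuals
  z2 <- (draws - mus)^2 / (mus * (1 + mus / 2))
  expect_equal(mean(z2[mus > 0]), 1, tolerance = 0.15)
  expect_error(simulate_counts(ls, contact_model_spec(
    "mass_action", beta = 1, traits = tr, adjustment = tiny_adjustment(),
    family = "negbin"), seed = 1), "requires the dispersion")
})

test_that("simulated counts respect envenomings <= bites <= population", {
  for (sd in 1:3) {
    fx <- make_fixture("paper-like", seed = sd)
    b <- fx$landscape$bite_counts$values
    e <- fx$landscape$envenoming_counts$values
    H <- fx$landscape$human_density$values
    expect_true(all(e <= b))
    expect_true(all(b <= H))
    expect_true(all(b >= 0) && all(e >= 0))
  }
})

test_that("species relabelling with permuted traits leaves incidence alone", {
  tr <- default_traits(c("N_naja", "D_russelii", "Hypnale_spp"))
  perm <- c(3, 1, 2)
  tr_p <- structure(tr[perm, ], row.names = NULL,
                    class = class(tr))
  cfg <- scenario_config(nrow = 8, ncol = 8, traits = tr, seed = 2,
                         env_model = NULL,
                         spec = contact_model_spec("mass_action", beta = 1,
                                                   traits = tr,
                                                   adjustment = tiny_adjustment(),
                                                   family = "poisson"),
                         lc_props = c(agriculture = 0.5, degraded = 0,
                                      forest = 0.5, tea = 0, urban = 0))
  ls <- generate_landscape(cfg)
  spec_p <- contact_model_spec("mass_action", beta = 1, traits = tr_p,
                               adjustment = tiny_adjustment(),
                               family = "poisson")
  e1 <- predict_bites(ls, cfg$spec)$expected$values
  e2 <- predict_bites(ls, spec_p)$expected$values
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("fixtures carry a truth record that reproduces their means", {
  fx <- make_fixture("minimal", seed = 6)
  fw <- predict_bites(fx$landscape, fx$truth$spec)
  expect_equal(fx$expected$bites$values, fw$expected$values,
               tolerance = 1e-12)
  expect_equal(dim(fx$landscape$human_density), c(10, 10))
  expect_equal(length(landscape_species(fx$landscape)), 2)
  pl <- make_fixture("paper-like", seed = 6)
  expect_equal(dim(pl$landscape$human_density), c(30, 30))
  expect_equal(length(landscape_species(pl$landscape)), 7)
  expect_false(is.null(pl$car_field))
  # CAR heterogeneity enters the mean multiplicatively
  fw_pl <- predict_bites(pl$landscape, pl$truth$spec)
  expect_equal(pl$expected$bites$values,
               fw_pl$expected$values * exp(pl$car_field),
               tolerance = 1e-12)
  expect_error(make_fixture("nonexistent"), "arg")
})
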