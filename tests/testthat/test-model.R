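test_that("the registry lists exactly the parameters the spec implies", {
  fx <- make_fixture("paper-like", seed = 1)
  spec <- contact_model_spec("mass_action", beta = 1,
                             traits = default_traits(),
                             adjustment = default_adjustment(),
                             family = "negbin")
  m <- build_model(fx$landscape, spec, prior_set(), r_by_class = TRUE)
  # 5 b0 + 5 b1 + 7 B_s + 5 r = 22 free parameters
  expect_length(m$par_names, 22)
  expect_equal(sum(grepl("^b0\\[", m$par_names)), 5)
  expect_equal(sum(grepl("^b1\\[", m$par_names)), 5)
  expect_equal(sum(grepl("^B_", m$par_names)), 7)
  expect_equal(sum(grepl("^r\\[", m$par_names)), 5)
  expect_named(m$blocks, c("species", "coefficients", "dispersion"))

  # free shape parameters join the registry; fixed ones do not
  fx2 <- make_fixture("minimal", seed = 1)
  sp_rf <- contact_model_spec("refuge_on_H", beta = 1, q_s = NA,
                              traits = fx2$truth$spec$traits,
                              adjustment = fx2$truth$spec$adjustment)
  m2 <- build_model(fx2$landscape, sp_rf, prior_set())
  expect_true("q_s" %in% m2$par_names)
  sp_rf_fixed <- contact_model_spec("refuge_on_H", beta = 1, q_s = 2,
                                    traits = fx2$truth$spec$traits,
                                    adjustment = fx2$truth$spec$adjustment)
  expect_false("q_s" %in%
                 build_model(fx2$landscape, sp_rf_fixed, prior_set())$par_names)
})

test_that("log-posterior peaks near the truth on a fixture", {
  fx <- make_fixture("minimal", seed = 1)
  m <- build_model(fx$landscape, fx$truth$spec, prior_set())
  truth <- c(fx$truth$spec$traits$B_s, -0.2, 0.2, -0.010, -0.030)
  names(truth) <- m$par_names
  lp_truth <- m$log_posterior(m$from_report(truth))
  expect_true(is.finite(lp_truth))
  set.seed(99)
  worse <- 0
  for (k in 1:20) {
    pert <- truth
    pert[1:2] <- pert[1:2] * exp(rnorm(2, sd = 0.5))
    pert[3:4] <- pert[3:4] + rnorm(2, sd = 0.5)
    pert[5:6] <- pert[5:6] * runif(2, 0.3, 2)
    if (m$log_posterior(m$from_report(pert)) < lp_truth) worse <- worse + 1
  }
  expect_gte(worse, 18)  # typical-set sanity: truth beats random perturbation
})

test_that("a zero-count landscape pushes the contact rates to zero", {
  fx <- make_fixture("minimal", seed = 1)
  ls <- fx$landscape
  ls$bite_counts$values[] <- 0
  # without an adjustment the contact-rate scales alone carry the mean, so
  # zero observed cases must collapse them toward zero
  spec0 <- contact_model_spec("mass_action", beta = 1,
                              traits = fx$truth$spec$traits,
                              family = "poisson")
  m <- build_model(ls, spec0, prior_set())
  s <- sample_posterior(m, n_iter = 4000, n_chains = 2, seed = 2)
  sm <- summary(s)
  B_med <- sm$median[grepl("^B_", sm$parameter)]
  expect_true(all(B_med < 0.1 * fx$truth$spec$traits$B_s))
})

test_that("models without an adjustment have no gauge and identified B_s", {
  fx <- make_fixture("minimal", seed = 2)
  spec <- contact_model_spec("mass_action", beta = 1,
                             traits = fx$truth$spec$traits,
                             family = "poisson")
  m <- build_model(fx$landscape, spec, prior_set())
  expect_null(m$gauge)
  expect_named(m$blocks, "species")
})

test_that("the envenoming model graph wires intercepts and species effects", {
  fx <- make_fixture("paper-like", seed = 1)
  Hb <- predict_bites(fx$landscape, fx$truth$spec)$expected
  m <- build_envenoming_model(fx$landscape, fx$truth$spec, Hb,
                              prior_set(), intercepts = TRUE,
                              family = "poisson")
  expect_equal(sum(grepl("^B_LC\\[", m$par_names)), 5)
  expect_equal(sum(grepl("^B_[^L]", m$par_names)), 7)
  expect_true(is.finite(m$log_posterior(m$init)))
  # expected envenomings bounded by conditioning bites
  mu <- m$mu_fn(m$init)
  expect_true(all(mu <= m$info$Hb + 1e-9))
  expect_error(build_envenoming_model(make_fixture("minimal", 1)$landscape,
                                      fx$truth$spec, Hb),
               "lacks envenoming counts")
})

test_that("the CAR variant, warm-started from the non-spatial fit,
           recovers spatial heterogeneity", {
  # two-step workflow: fit without spatial effects, convert the posterior
  # into warm priors for the main effects, then fit with the CAR field.
  # Counts are kept modest so the misspecified warm-up stage converges.
  tr <- default_traits(c("N_naja", "D_russelii"))
  spec <- contact_model_spec("mass_action", beta = 1, traits = tr,
                             adjustment = tiny_adjustment(),
                             family = "poisson")
  cfg <- scenario_config(nrow = 8, ncol = 8, traits = tr, spec = spec,
                         env_model = NULL, human_meanlog = log(800),
                         human_sdlog = 0.7, hotspots = 0,
                         lc_props = c(agriculture = 0.5, degraded = 0,
                                      forest = 0.5, tea = 0, urban = 0),
                         lc_patch = 3, seed = 5)
  sim <- simulate_counts(generate_landscape(cfg), spec, seed = 5,
                         car_on = TRUE, tau = 4)
  m0 <- build_model(sim, spec, prior_set())
  s0 <- sample_posterior(m0, n_iter = 8000, n_chains = 2, seed = 8)
  m1 <- build_model(sim, spec, warm_start(s0), car = TRUE)
  s1 <- sample_posterior(m1, n_iter = 15000, n_chains = 2, seed = 9)
  expect_true("tau" %in% s1$par_names)
  sm <- summary(s1)
  expect_true(all(is.finite(sm$median)))
  # tau's credible interval covers the generating precision
  expect_lt(sm$lower95[sm$parameter == "tau"], 4)
  expect_gt(sm$upper95[sm$parameter == "tau"], 4)
  # centring constraint: the posterior-mean field sums to ~0
  rho_mean <- colMeans(do.call(rbind, s1$rho))
  expect_lt(abs(sum(rho_mean)), 1e-6)
  # the sampled field tracks the simulated heterogeneity
  expect_gt(cor(rho_mean, as.vector(attr(sim, "car_field"))), 0.4)
  # absorbing the heterogeneity improves DIC over the non-spatial fit
  expect_lt(compute_dic(s1, m1)$DIC, compute_dic(s0, m0)$DIC)
})

test_that("a negative binomial fit to Poisson data pushes r to its bound", {
  fx <- make_fixture("minimal", seed = 9)  # Poisson-generated counts
  spec_nb <- contact_model_spec("mass_action", beta = 1,
                                traits = fx$truth$spec$traits,
                                adjustment = fx$truth$spec$adjustment,
                                family = "negbin")
  m <- build_model(fx$landscape, spec_nb, prior_set())
  expect_true("r" %in% m$par_names)
  s <- sample_posterior(m, n_iter = 10000, n_chains = 2, seed = 4)
  sm <- summary(s)
  # no overdispersion to absorb: r piles up near the prior's upper bound
  expect_gt(sm$median[sm$parameter == "r"], 30)
  expect_gt(sm$upper95[sm$parameter == "r"], 45)
})
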