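# A correlated 2-D Gaussian target exercises the whole sampling machinery
# against analytic truth.
gauss2d_model <- function(mu = c(1, -2), S = matrix(c(1, 0.8, 0.8, 2), 2)) {
  Si <- solve(S)
  mcmc_model(
    par_names = c("x", "y"), init = c(0, 0),
    log_posterior = function(theta, rho = NULL) {
      d <- theta - mu
      -0.5 * as.numeric(t(d) %*% Si %*% d)
    },
    blocks = list(xy = 1:2),
    deviance = function(theta, rho = NULL) {
      d <- theta - mu
      as.numeric(t(d) %*% Si %*% d)
    })
}

test_that("the sampler recovers a known 2-D Gaussian target", {
  m <- gauss2d_model()
  s <- sample_posterior(m, n_iter = 30000, n_chains = 2, seed = 4)
  draws <- do.call(rbind, s$chains)
  expect_equal(colMeans(draws), c(x = 1, y = -2), tolerance = 0.1)
  expect_equal(cov(draws)[1, 2], 0.8, tolerance = 0.25)
  expect_equal(apply(draws, 2, var), c(x = 1, y = 2), tolerance = 0.25)
  sm <- summary(s)
  expect_true(all(sm$rhat < 1.05))
})

test_that("sampling is reproducible and seeds differentiate chains", {
  m <- gauss2d_model()
  a <- sample_posterior(m, n_iter = 2000, n_chains = 2, seed = 9)
  b <- sample_posterior(m, n_iter = 2000, n_chains = 2, seed = 9)
  expect_identical(a$chains, b$chains)
  c2 <- sample_posterior(m, n_iter = 2000, n_chains = 2, seed = 10)
  expect_false(identical(a$chains[[1]], c2$chains[[1]]))
  expect_false(identical(a$chains[[1]], a$chains[[2]]))
})

test_that("initial-state handling: overrides and non-finite starts", {
  m <- gauss2d_model()
  expect_error(sample_posterior(m, n_iter = 100, init_overrides =
                                  list(zz = 1)), "unknown parameters")
  bad <- mcmc_model("x", 0, function(theta, rho = NULL) -Inf,
                    blocks = list(x = 1L))
  expect_error(sample_posterior(bad, n_iter = 100, n_chains = 1, seed = 1),
               "non-finite initial log-posterior")
  # overrides land in the chains
  s <- sample_posterior(m, n_iter = 200, burn_in = 100, n_chains = 1,
                        seed = 1, init_overrides = list(x = 1, y = -2))
  expect_true(is.finite(s$chains[[1]][1, 1]))
})

test_that("acceptance rates settle inside the adaptive targets", {
  m <- gauss2d_model()
  s <- sample_posterior(m, n_iter = 20000, n_chains = 1, seed = 6)
  acc <- s$acceptance[[1]]["xy"]
  expect_gt(acc, 0.15); expect_lt(acc, 0.55)
})

test_that("warm starts carry posterior moments into the next prior set", {
  fx <- make_fixture("minimal", seed = 4)
  m <- build_model(fx$landscape, fx$truth$spec, prior_set())
  s <- sample_posterior(m, n_iter = 8000, n_chains = 2, seed = 3)
  pr2 <- warm_start(s)
  sm <- summary(s)
  expect_named(pr2$warm, sm$parameter[grepl("^(B_|b0\\[|b1\\[)", sm$parameter)],
               ignore.order = TRUE)
  i <- match("B_N_naja", sm$parameter)
  expect_equal(pr2$warm$B_N_naja, c(sm$mean[i], sm$sd[i]))
  # degenerate chains floor the sd instead of collapsing the prior
  s0 <- s
  s0$chains <- lapply(s0$chains, function(m2) { m2[, 1] <- 1; m2 })
  pr3 <- suppressWarnings(warm_start(s0, min_sd = 1e-3))
  expect_equal(pr3$warm$B_N_naja[2], 1e-3)
  # warm priors actually drive prior evaluation
  expect_equal(prior_logdensity(pr2, "B_N_naja", pr2$warm$B_N_naja[1], "B"),
               dnorm(0, sd = pr2$warm$B_N_naja[2], log = TRUE))
})

test_that("posterior containers summarise and serialise", {
  m <- gauss2d_model()
  s <- sample_posterior(m, n_iter = 3000, n_chains = 2, seed = 12)
  sm <- summary(s)
  expect_named(sm, c("parameter", "mean", "sd", "median", "lower95",
                     "upper95", "rhat"))
  df <- as.data.frame(s)
  expect_equal(nrow(df), 2 * nrow(s$chains[[1]]) * 2)
  dir <- file.path(tempdir(), "post")
  write_posterior(s, dir)
  expect_true(file.exists(file.path(dir, "posterior_long.csv")))
  js <- jsonlite::read_json(file.path(dir, "posterior_summary.json"),
                            simplifyVector = TRUE)
  expect_equal(js$x$median, sm$median[1], tolerance = 1e-12)
})
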