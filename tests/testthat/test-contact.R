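test_that("effective abundance is the trait-weighted species sum", {
  one <- species_traits("N_naja", B_s = 1, A_s = 1, E_s = 1)
  expect_equal(effective_abundance(list(N_naja = matrix(10, 1, 1)), one,
                                   "snakebite"),
               matrix(10, 1, 1))
  tr <- species_traits(c("a", "b"), B_s = c(2, 1), A_s = c(0.5, 1),
                       E_s = c(1, 1))
  got <- effective_abundance(list(a = matrix(4, 1, 1), b = matrix(3, 1, 1)),
                             tr, "snakebite")
  expect_equal(got, matrix(2 * 0.5 * 4 + 1 * 1 * 3, 1, 1))  # = 7
  # envenoming stage multiplies in E_s
  tr2 <- species_traits(c("a", "b"), B_s = c(2, 1), A_s = c(0.5, 1),
                        E_s = c(0.5, 0.2))
  got2 <- effective_abundance(list(a = matrix(4, 1, 1), b = matrix(3, 1, 1)),
                              tr2, "envenoming")
  expect_equal(got2, matrix(2 * 0.5 * 0.5 * 4 + 1 * 1 * 0.2 * 3, 1, 1))
  # zero abundance everywhere stays zero
  expect_true(all(effective_abundance(list(a = matrix(0, 2, 2),
                                           b = matrix(0, 2, 2)),
                                      tr, "snakebite") == 0))
  expect_error(effective_abundance(list(zz = matrix(1, 1, 1)), tr,
                                   "snakebite"), "traits missing")
})

test_that("trait tables validate their index ranges", {
  expect_error(species_traits("x", B_s = -1, A_s = 0.5, E_s = 0.5), "B_s")
  expect_error(species_traits("x", B_s = 1, A_s = 0, E_s = 0.5), "A_s")
  expect_error(species_traits("x", B_s = 1, A_s = 0.5, E_s = 1.2), "E_s")
  expect_error(species_traits(c("x", "x"), B_s = c(1, 1), A_s = c(1, 1),
                              E_s = c(1, 1)), "duplicated")
  tr <- read_species_traits(system.file("extdata",
                                        "species_traits_synthetic.csv",
                                        package = "snakespill"))
  expect_s3_class(tr, "species_traits")
  expect_equal(nrow(tr), 7)
})

test_that("human-impact multiplier evaluates its four forms", {
  adj <- tiny_adjustment()
  # empty cells: log1p(0) = 0 so the multiplier is exactly exp(b0)
  expect_equal(abundance_multiplier(0, "agriculture", adj), exp(-0.2))
  expect_equal(abundance_multiplier(0, "forest", adj), exp(0.2))
  # b1 = 0 makes the multiplier independent of H
  flat <- abundance_adjustment("log_H_squared",
                               data.frame(class = "tea", b0 = 1.3, b1 = 0))
  expect_equal(abundance_multiplier(c(0, 10, 1e4), rep("tea", 3), flat),
               rep(exp(1.3), 3))
  expect_error(abundance_multiplier(5, "swamp", adj), "unknown land-cover")
  expect_error(abundance_multiplier(-1, "forest", adj), ">= 0")

  lin <- abundance_adjustment("linear_H",
                              data.frame(class = "global", b0 = 0.5, b1 = -0.01))
  expect_equal(abundance_multiplier(200, NULL, lin), exp(0.5 - 2))
  sq <- abundance_adjustment("H_squared",
                             data.frame(class = "global", b0 = 0, b1 = -1e-4))
  expect_equal(abundance_multiplier(50, NULL, sq), exp(-0.25))
  both <- abundance_adjustment("H_plus_H2",
                               data.frame(class = "global", b0 = 1,
                                          b1 = -0.1, b2 = 1e-3))
  expect_equal(abundance_multiplier(10, NULL, both), exp(1 - 1 + 0.1))
})

test_that("the published agriculture coefficients evaluate as printed", {
  # b0 = -12.9, b1 = -0.004 at H = e^10: exp(-12.9 - 0.004 * log(1+H)^2),
  # numerically exp(-12.9 - 0.4) up to the +1 offset in the logarithm
  adj <- abundance_adjustment("log_H_squared",
                              data.frame(class = "agriculture",
                                         b0 = -12.9, b1 = -0.004))
  got <- abundance_multiplier(exp(10), "agriculture", adj)
  oracle <- exp(-12.9 - 0.004 * log1p(exp(10))^2)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_equal(got, exp(-12.9 - 0.4), tolerance = 1e-3)
})

test_that("all six discrete forms give P = 0 with no snakes and stay in [0,1]", {
  specs <- all_contact_specs()
  H <- matrix(c(0, 1, 50, 2000), 2, 2)
  S0 <- matrix(0, 2, 2)
  for (nm in names(specs)) {
    expect_true(all(contact_probability(specs[[nm]], H, S0) == 0),
                label = paste(nm, "zero snakes"))
  }
  set.seed(20)
  for (nm in names(specs)) {
    Hr <- matrix(rlnorm(100, 5, 2), 10)
    Sr <- matrix(rlnorm(100, 0, 2), 10)
    P <- contact_probability(specs[[nm]], Hr, Sr)
    expect_true(all(P >= 0 & P <= 1), label = paste(nm, "in [0,1]"))
  }
  expect_error(contact_probability(specs$mass_action, -1, 1), ">= 0")
})

test_that("mass action has the closed form and its monotonicity", {
  spec <- contact_model_spec("mass_action", beta = 1, traits = tiny_traits())
  expect_equal(contact_probability(spec, 100, 0.5), 1 - exp(-0.5),
               tolerance = 1e-12)
  S <- seq(0, 5, 0.1)
  P <- contact_probability(spec, rep(1, length(S)), S)
  expect_true(all(diff(P) > 0))  # strictly increasing in S_eff
  # independent of H given fixed S_eff
  expect_equal(contact_probability(spec, 1, 2),
               contact_probability(spec, 1e6, 2))
})

test_that("discretisation maps rates to annual probabilities", {
  f <- discretise("mass_action", list(beta = 1))
  expect_equal(f(10, 0), 0)
  # small-rate limit P ~ beta*S within 1% at 0.01
  expect_equal(f(10, 0.01) / 0.01, 1, tolerance = 0.01)
  expect_error(discretise("gravity", list()), "unknown relationship")
  expect_error(discretise("power", list(beta = 1))(1, 1), "needs")
})

test_that("refuge forms clamp negative rates and vanish without humans", {
  rs <- discretise("refuge_on_S", list(beta = 1, q_h = 2))
  # S/H < 1/q_h: more refuge than exposure, probability 0
  expect_equal(rs(H = 10, S = 1), 0)
  expect_equal(rs(H = 10, S = 10), 1 - exp(-(1 - 0.5)))
  expect_equal(rs(H = 0, S = 5), 0)
  rh <- discretise("refuge_on_H", list(beta = 0.1, q_s = 0.5))
  expect_equal(rh(H = 10, S = 2), 1 - exp(-0.1 * 2 * (1 - 2 / 5)))
  expect_equal(rh(H = 10, S = 100), 0)  # crowding beyond refuge capacity
  expect_equal(rh(H = 0, S = 5), 0)
})

test_that("refuge_on_H discrete form equals the one-step ODE solution", {
  skip_if_not_installed("deSolve")
  beta <- 0.05; q_s <- 0.8; H <- 120; S <- 30
  rate <- beta * S * (1 - S / (q_s * H))
  # dHs/dt = -rate * Hs over one year; P = 1 - Hs(1)/Hs(0)
  sol <- deSolve::lsoda(c(Hs = H), c(0, 1),
                        function(t, y, p) list(-rate * y), NULL,
                        rtol = 1e-10, atol = 1e-10)
  P_ode <- 1 - sol[2, "Hs"] / H
  f <- discretise("refuge_on_H", list(beta = beta, q_s = q_s))
  expect_equal(f(H, S), as.numeric(P_ode), tolerance = 1e-8)
})

test_that("asymptotic variants saturate and halve at their constant", {
  fS <- discretise("asymptotic", list(beta = 0.01, c_half = 20,
                                      asymptote_on = "S"))
  fH <- discretise("asymptotic", list(beta = 0.01, c_half = 20,
                                      asymptote_on = "H"))
  # at X = c the continuous rate is half the mass-action rate
  ma <- discretise("mass_action", list(beta = 0.01))
  expect_equal(-log(1 - fS(50, 20)), -log(1 - ma(50, 20)) / 2,
               tolerance = 1e-12)
  expect_equal(-log(1 - fH(20, 5)), -log(1 - ma(20, 5)) / 2,
               tolerance = 1e-12)
  # saturating in S: rate bounded as S grows
  expect_lt(-log(1 - fS(50, 1e8)), 0.01 * 20 * 1.001)
})

test_that("spec validation enforces exactly the needed parameters", {
  tr <- tiny_traits()
  expect_error(contact_model_spec("power", beta = 1, p = 0.5, traits = tr),
               "requires parameter")
  expect_error(contact_model_spec("mass_action", beta = 1, q_h = 2,
                                  traits = tr), "not used")
  expect_error(contact_model_spec("separate_asymptotic", epsilon = 1.2,
                                  traits = tr), "0, 1")
  expect_error(contact_model_spec("refuge_on_H", q_s = -2, traits = tr),
               "> 0")
  # NA marks a shape parameter as free (estimated)
  sp <- contact_model_spec("refuge_on_H", q_s = NA, traits = tr)
  expect_true(is.na(sp$q_s))
})

test_that("expected bites respect the susceptible-population bound", {
  expect_equal(expected_bites(200, 0.01), 2)
  expect_equal(expected_bites(200, 0), 0)
  expect_equal(expected_bites(200, 1), 200)
  set.seed(30)
  H <- matrix(rlnorm(64, 6, 1), 8)
  P <- matrix(runif(64), 8)
  expect_true(all(expected_bites(H, P) <= H))
  expect_error(expected_bites(-1, 0.5), ">= 0")
  expect_error(expected_bites(10, 1.5), "0, 1")
})
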