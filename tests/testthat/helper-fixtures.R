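# Small deterministic fixtures shared across tests. Everything is built in
# code; no data files.

tiny_traits <- function() {
  species_traits(c("N_naja", "D_russelii"),
                 B_s = c(0.006, 0.0012), A_s = c(0.9, 0.6),
                 E_s = c(0.9, 0.9))
}

tiny_adjustment <- function() {
  abundance_adjustment("log_H_squared", data.frame(
    class = c("agriculture", "forest"),
    b0 = c(-0.2, 0.2), b1 = c(-0.010, -0.030)))
}

# A fully deterministic 4 x 5 landscape (no RNG) for structural tests.
tiny_landscape <- function(with_counts = FALSE) {
  nr <- 4; nc <- 5
  H <- sgrid(matrix(100 * (1:(nr * nc)), nr, nc))
  lc_codes <- matrix(rep(c(1L, 3L), length.out = nr * nc), nr, nc)
  lc <- sgrid(lc_codes, kind = "categorical", labels = LAND_COVER_CLASSES)
  snakes <- list(
    N_naja = sgrid(matrix(3 + sin(1:(nr * nc)), nr, nc)),
    D_russelii = sgrid(matrix(2 + cos(1:(nr * nc)), nr, nc)))
  counts <- if (with_counts)
    sgrid(matrix(rep(c(5, 0, 12, 3), length.out = nr * nc), nr, nc))
  else NULL
  grid_landscape(H, snakes, lc, bite_counts = counts)
}

# All six relationships with valid parameters, for sweeps.
all_contact_specs <- function(traits = tiny_traits()) {
  list(
    mass_action = contact_model_spec("mass_action", beta = 0.01,
                                     traits = traits),
    power = contact_model_spec("power", beta = 0.01, p = 0.8, q = 1.1,
                               traits = traits),
    refuge_on_S = contact_model_spec("refuge_on_S", beta = 0.01, q_h = 2,
                                     traits = traits),
    refuge_on_H = contact_model_spec("refuge_on_H", beta = 0.01, q_s = 0.5,
                                     traits = traits),
    separate_asymptotic = contact_model_spec("separate_asymptotic",
                                             beta = 0.01, epsilon = 0.4,
                                             traits = traits),
    asymptotic = contact_model_spec("asymptotic", beta = 0.01, c_half = 50,
                                    traits = traits))
}
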