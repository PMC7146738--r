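# Shared fixtures: small synthetic datasets and an exact additive oracle.

ester_pair <- c("EA", "BA")

make_dataset <- function(seed, ..., pair = ester_pair) {
  generate_panel_dataset(
    generator_config(pair[1], pair[2], seed = seed, ...))
}

# Exact ground-truth predictor for a generated dataset's pair.
truth_predictor <- function(pair, rho_max, shape_p = 1) {
  oa <- get_odorant(pair[1])
  ob <- get_odorant(pair[2])
  function(conc_a, conc_b) {
    true_mixture_oi(ln_oav(conc_a, oa), ln_oav(conc_b, ob),
                    oa$family, ob$family, rho_max, shape_p)
  }
}

# Small grid keeps CV affordable in pipeline-level tests.
small_grid <- function() {
  hyperparameter_grid(c_values = 2^c(1, 5, 9), gamma_values = 2^c(-7, -3, 1))
}
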