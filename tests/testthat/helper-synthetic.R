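# Shared fixtures: small synthetic configurations kept cheap enough for
# unit tests; the defaults are exercised in the acceptance suite.

small_plan <- function(seed = 1L, ...) {
  sampling_plan(n_plant_sections = 2, n_carb_sections = 3,
                n_sst_sections = 2, samples_per_section = 25, seed = seed,
                ...)
}

# a constant-history configuration (no excursion anywhere)
constant_config <- function(pco2 = 425, carb = 2.2, sst = 25) {
  true_history_config(pco2_background = pco2, pco2_peak = pco2,
                      pco2_post = pco2,
                      d13c_carb_background = carb, cie_carb = 0,
                      d13c_carb_post = carb,
                      sst_background = sst, sst_rise = 0, sst_post = sst)
}

# exact (noise-free, zero-sd) reconstruction inputs from a true history
exact_inputs <- function(truth, pco2_ref = attr(truth, "config")$pco2_background) {
  list(plant = stack_from_truth(truth, "d13c_p"),
       carb = stack_from_truth(truth, "d13c_carb"),
       sst = stack_from_truth(truth, "sst"),
       params = proxy_params(A_sd = 0, B_sd = 0,
                             pco2_ref = pco2_ref, pco2_ref_sd = 0,
                             d13c_p_ref = truth$d13c_p_true[1],
                             d13c_p_ref_sd = 0))
}

# independent inversion oracle: solve the forward hyperbola by root finding
bisect_invert <- function(ddc, pco2_ref, params = proxy_params()) {
  f <- function(p) frac_forward(p, params) - frac_forward(pco2_ref, params) - ddc
  stats::uniroot(f, c(0, 1e8), tol = 1e-10)$root
}
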