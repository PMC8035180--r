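test_that("degenerate propagation collapses to the reference pCO2 everywhere", {
  truth <- generate_true_history(constant_config())
  truth$d13c_p_true <- forward_model_plant_d13c(truth)
  inp <- exact_inputs(truth)
  rec <- mc_reconstruct(inp$plant, inp$carb, inp$sst, inp$params,
                        n_draws = 200, seed = 1)
  expect_equal(rec$median, rep(425, nrow(rec)))
  expect_equal(rec$p16, rec$median)
  expect_equal(rec$p84, rec$median)
  expect_true(all(rec$n_valid == 200))
  # degenerate interval: zero errors
  iv <- report_interval(rec, rec$age_ma[10])
  expect_equal(unname(iv), c(425, 0, 0))
})

test_that("with only the reference-pCO2 prior active the median recovers its mean", {
  truth <- generate_true_history(constant_config())
  truth$d13c_p_true <- forward_model_plant_d13c(truth)
  grid1 <- truth[1:3, ]  # short grid is enough when nothing varies in time
  pl <- stack_from_truth(grid1, "d13c_p")
  ca <- stack_from_truth(grid1, "d13c_carb")
  ss <- stack_from_truth(grid1, "sst")
  pp <- proxy_params(A_sd = 0, B_sd = 0, pco2_ref = 425, pco2_ref_sd = 68,
                     d13c_p_ref = grid1$d13c_p_true[1], d13c_p_ref_sd = 0)
  rec <- mc_reconstruct(pl, ca, ss, pp, n_draws = 10000, seed = 3)
  expect_equal(rec$median[1], 425, tolerance = 3 / 425)
  # draws are shared across gridsteps: identical summaries at every step
  expect_equal(rec$median, rep(rec$median[1], 3))
})

test_that("reconstruction summaries and intervals follow the percentile rules", {
  rec <- structure(
    data.frame(age_ma = c(252.2, 252.198), median = c(550, 500),
               p16 = c(244, 400), p84 = c(856, 600),
               n_valid = c(10L, 10L), excluded_frac = c(0, 0)),
    class = c("pco2_reconstruction", "data.frame"))
  iv <- report_interval(rec, 252.2)
  expect_equal(unname(iv), c(550, 306, 306))
  expect_warning(report_interval(rec, 252.150), "off-grid")
  # type-7 quantiles of an injected draw set match the reported convention
  draws <- seq(100, 1000, by = 100)
  q <- quantile(draws, c(0.16, 0.5, 0.84), type = 7, names = FALSE)
  expect_equal(q, c(244, 550, 856))
})

test_that("noisy default reconstruction is right-skewed at peak with bounded exclusions", {
  ds <- synthetic_dataset()
  stacks <- lapply(split(ds$samples, ds$samples$substrate), fit_stack,
                   grid = ds$truth$age_ma, span = 0.3)
  pp <- proxy_params(d13c_p_ref = ds$truth$d13c_p_true[1])
  rec <- mc_reconstruct(stacks$plant, stacks$carbonate, stacks$sst, pp,
                        n_draws = 4000, seed = 2)
  i <- which.max(rec$median)
  expect_gt(rec$p84[i] - rec$median[i], rec$median[i] - rec$p16[i])
  # exclusion fraction below one half everywhere, and larger at the peak
  expect_true(all(rec$excluded_frac < 0.5, na.rm = TRUE))
  bg <- which.max(rec$age_ma * is.finite(rec$median))
  expect_gte(rec$excluded_frac[i], rec$excluded_frac[bg])
  expect_true(all(rec$p16 <= rec$median & rec$median <= rec$p84,
                  na.rm = TRUE))
  # Monte Carlo stability: an independent seed moves the peak median by
  # little relative to the band width
  rec2 <- mc_reconstruct(stacks$plant, stacks$carbonate, stacks$sst, pp,
                         n_draws = 4000, seed = 202)
  expect_lt(abs(rec2$median[i] - rec$median[i]),
            0.1 * (rec$p84[i] - rec$p16[i]))
})

test_that("grid mismatches and bad draw counts are rejected", {
  truth <- generate_true_history(constant_config())
  truth$d13c_p_true <- forward_model_plant_d13c(truth)
  inp <- exact_inputs(truth)
  short <- inp$carb[-1, ]
  expect_error(mc_reconstruct(inp$plant, short, inp$sst, inp$params),
               "same age grid")
  expect_error(mc_reconstruct(inp$plant, inp$carb, inp$sst, inp$params,
                              n_draws = 50), "at least 100")
})

test_that("sensitivity sweeps move the peak in the analytically expected direction", {
  truth <- generate_true_history()
  truth$d13c_p_true <- forward_model_plant_d13c(truth)
  inp <- exact_inputs(truth)
  # single value: identical to a direct reconstruction
  sw0 <- sensitivity_sweep(inp$plant, inp$carb, inp$sst, inp$params,
                           "pco2_ref", 425, n_draws = 200, seed = 4)
  rec <- mc_reconstruct(inp$plant, inp$carb, inp$sst, inp$params,
                        n_draws = 200, seed = 4)
  expect_equal(sw0$peak_median, max(rec$median))
  # larger reference pCO2 raises the peak strictly
  sw <- sensitivity_sweep(inp$plant, inp$carb, inp$sst, inp$params,
                          "pco2_ref", c(300, 425, 500), n_draws = 200,
                          seed = 4)
  expect_true(all(diff(sw$peak_median) > 0))
  # pushing the reference high enough sends the peak fractionation change
  # beyond the asymptote: those gridsteps drop out with a warning
  expect_warning(
    sensitivity_sweep(inp$plant, inp$carb, inp$sst, inp$params,
                      "pco2_ref", 600, n_draws = 200, seed = 4),
    "no valid draw")
  # larger curvature B saturates the hyperbola sooner, so a fixed
  # fractionation change maps to a higher peak -- the sweep must move in
  # the same direction as the root-finding oracle
  swb <- sensitivity_sweep(inp$plant, inp$carb, inp$sst, inp$params, "B",
                           c(0.22, 0.25), n_draws = 200, seed = 4)
  ddc_pk <- frac_forward(2500) - frac_forward(425)
  oracle_dir <- sign(bisect_invert(ddc_pk, 425, proxy_params(B = 0.25)) -
                       bisect_invert(ddc_pk, 425, proxy_params(B = 0.22)))
  expect_identical(sign(swb$peak_median[2] - swb$peak_median[1]),
                   oracle_dir)
  expect_gt(swb$peak_median[2], swb$peak_median[1])
  expect_error(sensitivity_sweep(inp$plant, inp$carb, inp$sst, inp$params,
                                 "no_such", 1), "unknown parameter")
})
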