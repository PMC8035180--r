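test_that("zero-amplitude configuration yields constant trajectories", {
  truth <- generate_true_history(constant_config())
  expect_true(all(truth$pco2_true == 425))
  expect_true(all(truth$d13c_carb_true == 2.2))
  expect_true(all(truth$sst_true == 25))
})

test_that("default history ramps pCO2 across the onset and hits the configured CIE exactly", {
  truth <- generate_true_history()
  cfg <- attr(truth, "config")
  expect_equal(range(truth$pco2_true), c(425, 2500))
  # background everywhere before the onset, peak through the body
  expect_true(all(truth$pco2_true[truth$age_ma >= cfg$onset_age] == 425))
  expect_true(all(truth$pco2_true[truth$stage == "body"] == 2500))
  # carbonate minimum minus background equals the configured CIE
  expect_equal(min(truth$d13c_carb_true) - cfg$d13c_carb_background,
               cfg$cie_carb)
  # SST rise co-timed with pCO2
  expect_equal(max(truth$sst_true) - cfg$sst_background, cfg$sst_rise)
  expect_true(all(truth$pco2_true > 0))
  expect_true(all(diff(truth$age_ma) < 0))
})

test_that("misordered stage boundaries are rejected naming the offender", {
  cfg <- true_history_config(body_age = 252.15)  # older than onset_age
  expect_error(generate_true_history(cfg), "body_age")
  cfg2 <- true_history_config(post_age = 252.11)
  expect_error(generate_true_history(cfg2), "post_age")
})

test_that("optional transient dip stays inside the body stage", {
  truth <- generate_true_history(
    true_history_config(pco2_dip = TRUE, dip_age = 251.972))  # on-grid
  expect_equal(min(truth$pco2_true[truth$stage == "body"]), 1300)
  expect_true(all(truth$pco2_true[truth$stage == "pre_cie"] == 425))
  expect_error(generate_true_history(
    true_history_config(pco2_dip = TRUE, dip_age = 252.2)), "body stage")
})

test_that("forward plant model chains the proxy equations exactly", {
  # constant truth: one hand-checkable value through Eq. chain
  truth <- generate_true_history(constant_config(425, 3.2, 25))
  dp <- forward_model_plant_d13c(truth)
  expect_equal(unique(round(dp, 10)), -26.8675181092, tolerance = 1e-9)
  # zero fractionation is the identity on the atmosphere value
  expect_equal(plant_d13c_forward(-6.5, 0), -6.5)
  # round trip through the fractionation definition
  expect_equal(big_delta(-6.5, plant_d13c_forward(-6.5, 20)), 20)
})

test_that("default truth amplifies a -3.5 permil marine CIE to about -7 permil in plants", {
  truth <- generate_true_history()
  dp <- forward_model_plant_d13c(truth)
  plant_cie <- min(dp) - dp[1]
  expect_equal(plant_cie, -7.0, tolerance = 0.05)
  carb_cie <- min(truth$d13c_carb_true) - truth$d13c_carb_true[1]
  expect_equal(carb_cie, -3.5)
})

test_that("rising pCO2 strictly amplifies the plant CIE relative to constant pCO2", {
  base <- generate_true_history()
  flat_cfg <- true_history_config(pco2_peak = 425, pco2_post = 425)
  flat <- generate_true_history(flat_cfg)
  cie_rise <- with(list(d = forward_model_plant_d13c(base)), min(d) - d[1])
  cie_flat <- with(list(d = forward_model_plant_d13c(flat)), min(d) - d[1])
  expect_lt(cie_rise, cie_flat)  # more negative with rising pCO2
})

test_that("section sampling is noise-faithful, deterministic and bookkept", {
  truth <- generate_true_history()
  truth$d13c_p_true <- forward_model_plant_d13c(truth)
  plan0 <- small_plan(noise_sd_plant = 0, noise_sd_carb = 0,
                      noise_sd_sst = 0)
  s0 <- sample_sections(truth, truth$d13c_p_true, plan0)
  # zero noise: samples lie exactly on the interpolated true curves
  carb <- s0[s0$substrate == "carbonate", ]
  o <- order(truth$age_ma)
  expect_equal(carb$value,
               approx(truth$age_ma[o], truth$d13c_carb_true[o],
                      xout = carb$age_ma)$y)
  # fixed seed: byte-identical tables
  plan <- sampling_plan(seed = 11L)
  a <- sample_sections(truth, truth$d13c_p_true, plan)
  b <- sample_sections(truth, truth$d13c_p_true, plan)
  expect_identical(a, b)
  # 4 plant sections x 40 samples
  expect_identical(sum(a$substrate == "plant"), 160L)
  expect_error(sampling_plan(samples_per_section = 1), "at least 2")
  expect_error(sampling_plan(noise_sd_carb = -1), "noise_sd_carb")
})

test_that("ages stay within the grid span and all sections are emitted", {
  ds <- synthetic_dataset(plan = small_plan())
  expect_true(all(ds$samples$age_ma <= max(ds$truth$age_ma)))
  expect_true(all(ds$samples$age_ma >= min(ds$truth$age_ma)))
  expect_setequal(unique(ds$samples$substrate),
                  c("plant", "carbonate", "sst"))
  expect_identical(length(unique(ds$samples$section_id)), 7L)
})
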