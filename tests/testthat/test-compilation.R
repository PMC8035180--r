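test_that("stage assignment is monotone in age with the stated tie-break", {
  ser <- data.frame(age_ma = c(252.15, 252.10, 252.05, 252.025, 251.95,
                               251.90))
  b <- c(252.10, 252.025, 251.92)
  lab <- assign_stages(ser, b)$stage
  expect_identical(as.character(lab),
                   c("pre_cie", "pre_cie",  # exactly on b1 -> older stage
                     "onset", "onset",      # exactly on b2 -> older stage
                     "body", "post_cie"))
  # all boundaries older than every sample: everything post-CIE
  young <- data.frame(age_ma = c(251.5, 251.4))
  expect_true(all(assign_stages(young, b)$stage == "post_cie"))
  expect_error(assign_stages(ser, c(252.0, 252.1, 251.9)), "decreasing")
})

test_that("generator stage labels agree with assign_stages at the true boundaries", {
  truth <- generate_true_history()
  cfg <- attr(truth, "config")
  relab <- assign_stages(data.frame(age_ma = truth$age_ma),
                         c(cfg$onset_age, cfg$body_age, cfg$post_age))
  expect_identical(as.character(relab$stage), as.character(truth$stage))
})

test_that("CIE magnitude is peak minus background with documented conventions", {
  ser <- data.frame(
    age_ma = seq(252.2, 251.9, by = -0.02),
    value = c(rep(-25, 8), -28, -32, -31, -30, -30, -29, -28, -27))
  ser <- assign_stages(ser, c(252.05, 252.0, 251.93))
  m <- cie_magnitude(ser)
  expect_equal(m$d13c_background, -25)
  expect_equal(m$d13c_peak, -32)
  expect_equal(m$magnitude, -7)
  # flat series: zero magnitude
  flat <- data.frame(age_ma = ser$age_ma, value = -25)
  flat <- assign_stages(flat, c(252.05, 252.0, 251.93))
  expect_equal(cie_magnitude(flat)$magnitude, 0)
  # missing stages are named
  pre_only <- ser[ser$stage == "pre_cie", ]
  expect_error(cie_magnitude(pre_only), "onset")
  exc_only <- ser[ser$stage != "pre_cie", ]
  expect_error(cie_magnitude(exc_only), "pre_cie")
})

test_that("CIE magnitude is translation-equivariant", {
  set.seed(3)
  for (i in 1:10) {
    ser <- data.frame(age_ma = seq(252.2, 251.9, by = -0.01),
                      value = rnorm(31, -27, 2))
    ser <- assign_stages(ser, c(252.1, 252.02, 251.95))
    c0 <- cie_magnitude(ser)$magnitude
    ser$value <- ser$value + runif(1, -10, 10)
    expect_equal(cie_magnitude(ser)$magnitude, c0)
  }
})

test_that("noise-free synthetic carbonate sections recover the configured CIE", {
  truth <- generate_true_history()
  cfg <- attr(truth, "config")
  truth$d13c_p_true <- forward_model_plant_d13c(truth)
  plan0 <- small_plan(noise_sd_plant = 0, noise_sd_carb = 0,
                      noise_sd_sst = 0)
  s <- sample_sections(truth, truth$d13c_p_true, plan0)
  mags <- compile_cie_magnitudes(s[s$substrate == "carbonate", ],
                                 c(cfg$onset_age, cfg$body_age,
                                   cfg$post_age))
  expect_equal(mags$magnitude, rep(-3.5, nrow(mags)), tolerance = 1e-6)
})

test_that("rank-sum p-values match independent oracles on small groups", {
  # identical groups: exact p = 1
  g <- list(carbonate = c(-3.0, -3.5, -4.7), plant = c(-3.0, -3.5, -4.7))
  cmp <- compare_substrate_magnitudes(g)
  expect_equal(cmp$ranksum$p, 1)
  # separated groups: all 20 label assignments -> p = 2/20
  g2 <- list(carbonate = c(-3.0, -3.5, -4.7), plant = c(-5.2, -6.5, -7.1))
  cmp2 <- compare_substrate_magnitudes(g2)
  expect_equal(cmp2$ranksum$p, 0.1)
  # ... which is what the exact rank-sum distribution gives (tie-free)
  expect_equal(cmp2$ranksum$p,
               wilcox.test(g2$carbonate, g2$plant, exact = TRUE)$p.value)
  # random tie-free groups, total n <= 10: agree with stats::wilcox.test
  set.seed(7)
  for (i in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- round(rnorm(n1), 3); y <- round(rnorm(n2, 1), 3)
    if (anyDuplicated(c(x, y))) next
    got <- compare_substrate_magnitudes(
      list(carbonate = x, plant = y))$ranksum$p
    expect_equal(got, wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("substrate comparison handles degenerate groups and reports quartiles", {
  g <- list(carbonate = c(-3, -4, -3.5), plant = c(-6, -7, -7.5),
            bulk_om = -5)  # n = 1: not testable
  cmp <- compare_substrate_magnitudes(g)
  expect_true("bulk_om" %in% cmp$not_testable)
  expect_identical(rownames(cmp$quartiles), c("carbonate", "plant"))
  expect_equal(unname(cmp$quartiles["carbonate", ]),
               unname(quantile(g$carbonate, c(.25, .5, .75), type = 7)))
  expect_error(compare_substrate_magnitudes(list(a = 1, b = 2)),
               "at least 2 groups")
})

test_that("marine and plant CIE magnitudes separate at study-like effect sizes", {
  set.seed(101)
  mags <- data.frame(
    substrate = rep(c("carbonate", "plant"), each = 30),
    magnitude = c(rnorm(30, -3.5, 0.5), rnorm(30, -7, 0.7)))
  cmp <- compare_substrate_magnitudes(mags)
  expect_lt(cmp$kruskal$p, 0.001)
  expect_lt(cmp$ranksum$p, 0.001)
  expect_identical(cmp$ranksum$method, "normal approximation")
})
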