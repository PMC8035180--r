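test_that("local linear fitting reproduces a straight line exactly", {
  x <- seq(252.2, 252.0, by = -0.004)
  s <- data.frame(age_ma = x, value = 2 + 3 * (252.2 - x))
  for (sp in c(0.2, 0.5, 1.0)) {
    st <- fit_stack(s, span = sp)
    truth <- 2 + 3 * (252.2 - st$age_ma)
    expect_lt(max(abs(st$center - truth), na.rm = TRUE), 1e-9)
    expect_lt(max(st$se, na.rm = TRUE), 1e-9)
  }
})

test_that("span 1 on linear truth matches the ordinary least-squares line", {
  set.seed(5)
  x <- sort(runif(60, 252.0, 252.2), decreasing = TRUE)
  s <- data.frame(age_ma = x, value = -25 + 4 * (252.2 - x))
  st <- fit_stack(s, span = 1)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% s$value)  # normal equations oracle
  ok <- is.finite(st$center)
  expect_lt(max(abs(st$center[ok] - (beta[1] + beta[2] * st$age_ma[ok]))),
            1e-8)
})

test_that("standard error shrinks with local sample count on constant truth", {
  mean_se <- function(n, seeds = 1:50) {
    mean(vapply(seeds, function(sd) {
      set.seed(sd)
      s <- data.frame(age_ma = runif(n, 252.0, 252.2),
                      value = rnorm(n, 5, 0.4))
      st <- fit_stack(s, grid = seq(252.18, 252.02, by = -0.02), span = 0.8)
      mean(st$se, na.rm = TRUE)
    }, numeric(1)))
  }
  se_small <- mean_se(30); se_big <- mean_se(120)
  expect_lt(se_big, se_small)
  # and the centre estimates the constant
  set.seed(9)
  s <- data.frame(age_ma = runif(200, 252.0, 252.2),
                  value = rnorm(200, 5, 0.4))
  st <- fit_stack(s, span = 0.8)
  expect_lt(max(abs(st$center - 5), na.rm = TRUE), 0.2)
})

test_that("stacked synthetic carbonate tracks the true curve", {
  ds <- synthetic_dataset(plan = sampling_plan(seed = 21L))
  carb <- ds$samples[ds$samples$substrate == "carbonate", ]
  st <- fit_stack(carb, grid = ds$truth$age_ma)
  ok <- is.finite(st$center)
  frac_close <- mean(abs(st$center[ok] - ds$truth$d13c_carb_true[ok])
                     <= 0.3)
  expect_gte(frac_close, 0.95)
  # grid points beyond the data span are missing, never extrapolated
  expect_true(all(!is.finite(st$center[!ok])))
  expect_true(all(st$n_local[!ok] == 0))
})

test_that("stacking is invariant to sample order and section relabelling", {
  ds <- synthetic_dataset(plan = small_plan(seed = 4L))
  carb <- ds$samples[ds$samples$substrate == "carbonate", ]
  st1 <- fit_stack(carb, grid = ds$truth$age_ma, span = 0.3)
  set.seed(1)
  shuf <- carb[sample(nrow(carb)), ]
  shuf$section_id <- paste0("renamed_", shuf$section_id)
  st2 <- fit_stack(shuf, grid = ds$truth$age_ma, span = 0.3)
  expect_equal(st1$center, st2$center)
  expect_equal(st1$se, st2$se)
})

test_that("cross-validated span selection returns a finite table and a usable span", {
  ds <- synthetic_dataset(plan = small_plan(seed = 2L))
  carb <- ds$samples[ds$samples$substrate == "carbonate", ]
  tab <- select_span_cv(carb)
  expect_identical(names(tab), c("span", "cv_mse"))
  expect_true(any(is.finite(tab$cv_mse)))
  st <- fit_stack(carb, grid = ds$truth$age_ma)
  expect_true(attr(st, "span") %in% tab$span)
  expect_error(fit_stack(carb[1:5, ]), "at least 10")
})

test_that("robustness refits reduce to the full fit in the degenerate settings", {
  ds <- synthetic_dataset(plan = small_plan(seed = 8L))
  carb <- ds$samples[ds$samples$substrate == "carbonate", ]
  full <- fit_stack(carb, grid = ds$truth$age_ma, span = 0.3)
  # fraction 1.0, one rep: identical to the full fit
  rf <- robustness_refits(carb, ds$truth$age_ma, "subsample80",
                          n_reps = 1, fraction = 1.0, span = 0.3)
  expect_equal(rf$curves[[1]]$center, full$center)
  # two identical duplicated sections: leave-one-out refits are identical
  dup <- carb[carb$section_id == "carb_01", ]
  dup2 <- dup; dup2$section_id <- "carb_99"
  rf2 <- robustness_refits(rbind(dup, dup2), ds$truth$age_ma,
                           "leave_section_out", span = 0.3)
  expect_equal(rf2$curves[[1]]$center, rf2$curves[[2]]$center)
})

test_that("refit dispersion stays within the full-fit standard error band", {
  ds <- synthetic_dataset()  # default 10 carbonate sections
  carb <- ds$samples[ds$samples$substrate == "carbonate", ]
  full <- fit_stack(carb, grid = ds$truth$age_ma, span = 0.3)
  rf <- robustness_refits(carb, ds$truth$age_ma, "subsample80",
                          n_reps = 10, seed = 5L, span = 0.3)
  for (cv in rf$curves) {
    ok <- is.finite(full$center) & is.finite(cv$center) & full$se > 0
    frac <- mean(abs(cv$center[ok] - full$center[ok]) < 3 * full$se[ok])
    expect_gte(frac, 0.9)
  }
  # leave-section-out: one refit per section
  rf2 <- robustness_refits(carb, ds$truth$age_ma, "leave_section_out",
                           span = 0.3)
  expect_identical(length(rf2$curves), 10L)
})
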