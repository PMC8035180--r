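#' Configuration of the true synthetic history
#'
#' Defines the piecewise-linear "true" trajectories of pCO2, marine
#' carbonate d13C and sea surface temperature across a four-stage carbon
#' isotope excursion (pre-CIE plateau, onset ramp, CIE body, recovery).
#' Defaults mirror a Permian-Triassic-style event: pCO2 ramps from a 425 ppmv
#' background to a 2500 ppmv peak over a 75 kyr onset, carbonate d13C drops
#' 3.5 permil from a +2.2 permil background, and SST rises 10 degrees C from
#' 25 degrees C, co-timed with pCO2.
#'
#' Stage boundaries are ages in Ma (decreasing toward younger): the onset
#' ramp runs from `onset_age` to `body_age`, the body from `body_age` to
#' `post_age`, and recovery takes `recovery_duration` Myr after `post_age`.
#' An optional transient pCO2 dip inside the body stage (down to
#' `pco2_dip_level`) is off by default.
#'
#' @param age_start,age_end Grid span, Ma (old to young).
#' @param step Grid step, Myr.
#' @param onset_age,body_age,post_age Stage boundary ages, Ma, strictly
#'   decreasing and inside `(age_end, age_start)`.
#' @param recovery_duration Length of the post-CIE recovery ramp, Myr.
#' @param pco2_background,pco2_peak,pco2_post pCO2 levels, ppmv, positive.
#' @param pco2_dip Logical; carve a transient dip into the body stage?
#' @param pco2_dip_level,dip_age,dip_width Dip minimum (ppmv), centre age
#'   (Ma; default mid-body) and full width (Myr).
#' @param d13c_carb_background Carbonate background, permil VPDB.
#' @param cie_carb Carbonate CIE magnitude, permil (negative for a negative
#'   excursion); the body level is exactly `d13c_carb_background + cie_carb`.
#' @param d13c_carb_post Post-recovery carbonate level, permil VPDB.
#' @param sst_background,sst_rise,sst_post SST background (deg C), rise
#'   co-timed with the pCO2 ramp, and post-recovery level.
#' @return A list of class `"true_history_config"`.
#' @export
true_history_config <- function(age_start = 252.2, age_end = 251.85,
                                step = 0.002,
                                onset_age = 252.1, body_age = 252.025,
                                post_age = 251.92, recovery_duration = 0.03,
                                pco2_background = 425, pco2_peak = 2500,
                                pco2_post = 700,
                                pco2_dip = FALSE, pco2_dip_level = 1300,
                                dip_age = NULL, dip_width = 0.02,
                                d13c_carb_background = 2.2, cie_carb = -3.5,
                                d13c_carb_post = 0.8,
                                sst_background = 25, sst_rise = 10,
                                sst_post = 29) {
  cfg <- list(age_start = age_start, age_end = age_end, step = step,
              onset_age = onset_age, body_age = body_age, post_age = post_age,
              recovery_duration = recovery_duration,
              pco2_background = pco2_background, pco2_peak = pco2_peak,
              pco2_post = pco2_post, pco2_dip = isTRUE(pco2_dip),
              pco2_dip_level = pco2_dip_level, dip_age = dip_age,
              dip_width = dip_width,
              d13c_carb_background = d13c_carb_background,
              cie_carb = cie_carb, d13c_carb_post = d13c_carb_post,
              sst_background = sst_background, sst_rise = sst_rise,
              sst_post = sst_post)
  class(cfg) <- "true_history_config"
  cfg
}

.check_history_config <- function(cfg) {
  b <- c(age_start = cfg$age_start, onset_age = cfg$onset_age,
         body_age = cfg$body_age, post_age = cfg$post_age,
         age_end = cfg$age_end)
  if (any(!is.finite(b))) stop("stage boundaries must all be finite")
  d <- diff(b)  # should be strictly negative (ages decrease)
  if (any(d >= 0)) {
    bad <- names(b)[which(d >= 0)[1] + 1L]
    stop("stage boundaries must be strictly decreasing in age; '",
         bad, "' (", b[bad], " Ma) is out of order")
  }
  if (cfg$recovery_duration < 0 ||
      cfg$post_age - cfg$recovery_duration < cfg$age_end)
    stop("'recovery_duration' must be >= 0 and end within the grid span")
  if (cfg$pco2_background <= 0 || cfg$pco2_peak <= 0 || cfg$pco2_post <= 0)
    stop("pCO2 levels must all be positive")
  if (cfg$pco2_dip) {
    dip_age <- if (is.null(cfg$dip_age))
      (cfg$body_age + cfg$post_age) / 2 else cfg$dip_age
    if (dip_age + cfg$dip_width / 2 > cfg$body_age ||
        dip_age - cfg$dip_width / 2 < cfg$post_age)
      stop("pCO2 dip must lie entirely within the CIE body stage")
    if (cfg$pco2_dip_level <= 0) stop("'pco2_dip_level' must be positive")
  }
  invisible(cfg)
}

# piecewise-linear interpolation through (age, value) keyframes;
# ages descend, approx() wants ascending x
.piecewise <- function(key_age, key_val, grid) {
  o <- order(key_age)
  stats::approx(key_age[o], key_val[o], xout = grid, rule = 2,
                ties = "ordered")$y
}

.stage_labels <- function(age, b1, b2, b3) {
  # sample exactly on a boundary goes to the older (larger-age) stage
  factor(ifelse(age >= b1, "pre_cie",
         ifelse(age >= b2, "onset",
         ifelse(age >= b3, "body", "post_cie"))),
         levels = c("pre_cie", "onset", "body", "post_cie"))
}

#' Generate the true synthetic history
#'
#' Evaluates the configured piecewise-linear trajectories on the regular age
#' grid. The carbonate minimum equals `d13c_carb_background + cie_carb`
#' exactly, and the pCO2 ramp covers background to peak across the onset
#' stage.
#'
#' @param config A [true_history_config()].
#' @return A data frame of class `"true_history"` with columns `age_ma`,
#'   `pco2_true`, `d13c_carb_true`, `sst_true`, `stage`; the configuration is
#'   attached as attribute `"config"`.
#' @examples
#' truth <- generate_true_history()
#' range(truth$pco2_true)  # 425 to 2500 ppmv
#' @export
generate_true_history <- function(config = true_history_config()) {
  cfg <- .check_history_config(config)
  grid <- make_age_grid(cfg$age_start, cfg$age_end, cfg$step)
  rec_end <- cfg$post_age - cfg$recovery_duration

  key_p_age <- c(cfg$age_start, cfg$onset_age, cfg$body_age, cfg$post_age,
                 rec_end, cfg$age_end - cfg$step)
  key_p_val <- c(cfg$pco2_background, cfg$pco2_background, cfg$pco2_peak,
                 cfg$pco2_peak, cfg$pco2_post, cfg$pco2_post)
  if (cfg$pco2_dip) {
    dip_age <- if (is.null(cfg$dip_age))
      (cfg$body_age + cfg$post_age) / 2 else cfg$dip_age
    key_p_age <- c(key_p_age, dip_age + cfg$dip_width / 2, dip_age,
                   dip_age - cfg$dip_width / 2)
    key_p_val <- c(key_p_val, cfg$pco2_peak, cfg$pco2_dip_level,
                   cfg$pco2_peak)
  }
  pco2 <- .piecewise(key_p_age, key_p_val, grid)

  carb_body <- cfg$d13c_carb_background + cfg$cie_carb
  carb <- .piecewise(
    c(cfg$age_start, cfg$onset_age, cfg$body_age, cfg$post_age, rec_end,
      cfg$age_end - cfg$step),
    c(cfg$d13c_carb_background, cfg$d13c_carb_background, carb_body,
      carb_body, cfg$d13c_carb_post, cfg$d13c_carb_post),
    grid)

  sst_peak <- cfg$sst_background + cfg$sst_rise
  sst <- .piecewise(
    c(cfg$age_start, cfg$onset_age, cfg$body_age, cfg$post_age, rec_end,
      cfg$age_end - cfg$step),
    c(cfg$sst_background, cfg$sst_background, sst_peak, sst_peak,
      cfg$sst_post, cfg$sst_post),
    grid)

  out <- data.frame(age_ma = grid, pco2_true = pco2, d13c_carb_true = carb,
                    sst_true = sst,
                    stage = .stage_labels(grid, cfg$onset_age, cfg$body_age,
                                          cfg$post_age))
  stopifnot(all(out$pco2_true > 0))
  attr(out, "config") <- cfg
  class(out) <- c("true_history", "data.frame")
  out
}

#' Forward-model the plant d13C record from a true history
#'
#' Chains the proxy equations forward: DIC from carbonate (constant 1 permil
#' offset), atmospheric CO2 d13C from DIC and SST (temperature-dependent
#' fractionation), fractionation from true pCO2 (hyperbolic model), then the
#' exact algebraic inverse of the fractionation definition to obtain plant
#' d13C. Total on any valid history; feeding the result back through the
#' reconstruction recovers `pco2_true` exactly.
#'
#' @param truth A `"true_history"` data frame.
#' @param params A [proxy_params()] object (only `A`, `B`, `C` are used).
#' @return Numeric vector of plant d13C (permil VPDB), one per gridpoint.
#' @export
forward_model_plant_d13c <- function(truth, params = proxy_params()) {
  stopifnot(all(c("age_ma", "pco2_true", "d13c_carb_true", "sst_true")
                %in% names(truth)))
  co2 <- .co2_from_dic(d13c_dic_from_carb(truth$d13c_carb_true),
                       truth$sst_true)
  frac <- frac_forward(truth$pco2_true, params)
  plant_d13c_forward(co2, frac)
}

#' Sampling plan for synthetic sections
#'
#' How many sections of each substrate to emit, how many samples per section,
#' how uneven the sample ages are, and the per-measurement Gaussian noise.
#' Defaults emulate the study layout: four terrestrial plant sections, ten
#' marine carbonate sections, five SST records, roughly 40 samples each.
#' Noise defaults combine analytical precision (about 0.2 permil) with
#' modest geological scatter.
#'
#' @param n_plant_sections,n_carb_sections,n_sst_sections Section counts.
#' @param samples_per_section Samples per section, `>= 2`.
#' @param age_jitter Half-amplitude of the uniform age jitter, Myr. Samples
#'   are spread one per equal-width age bin and jittered within
#'   `+/- age_jitter`, giving uneven but well-spread coverage.
#' @param noise_sd_plant,noise_sd_carb Measurement noise 1-sigma, permil.
#' @param noise_sd_sst Measurement noise 1-sigma, degrees C.
#' @param seed Integer; fixes the entire generated dataset bit-for-bit.
#' @return A list of class `"sampling_plan"`.
#' @export
sampling_plan <- function(n_plant_sections = 4, n_carb_sections = 10,
                          n_sst_sections = 5, samples_per_section = 40,
                          age_jitter = 0.004,
                          noise_sd_plant = 0.3, noise_sd_carb = 0.25,
                          noise_sd_sst = 1.0, seed = 1L) {
  sds <- c(noise_sd_plant = noise_sd_plant, noise_sd_carb = noise_sd_carb,
           noise_sd_sst = noise_sd_sst)
  bad <- names(sds)[!is.finite(sds) | sds < 0]
  if (length(bad))
    stop("noise standard deviations must be >= 0; offending: ",
         paste(bad, collapse = ", "))
  if (samples_per_section < 2)
    stop("'samples_per_section' must be at least 2")
  if (age_jitter < 0) stop("'age_jitter' must be >= 0")
  structure(list(n_plant_sections = n_plant_sections,
                 n_carb_sections = n_carb_sections,
                 n_sst_sections = n_sst_sections,
                 samples_per_section = samples_per_section,
                 age_jitter = age_jitter,
                 noise_sd_plant = noise_sd_plant,
                 noise_sd_carb = noise_sd_carb,
                 noise_sd_sst = noise_sd_sst,
                 seed = as.integer(seed)),
            class = "sampling_plan")
}

# interpolate a true curve (descending ages) at arbitrary ages
.truth_at <- function(truth, col, ages) {
  o <- order(truth$age_ma)
  stats::approx(truth$age_ma[o], truth[[col]][o], xout = ages, rule = 2)$y
}

.draw_section <- function(truth, col, plan, noise_sd, section_id, substrate) {
  m <- plan$samples_per_section
  old <- max(truth$age_ma); young <- min(truth$age_ma)
  width <- (old - young) / m
  base <- old - (seq_len(m) - 0.5) * width
  ages <- base + stats::runif(m, -1, 1) * plan$age_jitter
  ages <- pmin(pmax(ages, young), old)
  vals <- .truth_at(truth, col, ages) + stats::rnorm(m, 0, noise_sd)
  data.frame(section_id = section_id, substrate = substrate,
             age_ma = ages, value = vals, sd = noise_sd)
}

#' Sample synthetic sections from a true history
#'
#' Draws multi-section records at uneven ages with i.i.d. Gaussian
#' measurement noise per substrate. Deterministic under the plan's seed: two
#' calls with the same inputs return identical tables.
#'
#' @param truth A `"true_history"` data frame.
#' @param d13c_p_true Plant d13C per gridpoint, from
#'   [forward_model_plant_d13c()]. Required if `n_plant_sections > 0`.
#' @param plan A [sampling_plan()].
#' @return Data frame with columns `section_id`, `substrate`
#'   (`"plant"`, `"carbonate"` or `"sst"`), `age_ma`, `value`, `sd`.
#' @export
sample_sections <- function(truth, d13c_p_true = NULL,
                            plan = sampling_plan()) {
  stopifnot(inherits(plan, "sampling_plan"))
  if (plan$n_plant_sections > 0 && is.null(d13c_p_true))
    stop("'d13c_p_true' is required when plant sections are requested")
  set.seed(plan$seed)
  tr <- truth
  if (!is.null(d13c_p_true)) tr$d13c_p_true <- d13c_p_true
  out <- list()
  for (i in seq_len(plan$n_plant_sections))
    out[[length(out) + 1L]] <- .draw_section(
      tr, "d13c_p_true", plan, plan$noise_sd_plant,
      sprintf("plant_%02d", i), "plant")
  for (i in seq_len(plan$n_carb_sections))
    out[[length(out) + 1L]] <- .draw_section(
      tr, "d13c_carb_true", plan, plan$noise_sd_carb,
      sprintf("carb_%02d", i), "carbonate")
  for (i in seq_len(plan$n_sst_sections))
    out[[length(out) + 1L]] <- .draw_section(
      tr, "sst_true", plan, plan$noise_sd_sst,
      sprintf("sst_%02d", i), "sst")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: true history, forward-modelled plant record, and
#' noisy multi-section samples in one object.
#'
#' @param config A [true_history_config()].
#' @param plan A [sampling_plan()].
#' @param params A [proxy_params()] used for the forward model.
#' @return List of class `"synthetic_dataset"`: `truth` (with an added
#'   `d13c_p_true` column), `samples`, `config`, `plan`, `params`.
#' @export
synthetic_dataset <- function(config = true_history_config(),
                              plan = sampling_plan(),
                              params = proxy_params()) {
  truth <- generate_true_history(config)
  truth$d13c_p_true <- forward_model_plant_d13c(truth, params)
  samples <- sample_sections(truth, truth$d13c_p_true, plan)
  structure(list(truth = truth, samples = samples, config = config,
                 plan = plan, params = params),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic isotope dataset\n")
  cat(sprintf("  grid: %d points, %.3f-%.3f Ma (step %g Myr)\n",
              nrow(x$truth), max(x$truth$age_ma), min(x$truth$age_ma),
              x$config$step))
  tab <- table(x$samples$substrate)
  cat("  samples:", paste(sprintf("%s=%d", names(tab), tab),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Stacked curve taken directly from the true history
#'
#' Bypasses LOESS: centres are the true gridpoint values and the standard
#' error is fixed (default 0). This is the closed-form verification path used
#' to check that the reconstruction chain inverts the forward model exactly,
#' isolating inversion error from smoothing error.
#'
#' @param truth A `"true_history"`, with `d13c_p_true` present when
#'   `variable = "d13c_p"`.
#' @param variable One of `"d13c_p"`, `"d13c_carb"`, `"sst"`.
#' @param se Standard error assigned to every gridpoint.
#' @return A `"stacked_curve"` data frame (see [fit_stack()]).
#' @export
stack_from_truth <- function(truth,
                             variable = c("d13c_p", "d13c_carb", "sst"),
                             se = 0) {
  variable <- match.arg(variable)
  col <- switch(variable, d13c_p = "d13c_p_true",
                d13c_carb = "d13c_carb_true", sst = "sst_true")
  if (!col %in% names(truth))
    stop("column '", col, "' not found in truth")
  out <- data.frame(age_ma = truth$age_ma, center = truth[[col]],
                    se = se, n_local = NA_integer_)
  attr(out, "span") <- NA_real_
  class(out) <- c("stacked_curve", "data.frame")
  out
}
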