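#' Default run configuration
#'
#' Nested list of every tunable of the pipeline, with the published
#' constants as defaults: A = 28.26 +/- 0, B = 0.22 +/- 0.028,
#' pCO2(t=0) = 425 +/- 68 ppmv, d13Cp(t=0) = -24.42 +/- 0.5 permil, grid
#' step 0.002 Myr, 10,000 Monte Carlo draws, validity bounds (0, 1e6] ppmv,
#' DIC-carbonate offset 1 permil, 0.3 ppmv per Gt C. The `synthetic` block
#' holds [true_history_config()] and [sampling_plan()] fields; set
#' `inputs$samples_csv` to run on external data instead.
#'
#' @return Nested configuration list.
#' @export
default_run_config <- function() {
  list(
    synthetic = list(enabled = TRUE,
                     history = unclass(true_history_config()),
                     plan = unclass(sampling_plan())),
    inputs = list(samples_csv = NULL, truth_csv = NULL),
    proxy = list(A = 28.26, A_sd = 0, B = 0.22, B_sd = 0.028,
                 pco2_ref = 425, pco2_ref_sd = 68,
                 d13c_p_ref = -24.42, d13c_p_ref_sd = 0.5),
    stacking = list(step = 0.002, span = NULL, cv_folds = 5,
                    from_truth = FALSE),
    mc = list(n_draws = 10000, seed = 1, bounds = c(0, 1e6),
              d13c_p_ref_from_stack = FALSE),
    mass_balance = list(cie_grid = seq(-1, -8, by = -0.5),
                        sources = c(-6, -25, -40, -60),
                        m_background = c(66000, 82000),
                        d13c_background = 2.2),
    output_dir = "c3pco2_out")
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a YAML run configuration
#'
#' Reads `path`, merges it over [default_run_config()] (unset keys keep
#' their defaults) and validates it.
#'
#' @param path YAML file.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  validate_run_config(.merge_config(default_run_config(),
                                    yaml::read_yaml(path)))
}

#' Validate a run configuration
#'
#' Checks the constants and block shapes before any compute; fails with the
#' offending key in the message.
#'
#' @param config Configuration list (see [default_run_config()]).
#' @return `config`, invisibly-valid (returned for chaining).
#' @export
validate_run_config <- function(config) {
  p <- config$proxy
  proxy_params(p$A, p$A_sd, p$B, p$B_sd, p$pco2_ref, p$pco2_ref_sd,
               p$d13c_p_ref, p$d13c_p_ref_sd)  # throws with the bad field
  if (!is.numeric(config$mc$n_draws) || config$mc$n_draws < 100)
    stop("config: mc$n_draws must be at least 100")
  b <- config$mc$bounds
  if (length(b) != 2L || b[1] >= b[2])
    stop("config: mc$bounds must be an increasing pair")
  if (config$stacking$step <= 0) stop("config: stacking$step must be > 0")
  if (!is.null(config$stacking$span) &&
      (config$stacking$span <= 0 || config$stacking$span > 1))
    stop("config: stacking$span must be in (0, 1]")
  if (!isTRUE(config$synthetic$enabled) &&
      is.null(config$inputs$samples_csv))
    stop("config: either synthetic$enabled or inputs$samples_csv required")
  invisible(config)
}

.log_line <- function(out_dir, ...) {
  cat(paste0(..., "\n"), file = file.path(out_dir, "run_log.txt"),
      append = TRUE)
}

#' Run the reconstruction pipeline
#'
#' Chains the stages `simulate` -> `stack` -> `reconstruct` ->
#' `massbalance` -> `metrics`, each reading and writing only the documented
#' CSV dialects under `out_dir`, so any stage can also be re-run on its own
#' against an existing output directory. `all` runs the full chain. Every
#' run echoes the configuration (`config.yaml`) and appends seed, config
#' hash and per-stage record counts to `run_log.txt`. With a fixed seed a
#' rerun is byte-identical.
#'
#' Artifacts: `samples.csv`, `truth.csv` (synthetic runs), `stack_plant.csv`,
#' `stack_carbonate.csv`, `stack_sst.csv`, `reconstruction.csv`,
#' `scenarios.csv`, `metrics.json`.
#'
#' @param config Configuration list (see [default_run_config()]).
#' @param stage One of `"all"`, `"simulate"`, `"stack"`, `"reconstruct"`,
#'   `"massbalance"`, `"metrics"`.
#' @param out_dir Output directory (default `config$output_dir`); created
#'   if absent.
#' @return Invisibly, a named list of artifact paths written.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stage = c("all", "simulate", "stack", "reconstruct",
                                   "massbalance", "metrics"),
                         out_dir = NULL) {
  stage <- match.arg(stage)
  config <- validate_run_config(config)
  if (is.null(out_dir)) out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  if (stage == "all")
    unlink(file.path(out_dir, "run_log.txt"))
  .log_line(out_dir, "stage=", stage,
            " seed=", config$mc$seed,
            " config_md5=", unname(tools::md5sum(cfg_path)))
  stages <- if (stage == "all")
    c("simulate", "stack", "reconstruct", "massbalance", "metrics")
  else stage
  if (!isTRUE(config$synthetic$enabled))
    stages <- setdiff(stages, "simulate")
  arts <- list()
  for (st in stages)
    arts <- c(arts, switch(st,
      simulate = .stage_simulate(config, out_dir),
      stack = .stage_stack(config, out_dir),
      reconstruct = .stage_reconstruct(config, out_dir),
      massbalance = .stage_massbalance(config, out_dir),
      metrics = .stage_metrics(config, out_dir)))
  invisible(arts)
}

.stage_simulate <- function(config, out_dir) {
  hist_cfg <- do.call(true_history_config, config$synthetic$history)
  plan <- do.call(sampling_plan, config$synthetic$plan)
  p <- config$proxy
  params <- proxy_params(p$A, p$A_sd, p$B, p$B_sd, p$pco2_ref,
                         p$pco2_ref_sd, p$d13c_p_ref, p$d13c_p_ref_sd)
  ds <- synthetic_dataset(hist_cfg, plan, params)
  samples_path <- file.path(out_dir, "samples.csv")
  truth_path <- file.path(out_dir, "truth.csv")
  write_series_csv(ds$samples, samples_path)
  write_truth_csv(ds$truth, truth_path)
  .log_line(out_dir, "simulate: samples=", nrow(ds$samples),
            " gridpoints=", nrow(ds$truth))
  list(samples = samples_path, truth = truth_path)
}

.samples_path <- function(config, out_dir) {
  if (!is.null(config$inputs$samples_csv)) config$inputs$samples_csv
  else file.path(out_dir, "samples.csv")
}

.truth_path <- function(config, out_dir) {
  if (!is.null(config$inputs$truth_csv)) config$inputs$truth_csv
  else file.path(out_dir, "truth.csv")
}

.stage_stack <- function(config, out_dir) {
  samples <- read_series_csv(.samples_path(config, out_dir))
  tp <- .truth_path(config, out_dir)
  truth <- if (file.exists(tp)) read_truth_csv(tp) else NULL
  grid <- if (!is.null(truth)) truth$age_ma
  else make_age_grid(max(samples$age_ma), min(samples$age_ma),
                     config$stacking$step)
  arts <- list()
  for (sub in c("plant", "carbonate", "sst")) {
    if (isTRUE(config$stacking$from_truth)) {
      if (is.null(truth)) stop("stacking$from_truth requires a truth CSV")
      stk <- stack_from_truth(truth, switch(sub, plant = "d13c_p",
                                            carbonate = "d13c_carb", "sst"))
    } else {
      sm <- samples[samples$substrate == sub, , drop = FALSE]
      if (nrow(sm) == 0L) next
      stk <- fit_stack(sm, grid, span = config$stacking$span,
                       cv_folds = config$stacking$cv_folds)
    }
    path <- file.path(out_dir, paste0("stack_", sub, ".csv"))
    write_stack_csv(stk, path)
    .log_line(out_dir, "stack ", sub, ": span=",
              format(attr(stk, "span")), " gridpoints=", nrow(stk))
    arts[[paste0("stack_", sub)]] <- path
  }
  arts
}

.stage_reconstruct <- function(config, out_dir) {
  plant <- read_stack_csv(file.path(out_dir, "stack_plant.csv"))
  carb <- read_stack_csv(file.path(out_dir, "stack_carbonate.csv"))
  sst <- read_stack_csv(file.path(out_dir, "stack_sst.csv"))
  p <- config$proxy
  ref_val <- p$d13c_p_ref
  if (isTRUE(config$mc$d13c_p_ref_from_stack)) {
    ok <- is.finite(plant$center)
    ref_val <- plant$center[ok][which.max(plant$age_ma[ok])]
  }
  params <- proxy_params(p$A, p$A_sd, p$B, p$B_sd, p$pco2_ref,
                         p$pco2_ref_sd, ref_val, p$d13c_p_ref_sd)
  rec <- mc_reconstruct(plant, carb, sst, params,
                        n_draws = config$mc$n_draws,
                        seed = config$mc$seed,
                        bounds = config$mc$bounds)
  path <- file.path(out_dir, "reconstruction.csv")
  write_recon_csv(rec, path)
  .log_line(out_dir, "reconstruct: draws=", config$mc$n_draws,
            " valid_gridpoints=", sum(is.finite(rec$median)))
  list(reconstruction = path)
}

# proxy rise and its asymmetric errors from a written reconstruction:
# background = oldest valid gridstep, peak = maximum median
.proxy_rise <- function(rec) {
  ok <- is.finite(rec$median)
  bg_i <- which(ok)[which.max(rec$age_ma[ok])]
  pk_i <- which.max(rec$median)
  list(bg = rec$median[bg_i], peak = rec$median[pk_i],
       rise = rec$median[pk_i] - rec$median[bg_i],
       pos_err = rec$p84[pk_i] - rec$median[pk_i],
       neg_err = rec$median[pk_i] - rec$p16[pk_i],
       peak_age = rec$age_ma[pk_i], bg_age = rec$age_ma[bg_i])
}

.stage_massbalance <- function(config, out_dir) {
  mb <- config$mass_balance
  tab <- scenario_table(mb$cie_grid, mb$sources, mb$m_background,
                        mb$d13c_background)
  rec_path <- file.path(out_dir, "reconstruction.csv")
  if (file.exists(rec_path)) {
    pr <- .proxy_rise(read_recon_csv(rec_path))
    tab <- compare_with_proxy(tab, pr$rise, pr$pos_err, pr$neg_err)
  }
  path <- file.path(out_dir, "scenarios.csv")
  .write_csv_full(as.data.frame(tab), path)
  .log_line(out_dir, "massbalance: scenarios=", nrow(tab))
  list(scenarios = path)
}

.stage_metrics <- function(config, out_dir) {
  rec <- read_recon_csv(file.path(out_dir, "reconstruction.csv"))
  sst <- read_stack_csv(file.path(out_dir, "stack_sst.csv"))
  pr <- .proxy_rise(rec)
  ok <- is.finite(sst$center)
  sst_bg <- sst$center[ok][which.max(sst$age_ma[ok])]
  delta_t <- max(sst$center, na.rm = TRUE) - sst_bg
  ess <- earth_system_sensitivity(delta_t, pr$peak, pr$bg)
  corr <- pco2_sst_correlation(rec, sst)
  metrics <- list(pco2_background_ppmv = pr$bg, pco2_peak_ppmv = pr$peak,
                  pco2_rise_ppmv = pr$rise, pos_err_ppmv = pr$pos_err,
                  neg_err_ppmv = pr$neg_err, delta_t_c = delta_t,
                  ess_c_per_doubling = ess,
                  r_pco2_sst = corr$r, p_pco2_sst = corr$p,
                  n_pairs = corr$n)
  path <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA)
  .log_line(out_dir, "metrics: ess=", format(ess), " r=", format(corr$r))
  list(metrics = path)
}
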