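#' Mass of carbon added, from isotope mass balance
#'
#' Single-box carbon isotope mass balance for an instantaneous addition:
#' \deqn{M_{added} = \frac{-CIE \times M_{background}}
#'   {\delta^{13}C_{peak} - \delta^{13}C_{added}}}
#' with the post-event reservoir composition
#' `d13c_peak = d13c_background + cie`. The source must be isotopically
#' lighter than the post-event reservoir, otherwise it cannot produce a
#' negative excursion.
#'
#' @param cie Global CIE magnitude, permil (negative).
#' @param m_background Initial ocean-atmosphere carbon reservoir, Gt C.
#' @param d13c_background Initial reservoir d13C, permil VPDB.
#' @param d13c_added Source d13C, permil VPDB; must be less than
#'   `d13c_background + cie`.
#' @return Mass of added carbon, Gt C (positive). Vectorised.
#' @examples
#' mass_added(-3.5, 66000, 2.2, -60)  # ~3935 Gt C
#' @export
mass_added <- function(cie, m_background, d13c_background, d13c_added) {
  if (any(!is.finite(cie)) || any(cie >= 0))
    stop("'cie' must be negative (a negative excursion)")
  if (any(m_background <= 0)) stop("'m_background' must be positive")
  peak <- d13c_background + cie
  if (any(d13c_added >= peak))
    stop("source cannot produce a negative CIE: 'd13c_added' must be ",
         "lighter than d13c_background + cie")
  (-cie * m_background) / (peak - d13c_added)
}

#' Convert added carbon to a pCO2 rise
#'
#' Fixed conversion 1 Gt C = 0.3 ppmv CO2.
#'
#' @param m_added Mass of added carbon, Gt C, `>= 0`.
#' @return pCO2 rise, ppmv.
#' @export
ppmv_rise <- function(m_added) {
  if (any(is.finite(m_added) & m_added < 0))
    stop("'m_added' must be >= 0")
  0.3 * m_added
}

#' Cross-product table of mass-balance scenarios
#'
#' Evaluates the mass balance over a grid of CIE magnitudes, candidate
#' source compositions and background reservoir sizes. Default sources are
#' volcanic CO2 (-6 permil), organic matter (-25), thermogenic methane
#' (-40) and biogenic methane hydrate (-60); default reservoirs 66,000 and
#' 82,000 Gt C; default CIE grid -1 to -8 permil. Rows whose source is not
#' lighter than the post-event reservoir are marked infeasible (`NA` mass)
#' rather than dropped.
#'
#' @param cie_grid CIE magnitudes, permil (negative).
#' @param sources Source d13C values, permil VPDB.
#' @param m_background Reservoir sizes, Gt C.
#' @param d13c_background Initial reservoir d13C, permil VPDB.
#' @return Data frame of class `"mass_balance_table"`: `cie_permil`,
#'   `source_permil`, `m_background_gt`, `feasible`, `m_added_gt`,
#'   `ppmv_rise`.
#' @export
scenario_table <- function(cie_grid = seq(-1, -8, by = -0.5),
                           sources = c(-6, -25, -40, -60),
                           m_background = c(66000, 82000),
                           d13c_background = 2.2) {
  if (!length(cie_grid) || !length(sources) || !length(m_background))
    stop("grids must be non-empty")
  tab <- expand.grid(cie_permil = cie_grid, source_permil = sources,
                     m_background_gt = m_background,
                     KEEP.OUT.ATTRS = FALSE)
  peak <- d13c_background + tab$cie_permil
  tab$feasible <- tab$source_permil < peak
  tab$m_added_gt <- NA_real_
  f <- tab$feasible
  tab$m_added_gt[f] <- mass_added(tab$cie_permil[f], tab$m_background_gt[f],
                                  d13c_background, tab$source_permil[f])
  tab$ppmv_rise <- ppmv_rise(tab$m_added_gt)
  attr(tab, "d13c_background") <- d13c_background
  class(tab) <- c("mass_balance_table", "data.frame")
  tab
}

#' Compare mass-balance scenarios with the proxy band
#'
#' Classifies each scenario's implied pCO2 rise against the reconstruction's
#' asymmetric 68% interval `[mid - neg_err, mid + pos_err]`.
#'
#' @param table A [scenario_table()] result.
#' @param mid Median proxy pCO2 rise, ppmv.
#' @param pos_err,neg_err Positive and negative errors of the rise, ppmv
#'   (both `>= 0`).
#' @return `table` with an added `band_flag` column
#'   (`"below"`/`"within"`/`"above"`, `NA` for infeasible rows).
#' @export
compare_with_proxy <- function(table, mid, pos_err, neg_err) {
  if (!is.finite(mid) || pos_err < 0 || neg_err < 0)
    stop("band must satisfy low <= mid <= high")
  lo <- mid - neg_err; hi <- mid + pos_err
  table$band_flag <- ifelse(!is.finite(table$ppmv_rise), NA_character_,
                     ifelse(table$ppmv_rise < lo, "below",
                     ifelse(table$ppmv_rise > hi, "above", "within")))
  table
}

#' Earth system sensitivity
#'
#' Warming per CO2 doubling including slow feedbacks:
#' `ess = delta_t / log2(pco2_peak / pco2_background)`.
#'
#' @param delta_t Temperature change, degrees C.
#' @param pco2_peak,pco2_background pCO2 endpoints, ppmv, both positive and
#'   distinct.
#' @return ESS in degrees C per doubling.
#' @examples
#' earth_system_sensitivity(10, 2507, 426)  # ~3.9
#' @export
earth_system_sensitivity <- function(delta_t, pco2_peak, pco2_background) {
  if (any(pco2_peak <= 0) || any(pco2_background <= 0))
    stop("pCO2 values must be positive")
  r <- pco2_peak / pco2_background
  if (any(r == 1)) stop("peak and background pCO2 must differ")
  delta_t / log2(r)
}

#' Correlation between reconstructed pCO2 and SST
#'
#' Pearson correlation (two-sided test) between the per-gridstep median
#' pCO2 and the SST stack centre, over gridsteps where both are finite.
#'
#' @param recon A `"pco2_reconstruction"`.
#' @param sst_stack A `"stacked_curve"` of SST on the same age grid.
#' @return List: `r`, `p`, `n`. If either input is constant the correlation
#'   is not computable and `r`/`p` are `NA` with `note` set.
#' @export
pco2_sst_correlation <- function(recon, sst_stack) {
  if (!isTRUE(all.equal(recon$age_ma, sst_stack$age_ma)))
    stop("reconstruction and SST stack must share the same age grid")
  ok <- is.finite(recon$median) & is.finite(sst_stack$center)
  x <- recon$median[ok]; y <- sst_stack$center[ok]
  if (length(x) < 3L)
    stop("need at least 3 complete pairs; got ", length(x))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x),
                note = "constant input; correlation not computable"))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
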