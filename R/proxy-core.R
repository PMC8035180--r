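#' Photosynthetic fractionation as a function of pCO2
#'
#' The hyperbolic response of C3-plant carbon isotope fractionation to
#' atmospheric CO2:
#' \deqn{\Delta^{13}C = \frac{A B (pCO2 + C)}{A + B (pCO2 + C)}}
#' Strictly increasing and concave in pCO2, equal to 4.4 permil at
#' pCO2 = 0 (by construction of `C`) and bounded above by `A`.
#'
#' @param pco2 Atmospheric CO2, ppmv; vector, all values `>= 0`.
#' @param params A [proxy_params()] object.
#' @return Fractionation in permil, same length as `pco2`.
#' @examples
#' frac_forward(425)   # 21.97 permil
#' frac_forward(0)     # 4.4 permil exactly
#' @export
frac_forward <- function(pco2, params = proxy_params()) {
  if (any(!is.finite(pco2)) || any(pco2 < 0))
    stop("'pco2' must be finite and >= 0 ppmv")
  A <- params$A; B <- params$B; C <- params$C
  A * B * (pco2 + C) / (A + B * (pco2 + C))
}

#' Fractionation between atmospheric CO2 and plant tissue
#'
#' \deqn{\Delta^{13}C = (\delta^{13}C_{CO2} - \delta^{13}C_p) /
#'   (1 + \delta^{13}C_p / 1000)}
#'
#' @param d13c_co2 d13C of atmospheric CO2, permil VPDB.
#' @param d13c_p d13C of plant tissue, permil VPDB; must exceed -1000.
#' @return Fractionation in permil; zero iff the two inputs are equal.
#' @examples
#' big_delta(-6.5, -24.42)  # 18.369 permil
#' @export
big_delta <- function(d13c_co2, d13c_p) {
  if (any(!is.finite(d13c_p)) || any(d13c_p <= -1000))
    stop("'d13c_p' must be finite and exceed -1000 permil")
  (d13c_co2 - d13c_p) / (1 + d13c_p / 1000)
}

#' Plant d13C implied by an atmosphere and a fractionation
#'
#' Exact algebraic inverse of [big_delta()] for the plant value:
#' `d13c_p = (d13c_co2 - frac) / (1 + frac / 1000)`. Used by the synthetic
#' generator to forward-model plant records from a known pCO2 history.
#'
#' @param d13c_co2 d13C of atmospheric CO2, permil VPDB.
#' @param frac Fractionation in permil.
#' @return Plant d13C, permil VPDB.
#' @examples
#' plant_d13c_forward(-6.5, 0)  # identity when fractionation is zero
#' @export
plant_d13c_forward <- function(d13c_co2, frac) {
  (d13c_co2 - frac) / (1 + frac / 1000)
}

#' Marine carbonate to dissolved inorganic carbon
#'
#' The carbonate-DIC fractionation is taken as a constant, temperature
#' independent 1 permil: `d13c_dic = d13c_carb - 1`.
#'
#' @param d13c_carb Marine carbonate d13C, permil VPDB.
#' @return DIC d13C, permil VPDB.
#' @export
d13c_dic_from_carb <- function(d13c_carb) {
  d13c_carb - 1.0
}

#' Atmospheric CO2 d13C from DIC and sea surface temperature
#'
#' Temperature-dependent fractionation between DIC and atmospheric CO2:
#' \deqn{\delta^{13}C_{CO2} = \delta^{13}C_{DIC} -
#'   (0.91 (-0.1141 T + 10.78) + 0.08 (-0.052 T + 7.22))}
#' The offset is 10.3874 permil at 0 degrees C and shrinks by
#' 0.107991 permil per degree.
#'
#' @param d13c_dic DIC d13C, permil VPDB.
#' @param sst Sea surface temperature, degrees C.
#' @param sst_bounds Sanity range; values outside trigger a warning but the
#'   result is still returned (the bounds are sanity, not physics).
#' @return Atmospheric CO2 d13C, permil VPDB.
#' @examples
#' d13c_co2_from_dic(1.2, 25)  # -6.488 permil
#' @export
d13c_co2_from_dic <- function(d13c_dic, sst, sst_bounds = c(-5, 60)) {
  if (any(is.finite(sst) & (sst < sst_bounds[1] | sst > sst_bounds[2])))
    warning("SST outside sanity bounds [", sst_bounds[1], ", ",
            sst_bounds[2], "] degrees C; value computed anyway")
  .co2_from_dic(d13c_dic, sst)
}

# unchecked kernel shared with the Monte Carlo layer
.co2_from_dic <- function(d13c_dic, sst) {
  d13c_dic - (0.91 * (-0.1141 * sst + 10.78) + 0.08 * (-0.052 * sst + 7.22))
}

#' Relative change in fractionation between two times
#'
#' `big_delta(t) - big_delta(reference)`; the quantity the proxy inverts.
#' Working with the difference cancels constant offsets in the plant record
#' (diagenesis, sample treatment).
#'
#' @param d13c_co2_t,d13c_p_t Atmosphere and plant d13C at the time of
#'   interest, permil VPDB.
#' @param d13c_co2_ref,d13c_p_ref The same at the reference time.
#' @return Change in fractionation, permil.
#' @export
delta_delta <- function(d13c_co2_t, d13c_p_t, d13c_co2_ref, d13c_p_ref) {
  big_delta(d13c_co2_t, d13c_p_t) - big_delta(d13c_co2_ref, d13c_p_ref)
}

#' Invert the fractionation change to pCO2
#'
#' Closed-form rearrangement of the hyperbolic model: given the change in
#' fractionation `ddc` relative to the reference time and the reference
#' pCO2, returns pCO2 at the time of interest,
#' \deqn{pCO2_t = \frac{d A^2 + d A B p_0 + 2 d A B C + d B^2 C p_0 +
#'   d B^2 C^2 + A^2 B p_0}{A^2 B - d A B - d B^2 p_0 - d B^2 C}}
#' with `d = ddc` and `p0 = pco2_ref`. It is the exact inverse of
#' [frac_forward()]: `invert_pco2(frac_forward(p) - frac_forward(p0), p0)`
#' recovers `p` on the valid branch.
#'
#' When the denominator is `<= 0` the requested fractionation change is at or
#' beyond the hyperbola's asymptote and no finite pCO2 exists; such elements
#' are returned as `NA` (a validity flag, not an error) so the Monte Carlo
#' layer can count and drop them.
#'
#' @param ddc Change in fractionation, permil (vector).
#' @param pco2_ref Reference pCO2, ppmv; defaults to `params$pco2_ref`.
#' @param params A [proxy_params()] object.
#' @return pCO2 in ppmv; `NA` where the inversion is beyond the asymptote.
#' @examples
#' invert_pco2(0)  # the reference pCO2, exactly
#' @export
invert_pco2 <- function(ddc, pco2_ref = NULL, params = proxy_params()) {
  if (is.null(pco2_ref)) pco2_ref <- params$pco2_ref
  if (any(!is.finite(pco2_ref)) || any(pco2_ref <= 0))
    stop("'pco2_ref' must be finite and positive")
  .invert_pco2_core(ddc, pco2_ref, params$A, params$B, params$C)
}

# vectorised over all arguments; NA where denominator <= 0
.invert_pco2_core <- function(ddc, p0, A, B, C) {
  num <- ddc * A^2 + ddc * A * B * p0 + 2 * ddc * A * B * C +
    ddc * B^2 * C * p0 + ddc * B^2 * C^2 + A^2 * B * p0
  den <- A^2 * B - ddc * A * B - ddc * B^2 * p0 - ddc * B^2 * C
  out <- num / den
  out[!is.finite(den) | den <= 0] <- NA_real_
  out
}
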