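#' Curve-fit parameters of the C3-plant fractionation proxy
#'
#' Bundles the constants of the hyperbolic relationship between
#' photosynthetic carbon isotope fractionation and pCO2, together with the
#' reference (pre-excursion) state and the 1-sigma uncertainties used by the
#' Monte Carlo propagation.
#'
#' `A` (permil) is the saturation fractionation of the hyperbola, `B` its
#' curvature. `C` is not free: it is pinned so that the fractionation at
#' pCO2 = 0 equals 4.4 permil, `C = A * 4.4 / ((A - 4.4) * B)` (see
#' [compute_C()]). The reference state is the pre-excursion atmosphere:
#' `pco2_ref` (ppmv, from independent stomatal estimates) and `d13c_p_ref`
#' (permil VPDB, the plant baseline immediately before the excursion).
#'
#' `A_sd` defaults to exactly 0: the parameter is still drawn in the Monte
#' Carlo layer, with zero variance, so all parameters are handled uniformly.
#'
#' @param A Saturation fractionation, permil. Must exceed 4.4.
#' @param A_sd 1-sigma uncertainty of `A` (permil), `>= 0`.
#' @param B Curvature parameter, permil^-1 ppmv^-1 scaled. Must be positive.
#' @param B_sd 1-sigma uncertainty of `B`, `>= 0`.
#' @param pco2_ref Reference-time pCO2, ppmv, positive.
#' @param pco2_ref_sd 1-sigma uncertainty of `pco2_ref` (ppmv), `>= 0`.
#' @param d13c_p_ref Reference-time plant d13C, permil VPDB.
#' @param d13c_p_ref_sd 1-sigma uncertainty of `d13c_p_ref` (permil), `>= 0`.
#'
#' @return An object of class `"proxy_params"`: a list with the above fields
#'   plus the derived `C` (ppmv).
#' @examples
#' p <- proxy_params()
#' p$C  # about 23.69 ppmv
#' @seealso [compute_C()], [frac_forward()], [invert_pco2()]
#' @export
proxy_params <- function(A = 28.26, A_sd = 0,
                         B = 0.22, B_sd = 0.028,
                         pco2_ref = 425, pco2_ref_sd = 68,
                         d13c_p_ref = -24.42, d13c_p_ref_sd = 0.5) {
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A),
            is.numeric(B), length(B) == 1L, is.finite(B),
            is.numeric(pco2_ref), length(pco2_ref) == 1L, is.finite(pco2_ref),
            is.numeric(d13c_p_ref), length(d13c_p_ref) == 1L,
            is.finite(d13c_p_ref))
  sds <- c(A_sd = A_sd, B_sd = B_sd, pco2_ref_sd = pco2_ref_sd,
           d13c_p_ref_sd = d13c_p_ref_sd)
  bad <- names(sds)[!is.finite(sds) | sds < 0]
  if (length(bad))
    stop("standard deviations must be finite and >= 0; offending: ",
         paste(bad, collapse = ", "))
  if (pco2_ref <= 0)
    stop("'pco2_ref' must be positive (got ", pco2_ref, ")")
  if (d13c_p_ref <= -1000)
    stop("'d13c_p_ref' must exceed -1000 permil")
  C <- compute_C(A, B)  # validates A > 4.4, B > 0
  structure(list(A = A, A_sd = A_sd, B = B, B_sd = B_sd, C = C,
                 pco2_ref = pco2_ref, pco2_ref_sd = pco2_ref_sd,
                 d13c_p_ref = d13c_p_ref, d13c_p_ref_sd = d13c_p_ref_sd),
            class = "proxy_params")
}

#' @export
print.proxy_params <- function(x, ...) {
  cat("C3-plant proxy parameters\n")
  cat(sprintf("  A          = %g +/- %g permil\n", x$A, x$A_sd))
  cat(sprintf("  B          = %g +/- %g\n", x$B, x$B_sd))
  cat(sprintf("  C          = %g ppmv (derived)\n", x$C))
  cat(sprintf("  pCO2(t=0)  = %g +/- %g ppmv\n", x$pco2_ref, x$pco2_ref_sd))
  cat(sprintf("  d13Cp(t=0) = %g +/- %g permil VPDB\n",
              x$d13c_p_ref, x$d13c_p_ref_sd))
  invisible(x)
}

#' Derived hyperbola offset C
#'
#' `C = A * 4.4 / ((A - 4.4) * B)`, the value that pins the fractionation at
#' pCO2 = 0 to 4.4 permil.
#'
#' @param A Saturation fractionation, permil; must exceed 4.4.
#' @param B Curvature parameter; must be positive.
#' @return C in ppmv. Vectorised over `A` and `B`.
#' @examples
#' compute_C(28.26, 0.22)  # 23.688...
#' @export
compute_C <- function(A, B) {
  if (any(!is.finite(A)) || any(A <= 4.4))
    stop("'A' must be finite and exceed 4.4 permil")
  if (any(!is.finite(B)) || any(B <= 0))
    stop("'B' must be finite and positive")
  A * 4.4 / ((A - 4.4) * B)
}
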