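#' Regular age grid, descending toward younger ages
#'
#' Ages are in Ma before present and decrease toward the young end. The grid
#' includes `age_old` and is half-open at the young end (excludes
#' `age_young`); the number of steps is integer-derived so repeated float
#' addition cannot accumulate.
#'
#' @param age_old Oldest age, Ma.
#' @param age_young Youngest age, Ma; must be less than `age_old`.
#' @param step Grid step in Myr (default 0.002).
#' @return Numeric vector of ages, strictly decreasing.
#' @examples
#' make_age_grid(252.2, 252.19)  # 5 gridpoints
#' @export
make_age_grid <- function(age_old, age_young, step = 0.002) {
  stopifnot(is.numeric(age_old), is.numeric(age_young), is.numeric(step),
            length(age_old) == 1L, length(age_young) == 1L, length(step) == 1L)
  if (!is.finite(step) || step <= 0) stop("'step' must be positive")
  if (age_old <= age_young)
    stop("'age_old' (", age_old, ") must exceed 'age_young' (", age_young, ")")
  n <- floor((age_old - age_young) / step + 1e-9)
  if (n < 1L) stop("grid span shorter than one step")
  age_old - step * (seq_len(n) - 1L)
}
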