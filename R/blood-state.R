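#' Blood sample descriptor
#'
#' A blood state bundles the quantities that determine the optical properties
#' of a (partially lysed) blood sample: initial hematocrit `H0`, lysis level
#' `LL` (fraction of cells ruptured), oxygen saturation `SO2`, the suspending
#' medium, and the total intracellular molar hemoglobin concentration.
#'
#' The current hematocrit after lysis is `H0 * (1 - LL)`; lysis releases the
#' hemoglobin of ruptured cells into the suspending medium, so total
#' hemoglobin is conserved while the cell volume fraction shrinks.
#'
#' @param H0 initial hematocrit, fraction in \[0, 1\].
#' @param LL lysis level, fraction in \[0, 1\].
#' @param SO2 oxygen saturation, fraction in \[0, 1\].
#' @param medium `"PBS"` (phosphate-buffered saline) or `"PLS"` (plasma).
#' @param c_total total intracellular hemoglobin concentration, mol/L.
#' @return an object of class `blood_state`.
#' @examples
#' blood_state(H0 = 0.5, LL = 0.06, SO2 = 0.68)
#' @export
blood_state <- function(H0 = 0.5, LL = 0, SO2 = 0.68,
                        medium = c("PBS", "PLS"), c_total = 5.1e-3) {
  medium <- match.arg(medium)
  stopifnot(is.numeric(H0), is.numeric(LL), is.numeric(SO2),
            length(H0) == 1L, length(LL) == 1L, length(SO2) == 1L)
  if (H0 < 0 || H0 > 1) stop("H0 must be in [0, 1]")
  if (LL < 0 || LL > 1) stop("LL must be in [0, 1]")
  if (SO2 < 0 || SO2 > 1) stop("SO2 must be in [0, 1]")
  if (!is.numeric(c_total) || c_total <= 0) stop("c_total must be positive")
  out <- list(H0 = H0, LL = LL, SO2 = SO2, medium = medium,
              c_total = c_total)
  class(out) <- "blood_state"
  out
}

#' Current (post-lysis) hematocrit of a blood state
#'
#' @param state a [blood_state()].
#' @return `H0 * (1 - LL)`.
#' @export
current_hematocrit <- function(state) {
  stopifnot(inherits(state, "blood_state"))
  state$H0 * (1 - state$LL)
}

#' Oxy-/deoxyhemoglobin partition of a blood state
#'
#' Splits the total intracellular hemoglobin concentration into the
#' oxygenated and deoxygenated species: `c_hbo = SO2 * c_total`,
#' `c_hb = (1 - SO2) * c_total`.
#'
#' @param state a [blood_state()].
#' @return named numeric vector `c(c_hbo = , c_hb = )`, mol/L.
#' @export
hemoglobin_partition <- function(state) {
  stopifnot(inherits(state, "blood_state"))
  c(c_hbo = state$SO2 * state$c_total,
    c_hb = (1 - state$SO2) * state$c_total)
}

#' @export
print.blood_state <- function(x, ...) {
  cat(sprintf(
    "blood_state: H0 = %.3f, LL = %.3f (H_cur = %.3f), SO2 = %.3f, %s, c_total = %.3g mol/L\n",
    x$H0, x$LL, current_hematocrit(x), x$SO2, x$medium, x$c_total))
  invisible(x)
}
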