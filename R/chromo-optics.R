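# Closed-form optics chain: blood state + wavelength -> absorption
# coefficients and complex refractive indices of the cell interior, the
# lysed suspending medium, and the whole sample. Canonical units: cm and
# cm^-1; wavelengths held in nm and converted to cm only inside the
# imaginary-index relation ni = mua * lambda / (4 pi).

NM_PER_CM <- 1e7

medium_field <- function(record, stem, medium) {
  record[[paste0(stem, "_", tolower(medium))]]
}

#' Intracellular absorption coefficient of a red blood cell
#'
#' The cell interior is a concentrated hemoglobin solution that is about 66%
#' water by volume, so its absorption combines the two hemoglobin species
#' (decadic extinction, hence the ln(10) = 2.303 factor) with a 0.66-weighted
#' water term:
#' `mua_RBC = 2.303 * (c_hbo * eps_hbo + c_hb * eps_hb) + 0.66 * mua_water`.
#'
#' @param c_hbo oxyhemoglobin concentration, mol/L.
#' @param c_hb deoxyhemoglobin concentration, mol/L.
#' @param record a one-row [chromophore_record()].
#' @return absorption coefficient, cm^-1.
#' @examples
#' rec <- chromophore_record(700)
#' rbc_absorption(0.68 * 5.1e-3, 0.32 * 5.1e-3, rec)  # ~9.07 cm^-1
#' @export
rbc_absorption <- function(c_hbo, c_hb, record) {
  stopifnot(c_hbo >= 0, c_hb >= 0, nrow(record) == 1L)
  2.303 * (c_hbo * record$eps_hbo + c_hb * record$eps_hb) +
    0.66 * record$mua_water
}

#' Complex refractive index of the red-cell interior
#'
#' The real part scales the medium index by the dissolved hemoglobin through
#' the specific refractive increment B: `nr = nr_M * (B * c_total + 1)`.
#' The imaginary part follows from the absorption coefficient:
#' `ni = mua_RBC * lambda / (4 pi)` with lambda in cm (ni dimensionless).
#'
#' @param c_total total hemoglobin concentration, mol/L.
#' @param record a one-row [chromophore_record()].
#' @param mua_rbc intracellular absorption coefficient, cm^-1.
#' @param medium `"PBS"` or `"PLS"` (selects the medium index nr_M).
#' @return named numeric vector `c(nr = , ni = )`.
#' @export
rbc_refractive_index <- function(c_total, record, mua_rbc,
                                 medium = c("PBS", "PLS")) {
  medium <- match.arg(medium)
  stopifnot(c_total >= 0, mua_rbc >= 0, nrow(record) == 1L)
  nr_m <- medium_field(record, "nr", medium)
  lambda_cm <- record$lambda_nm / NM_PER_CM
  c(nr = nr_m * (record$B * c_total + 1),
    ni = mua_rbc * lambda_cm / (4 * pi))
}

#' Absorption coefficient of the lysed suspending medium
#'
#' Hemoglobin released by ruptured cells mixes into the extracellular volume
#' `1 - H + H*LL` (per unit sample volume), raising the medium absorption:
#' `mua_LM = (H*LL*mua_RBC + (1-H)*mua_M) / (1 - H + H*LL)`.
#'
#' @param state a [blood_state()]; `H0` and `LL` are used.
#' @param mua_rbc intracellular absorption coefficient, cm^-1.
#' @param record a one-row [chromophore_record()] supplying the pure-medium
#'   absorption.
#' @return absorption coefficient of the lysed medium, cm^-1.
#' @export
lysed_medium_absorption <- function(state, mua_rbc, record) {
  stopifnot(inherits(state, "blood_state"), mua_rbc >= 0,
            nrow(record) == 1L)
  H <- state$H0
  LL <- state$LL
  denom <- 1 - H + H * LL
  if (denom <= 0) {
    stop("degenerate extracellular volume: 1 - H + H*LL must be positive ",
         "(H0 = ", H, ", LL = ", LL, ")")
  }
  mua_m <- medium_field(record, "mua", state$medium)
  (H * LL * mua_rbc + (1 - H) * mua_m) / denom
}

#' Complex refractive index of the lysed suspending medium
#'
#' The real index rises with the free-hemoglobin molarity in the
#' extracellular volume, `c_free = H*LL*c_total / (1 - H + H*LL)`, through
#' the same specific refractive increment used for the cell interior:
#' `nr_LM = nr_M * (B * c_free + 1)`. The imaginary part is
#' `ni_LM = mua_LM * lambda / (4 pi)` (lambda in cm).
#'
#' @param state a [blood_state()].
#' @param record a one-row [chromophore_record()].
#' @param mua_lm lysed-medium absorption coefficient, cm^-1
#'   (see [lysed_medium_absorption()]).
#' @return list with fields `mua_lm`, `nr_lm`, `ni_lm` (class `medium_optics`).
#' @export
lysed_medium_index <- function(state, record, mua_lm) {
  stopifnot(inherits(state, "blood_state"), mua_lm >= 0,
            nrow(record) == 1L)
  H <- state$H0
  LL <- state$LL
  denom <- 1 - H + H * LL
  if (denom <= 0) stop("degenerate extracellular volume")
  c_free <- H * LL * state$c_total / denom
  nr_m <- medium_field(record, "nr", state$medium)
  lambda_cm <- record$lambda_nm / NM_PER_CM
  out <- list(mua_lm = mua_lm,
              nr_lm = nr_m * (record$B * c_free + 1),
              ni_lm = mua_lm * lambda_cm / (4 * pi))
  class(out) <- "medium_optics"
  out
}

#' Whole-sample absorption coefficient
#'
#' Adds the contributions of the intact cells and the (lysed) suspending
#' medium by volume fraction:
#' `mua_BS = H*(1-LL)*mua_RBC + (1 - H + H*LL)*mua_LM`.
#' At fixed total hemoglobin this is independent of the lysis level —
#' absorption tracks total hemoglobin, which lysis merely redistributes.
#'
#' @param state a [blood_state()].
#' @param mua_rbc intracellular absorption coefficient, cm^-1.
#' @param mua_lm lysed-medium absorption coefficient, cm^-1.
#' @return whole-sample absorption coefficient, cm^-1.
#' @export
whole_blood_absorption <- function(state, mua_rbc, mua_lm) {
  stopifnot(inherits(state, "blood_state"), mua_rbc >= 0, mua_lm >= 0)
  H <- state$H0
  LL <- state$LL
  H * (1 - LL) * mua_rbc + (1 - H + H * LL) * mua_lm
}

#' Bulk optical coefficients from single-cell efficiencies
#'
#' Scales per-cell efficiency factors to per-volume coefficients using the
#' current cell number density `H_cur / V_RBC` and the geometric
#' cross-section `pi * aeff^2` of the equivalent-volume sphere; scattering
#' carries the `(1 - H_cur)^2` packing factor of concentrated suspensions:
#' `mua = (H/V) * Qabs * pi * aeff^2`,
#' `mus = (H/V) * (1-H)^2 * Qsca * pi * aeff^2`.
#' `H_cur` is the current, post-lysis hematocrit.
#'
#' @param h_cur current hematocrit (fraction, < 1).
#' @param qabs,qsca absorption and scattering efficiency factors.
#' @param aeff equivalent-volume-sphere radius, micrometers.
#' @param v_rbc cell volume, femtoliters (= cubic micrometers).
#' @return named numeric vector `c(mua = , mus = )`, cm^-1.
#' @examples
#' bulk_from_efficiencies(0.50, 389.4e-5, 3.045, aeff = 2.79, v_rbc = 91.52)
#' @export
bulk_from_efficiencies <- function(h_cur, qabs, qsca, aeff = 2.79,
                                   v_rbc = 91.52) {
  stopifnot(qabs >= 0, qsca >= 0, aeff > 0, v_rbc > 0)
  if (h_cur < 0 || h_cur >= 1) {
    stop("current hematocrit must lie in [0, 1); got ", h_cur)
  }
  # micrometer^-1 -> cm^-1 conversion factor 1e4
  sigma_g <- pi * aeff^2                   # um^2
  mua <- h_cur / v_rbc * qabs * sigma_g * 1e4
  mus <- h_cur / v_rbc * (1 - h_cur)^2 * qsca * sigma_g * 1e4
  c(mua = mua, mus = mus)
}

#' Bulk optics container
#'
#' The per-wavelength currency between the optics stage and photon
#' transport: whole-sample absorption, scattering and anisotropy.
#'
#' @param lambda_nm wavelength, nm.
#' @param mua bulk absorption coefficient, cm^-1.
#' @param mus bulk scattering coefficient, cm^-1.
#' @param g anisotropy factor in \[-1, 1\].
#' @return object of class `bulk_optics`.
#' @export
bulk_optics <- function(lambda_nm, mua, mus, g) {
  stopifnot(mua >= 0, mus >= 0, g >= -1, g <= 1)
  out <- list(lambda_nm = lambda_nm, mua = mua, mus = mus, g = g)
  class(out) <- "bulk_optics"
  out
}

#' @export
print.bulk_optics <- function(x, ...) {
  cat(sprintf("bulk_optics @ %g nm: mua = %.4g cm^-1, mus = %.4g cm^-1, g = %.4g\n",
              x$lambda_nm, x$mua, x$mus, x$g))
  invisible(x)
}

#' Bulk optics of a blood state from the published efficiency table
#'
#' Convenience lookup: matches `(lambda_nm, medium, LL)` in the packaged
#' single-cell efficiency table and returns the tabulated bulk coefficients
#' as a [bulk_optics()] object.
#'
#' @param state a [blood_state()].
#' @param lambda_nm wavelength, nm.
#' @return a [bulk_optics()].
#' @export
tabulated_bulk_optics <- function(state, lambda_nm) {
  tab <- bulk_optics_reference()
  i <- which(tab$lambda_nm == lambda_nm & tab$medium == state$medium &
             tab$ll_pct == round(100 * state$LL))
  if (length(i) != 1L) {
    stop("no tabulated bulk optics for lambda = ", lambda_nm, " nm, medium ",
         state$medium, ", LL = ", 100 * state$LL, "%")
  }
  bulk_optics(lambda_nm, tab$mua_bs[i], tab$mus_bs[i], tab$g[i])
}

#' Full closed-form optics chain for a blood state at one wavelength
#'
#' Runs the whole optics cascade: hemoglobin partition, intracellular
#' absorption and complex index, lysed-medium absorption and complex index,
#' and whole-sample absorption.
#'
#' @param state a [blood_state()].
#' @param lambda_nm wavelength, nm.
#' @param table a [chromophore_table()].
#' @return list with `mua_rbc`, `nr_rbc`, `ni_rbc`, `medium` (a
#'   `medium_optics`), and `mua_bs`.
#' @export
blood_optics <- function(state, lambda_nm, table = chromophore_table()) {
  record <- chromophore_record(lambda_nm, table)
  part <- hemoglobin_partition(state)
  mua_rbc <- rbc_absorption(part[["c_hbo"]], part[["c_hb"]], record)
  idx <- rbc_refractive_index(state$c_total, record, mua_rbc, state$medium)
  mua_lm <- lysed_medium_absorption(state, mua_rbc, record)
  med <- lysed_medium_index(state, record, mua_lm)
  list(mua_rbc = mua_rbc, nr_rbc = idx[["nr"]], ni_rbc = idx[["ni"]],
       medium = med,
       mua_bs = whole_blood_absorption(state, mua_rbc, mua_lm))
}
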