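#' Chromophore and medium constants table
#'
#' Loads the embedded compilation of decadic molar extinction coefficients for
#' oxy- and deoxyhemoglobin, water absorption, suspending-medium refractive
#' indices and absorption (PBS and blood plasma), and the specific refractive
#' index increment B, at the working wavelengths 700, 905 and 1000 nm.
#'
#' The hemoglobin extinction values are a literature compilation (the exact
#' tabulation behind published intracellular coefficients is not unique across
#' sources; values here sit within the spread of standard NIR compilations).
#' The table is replaceable: pass a path to a CSV with identical columns.
#'
#' @param path optional path to a user CSV overriding the packaged table.
#'   Columns: `lambda_nm`, `eps_hbo`, `eps_hb` (cm^-1 per mol/L), `mua_water`
#'   (cm^-1), `nr_pbs`, `nr_pls`, `B` (L/mol), `mua_pbs`, `mua_pls` (cm^-1).
#' @return data.frame with one row per wavelength.
#' @export
chromophore_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "chromophores.csv", package = "lysedpa",
                        mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("lambda_nm", "eps_hbo", "eps_hb", "mua_water",
                "nr_pbs", "nr_pls", "B", "mua_pbs", "mua_pls")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("chromophore table is missing columns: ",
         paste(missing, collapse = ", "))
  }
  num <- tab[required[-1]]
  if (any(!vapply(num, is.numeric, logical(1L)))) {
    stop("chromophore table columns must be numeric")
  }
  if (any(tab$eps_hbo < 0 | tab$eps_hb < 0 | tab$mua_water < 0 |
          tab$mua_pbs < 0 | tab$mua_pls < 0)) {
    stop("extinction and absorption entries must be non-negative")
  }
  if (any(tab$B <= 0)) stop("B must be positive")
  class(tab) <- c("chromophore_table", "data.frame")
  tab
}

#' Look up the chromophore record for one wavelength
#'
#' @param lambda_nm wavelength in nm.
#' @param table a [chromophore_table()]; default the packaged one.
#' @return one-row data.frame (a `ChromophoreRecord`).
#' @export
chromophore_record <- function(lambda_nm, table = chromophore_table()) {
  i <- which(table$lambda_nm == lambda_nm)
  if (length(i) != 1L) {
    stop("no chromophore record for wavelength ", lambda_nm,
         " nm; available: ", paste(table$lambda_nm, collapse = ", "))
  }
  table[i, , drop = FALSE]
}

#' Printed reference optics of lysed suspending media
#'
#' Published per-lysis-level values of the lysed-medium absorption
#' coefficient, its complex refractive index, and the whole-sample absorption
#' coefficient, for PBS- and plasma-based media at 700/905/1000 nm. Used both
#' as a cross-check for the closed-form optics chain and as pipeline input.
#'
#' @return data.frame with columns `lambda_nm`, `medium`, `h_pct`, `ll_pct`,
#'   `mua_lm` (cm^-1), `nr_lm`, `ni_lm_e5` (imaginary index x 1e5),
#'   `mua_bs` (cm^-1).
#' @export
lysed_medium_reference <- function() {
  utils::read.csv(system.file("extdata", "lysed_medium_reference.csv",
                              package = "lysedpa", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Published single-cell efficiencies and bulk optics per lysis level
#'
#' Orientation-averaged absorption/scattering efficiencies of a single red
#' cell embedded in progressively lysed media, with the resulting bulk
#' absorption and scattering coefficients and anisotropy factor. These values
#' are the standard optical input of the photon-transport stage.
#'
#' @return data.frame with columns `lambda_nm`, `medium`, `ll_pct`,
#'   `qabs_e5` (Qabs x 1e5), `mua_bs` (cm^-1), `qsca`, `mus_bs` (cm^-1), `g`.
#' @export
bulk_optics_reference <- function() {
  utils::read.csv(system.file("extdata", "bulk_optics_dda.csv",
                              package = "lysedpa", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Published intracellular absorption and refractive index at SO2 = 0.68
#'
#' @return data.frame with columns `lambda_nm`, `mua_rbc` (cm^-1), `nr_rbc`,
#'   `ni_rbc_e5`.
#' @export
intracellular_reference <- function() {
  utils::read.csv(system.file("extdata", "intracellular_reference.csv",
                              package = "lysedpa", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Published simulated dual-wavelength estimates per lysis level
#'
#' @return data.frame with columns `pair`, `medium`, `ll_pct`, `est_ll_pct`,
#'   `est_so2_pct`.
#' @export
simulated_estimates_reference <- function() {
  utils::read.csv(system.file("extdata", "simulated_estimates_reference.csv",
                              package = "lysedpa", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
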