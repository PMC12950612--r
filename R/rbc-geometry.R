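# Biconcave red-cell geometry: analytic Evans-Fung-type meridional profile
# plus discretization onto a cubic dipole/voxel lattice.

#' Biconcave cell shape parameters
#'
#' Four morphological parameters fix the meridional cross-section of a
#' biconcave disc: cell diameter `D`, central dimple thickness `t`, maximum
#' thickness `h`, and the diameter `d` of the circle where the thickness is
#' maximal. Defaults are the standard healthy-cell values.
#'
#' @param D cell diameter, micrometers.
#' @param t dimple (central) thickness, micrometers.
#' @param h maximum thickness, micrometers.
#' @param d diameter of the maximum-thickness circle, micrometers.
#' @return object of class `biconcave_params`.
#' @export
biconcave_params <- function(D = 8.40, t = 0.85, h = 2.04, d = 5.88) {
  if (!(t > 0 && t < h && h < D)) stop("need 0 < t < h < D")
  if (!(d > 0 && d < D)) stop("need 0 < d < D")
  out <- list(D = D, t = t, h = h, d = d)
  class(out) <- "biconcave_params"
  out
}

#' Quartic profile coefficients for a biconcave cell
#'
#' The half-thickness is modeled as the Evans-Fung-type quartic
#' `z(rho) = sqrt(1 - r^2) * (c0 + c2 r^2 + c4 r^4) / 2` where r denotes
#' the normalized radius `2 rho / D`.
#' The three coefficients are solved from `z(0) = t/2`, `z(d/2) = h/2`, and
#' stationarity of z at `rho = d/2` (the thickness maximum sits on the circle
#' of diameter d).
#'
#' @param params a [biconcave_params()].
#' @return named numeric vector `c(c0 = , c2 = , c4 = )` (micrometers).
#' @export
biconcave_coefficients <- function(params) {
  stopifnot(inherits(params, "biconcave_params"))
  rd <- params$d / params$D
  s <- sqrt(1 - rd^2)
  # value constraint:  s * (c0 + c2 rd^2 + c4 rd^4) = h
  # stationarity:      -rd/s * g(rd) + s * (2 c2 rd + 4 c4 rd^3) = 0
  g_rd <- params$h / s
  A <- rbind(c(rd^2, rd^4),
             c(2 * rd * s^2, 4 * rd^3 * s^2))
  b <- c(g_rd - params$t,
         rd * g_rd)
  sol <- tryCatch(solve(A, b), error = function(e) {
    stop("singular constraint system for biconcave coefficients ",
         "(inconsistent shape parameters)")
  })
  c(c0 = params$t, c2 = sol[1L], c4 = sol[2L])
}

#' Half-thickness of the biconcave profile
#'
#' @param rho radial coordinate in the equatorial plane, micrometers,
#'   vectorized over \[0, D/2\].
#' @param params a [biconcave_params()].
#' @return half-thickness z(rho), micrometers; zero at the rim rho = D/2.
#' @examples
#' p <- biconcave_params()
#' biconcave_halfthickness(0, p)            # t/2
#' biconcave_halfthickness(p$d / 2, p)      # h/2, the global maximum
#' @export
biconcave_halfthickness <- function(rho, params) {
  stopifnot(inherits(params, "biconcave_params"))
  if (any(rho < 0 | rho > params$D / 2)) {
    stop("rho must lie in [0, D/2]")
  }
  cf <- biconcave_coefficients(params)
  r2 <- (2 * rho / params$D)^2
  z <- sqrt(pmax(0, 1 - r2)) * (cf[["c0"]] + cf[["c2"]] * r2 +
                                  cf[["c4"]] * r2^2) / 2
  pmax(z, 0)
}

#' Analytic volume of the biconcave solid of revolution
#'
#' Closed-form integral of the quartic profile:
#' `V = (pi D^2 / 2) * (c0/3 + 2 c2/15 + 8 c4/105)`.
#'
#' @param params a [biconcave_params()].
#' @return volume in femtoliters (cubic micrometers).
#' @export
biconcave_volume <- function(params) {
  cf <- biconcave_coefficients(params)
  pi * params$D^2 / 2 *
    (cf[["c0"]] / 3 + 2 * cf[["c2"]] / 15 + 8 * cf[["c4"]] / 105)
}

#' Discretize the biconcave cell onto a cubic lattice
#'
#' A lattice site is occupied iff its center lies inside the solid of
#' revolution (standard center-in-solid DDA target generation; no
#' partial-volume weighting). Sites are integer triples centered on the cell,
#' with the symmetry axis along z.
#'
#' @param params a [biconcave_params()].
#' @param spacing lattice constant, micrometers.
#' @return object of class `dipole_lattice`: fields `sites` (integer matrix
#'   n x 3), `spacing`, `n_dipoles`, `volume` (fL), `aeff` (um), and
#'   `profile_coefficients`.
#' @export
voxelize_cell <- function(params, spacing) {
  stopifnot(inherits(params, "biconcave_params"))
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be positive")
  R <- params$D / 2
  zmax <- params$h / 2
  nr <- floor(R / spacing)
  nz <- floor(zmax / spacing)
  # symmetric half-offset ranges: site centers at (i + 1/2) d cover +/- the
  # same coordinates, so mirror (k -> -k-1) and 90-degree rotation
  # ((i, j) -> (-j-1, i)) are exact site-multiset symmetries
  ix <- seq.int(-nr - 1L, nr)
  iz <- seq.int(-nz - 1L, nz)
  # half-grid offsets center the lattice between sites along each axis so the
  # mirror/rotation symmetries are exact site-multiset symmetries
  xs <- (ix + 0.5) * spacing
  zs <- (iz + 0.5) * spacing
  rho <- sqrt(outer(xs^2, xs^2, "+"))          # |(x, y)| per (ix, iy)
  keep_rho <- rho <= R
  zprof <- matrix(0, nrow = length(xs), ncol = length(xs))
  zprof[keep_rho] <- biconcave_halfthickness(rho[keep_rho], params)
  sites_list <- vector("list", length(iz))
  for (k in seq_along(iz)) {
    inside <- keep_rho & (abs(zs[k]) <= zprof)
    if (any(inside)) {
      idx <- which(inside, arr.ind = TRUE)
      sites_list[[k]] <- cbind(ix[idx[, 1L]], ix[idx[, 2L]], iz[k])
    }
  }
  sites <- do.call(rbind, sites_list)
  if (is.null(sites) || nrow(sites) == 0L) {
    stop("spacing too coarse: no lattice sites fall inside the cell")
  }
  n <- nrow(sites)
  vol <- n * spacing^3
  out <- list(sites = sites, spacing = spacing, n_dipoles = n,
              volume = vol, aeff = (3 * vol / (4 * pi))^(1 / 3),
              offset = 0.5,
              profile_coefficients = biconcave_coefficients(params),
              params = params)
  class(out) <- "dipole_lattice"
  out
}

#' Discretize a sphere onto a cubic lattice
#'
#' Companion target generator used to validate the dipole solver against
#' Mie theory.
#'
#' @param radius sphere radius, micrometers.
#' @param spacing lattice constant, micrometers.
#' @return a `dipole_lattice` (see [voxelize_cell()]).
#' @export
voxelize_sphere <- function(radius, spacing) {
  stopifnot(radius > 0, spacing > 0)
  nr <- floor(radius / spacing)
  ix <- seq.int(-nr - 1L, nr)
  xs <- (ix + 0.5) * spacing
  grid <- expand.grid(i = ix, j = ix, k = ix)
  r2 <- (grid$i + 0.5)^2 + (grid$j + 0.5)^2 + (grid$k + 0.5)^2
  keep <- r2 * spacing^2 <= radius^2
  if (!any(keep)) stop("spacing too coarse: empty sphere lattice")
  sites <- as.matrix(grid[keep, , drop = FALSE])
  dimnames(sites) <- NULL
  n <- nrow(sites)
  vol <- n * spacing^3
  out <- list(sites = sites, spacing = spacing, n_dipoles = n,
              volume = vol, aeff = (3 * vol / (4 * pi))^(1 / 3),
              offset = 0.5, profile_coefficients = NULL, params = NULL)
  class(out) <- "dipole_lattice"
  out
}

#' Physical site coordinates of a lattice
#'
#' @param lattice a `dipole_lattice`.
#' @return numeric matrix n x 3 of site centers, micrometers.
#' @export
lattice_coordinates <- function(lattice) {
  stopifnot(inherits(lattice, "dipole_lattice"))
  (lattice$sites + lattice$offset) * lattice$spacing
}

#' @export
print.dipole_lattice <- function(x, ...) {
  cat(sprintf(
    "dipole_lattice: %d sites, spacing %.4g um, volume %.4g fL, aeff %.4g um\n",
    x$n_dipoles, x$spacing, x$volume, x$aeff))
  invisible(x)
}

#' Write a lattice as a whitespace target file plus JSON metadata
#'
#' One occupied site per line (`ix iy iz`); metadata (spacing, counts,
#' volume, aeff, profile coefficients) goes to `<path>.json`.
#'
#' @param lattice a `dipole_lattice`.
#' @param path output path for the site list.
#' @return `path`, invisibly.
#' @export
write_lattice <- function(lattice, path) {
  stopifnot(inherits(lattice, "dipole_lattice"))
  utils::write.table(lattice$sites, path, row.names = FALSE,
                     col.names = FALSE)
  meta <- list(spacing = lattice$spacing, n_dipoles = lattice$n_dipoles,
               volume = lattice$volume, aeff = lattice$aeff,
               offset = lattice$offset,
               profile_coefficients = as.list(lattice$profile_coefficients))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a lattice written by [write_lattice()]
#'
#' @param path path to the site list (with `<path>.json` alongside).
#' @return a `dipole_lattice`.
#' @export
read_lattice <- function(path) {
  sites <- as.matrix(utils::read.table(path, col.names = c("i", "j", "k")))
  dimnames(sites) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  out <- list(sites = sites, spacing = meta$spacing,
              n_dipoles = nrow(sites), volume = meta$volume,
              aeff = meta$aeff, offset = meta$offset,
              profile_coefficients = unlist(meta$profile_coefficients),
              params = NULL)
  class(out) <- "dipole_lattice"
  out
}
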