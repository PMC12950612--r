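# Voxelized Monte Carlo photon transport (hop-drop-spin) producing the
# deposited-fluence map used as the photoacoustic source term.

#' Voxel grid of optical properties
#'
#' @param bulk a [bulk_optics()] filled into every voxel (homogeneous
#'   sample), or `NULL` to pass explicit arrays.
#' @param dims voxel counts `(nx, ny, nz)`.
#' @param dx voxel edge, cm.
#' @param mua,mus,g optional arrays/scalars overriding `bulk`.
#' @param n_medium refractive index of the sample for the top-surface
#'   Fresnel computation.
#' @return object of class `voxel_grid` with 3D arrays `mua`, `mus`, `g`.
#' @examples
#' build_grid(bulk_optics(700, 5.203, 1017.2, 0.991), dims = c(20, 20, 20))
#' @export
build_grid <- function(bulk = NULL, dims = c(200L, 200L, 200L), dx = 0.005,
                       mua = NULL, mus = NULL, g = NULL, n_medium = 1.33) {
  if (!is.numeric(dx) || dx <= 0) stop("dx must be positive")
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) stop("dims must be 3 positive counts")
  fill <- function(x, what) {
    if (is.null(x)) stop("missing optical property: ", what)
    if (length(x) == 1L) x <- array(x, dim = dims)
    if (!all(dim(x) == dims)) stop(what, " array does not match dims")
    x
  }
  if (!is.null(bulk)) {
    stopifnot(inherits(bulk, "bulk_optics"))
    if (!all(is.finite(c(bulk$mua, bulk$mus, bulk$g)))) {
      stop("bulk optical properties must be finite")
    }
    mua <- bulk$mua; mus <- bulk$mus; g <- bulk$g
  }
  mua <- fill(mua, "mua"); mus <- fill(mus, "mus"); g <- fill(g, "g")
  if (any(mua < 0) || any(mus < 0)) stop("mua and mus must be non-negative")
  if (any(g < -1 | g > 1)) stop("g must lie in [-1, 1]")
  out <- list(dims = dims, dx = dx, mua = mua, mus = mus, g = g,
              n_medium = n_medium)
  class(out) <- "voxel_grid"
  out
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "voxel_grid: %d x %d x %d voxels, dx = %g cm, mua in [%.3g, %.3g] cm^-1\n",
    x$dims[1L], x$dims[2L], x$dims[3L], x$dx, min(x$mua), max(x$mua)))
  invisible(x)
}

#' Random absorption fluctuations on a fraction of voxels
#'
#' Multiplies the absorption coefficient of exactly
#' `round(fraction * n_voxels)` randomly selected voxels by `(1 + u)`,
#' `u ~ Uniform(-amplitude, amplitude)`, emulating sample heterogeneity.
#'
#' @param grid a [build_grid()] result.
#' @param fraction fraction of voxels perturbed (default 0.10).
#' @param amplitude relative fluctuation amplitude (default 0.01 = 1%).
#' @param seed RNG seed for reproducibility.
#' @return the perturbed `voxel_grid`.
#' @export
perturb_mua <- function(grid, fraction = 0.10, amplitude = 0.01, seed = 1L) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  n <- prod(grid$dims)
  n_sel <- round(fraction * n)
  if (n_sel == 0L) return(grid)
  set.seed(seed)
  sel <- sample.int(n, n_sel)
  u <- stats::runif(n_sel, -amplitude, amplitude)
  grid$mua[sel] <- grid$mua[sel] * (1 + u)
  grid
}

#' Illumination beam
#'
#' Uniform-disk, normally incident, temporally impulsive beam entering at
#' the center of the top face (z = 0).
#'
#' @param diameter beam diameter, cm (default 0.10).
#' @return object of class `beam`.
#' @export
beam <- function(diameter = 0.10) {
  stopifnot(diameter > 0)
  out <- list(diameter = diameter, profile = "uniform_disk",
              temporal = "delta")
  class(out) <- "beam"
  out
}

#' Run photon packets through a voxel grid
#'
#' Hop lengths are exponential in the local total attenuation
#' `mu_t = mua + mus`, with hops split exactly at voxel boundaries; each
#' interaction deposits the fraction `mua/mu_t` of the packet weight in the
#' interaction voxel and scatters through a Henyey-Greenstein polar angle
#' with the voxel's g. Packets below `w_threshold` play Russian roulette
#' (survival factor `roulette_m`). The top surface (z = 0) applies Fresnel
#' specular/internal reflection between `n_medium` and `n_outside`; side and
#' bottom walls absorb. Fluence is deposited weight per voxel divided by
#' `mua * voxel volume * n_photons` (per unit incident energy).
#'
#' @param grid a [build_grid()] result.
#' @param bm a [beam()].
#' @param n_photons number of packets.
#' @param seed RNG seed.
#' @param n_outside refractive index above the top surface (default 1.0).
#' @param w_threshold roulette threshold (default 1e-4).
#' @param roulette_m roulette survival factor (default 10); `<= 1` disables
#'   roulette (packets terminate at the threshold).
#' @param specular apply the normal-incidence specular reflection at launch.
#' @param top_fresnel enable Fresnel reflection at the top surface.
#' @return object of class `fluence_map`: `values` (3D array, J/cm^2 per J
#'   incident), `deposited` (raw weight), `audit` (weight ledger), `dims`,
#'   `dx`, `n_photons`, `seed`.
#' @export
run_photons <- function(grid, bm = beam(), n_photons, seed = 1L,
                        n_outside = 1.0, w_threshold = 1e-4,
                        roulette_m = 10, specular = TRUE,
                        top_fresnel = TRUE) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(bm, "beam"))
  if (n_photons < 1L) stop("n_photons must be >= 1")
  if (bm$diameter > min(grid$dims[1:2]) * grid$dx) {
    stop("beam diameter exceeds the lateral grid extent")
  }
  if (all(grid$mua + grid$mus == 0)) {
    warning("zero total attenuation: photons traverse ballistically to the absorbing walls")
  }
  set.seed(seed)
  res <- cpp_run_photons(as.numeric(grid$mua), as.numeric(grid$mus),
                         as.numeric(grid$g), grid$dims, grid$dx,
                         bm$diameter / 2, grid$n_medium, n_outside,
                         as.integer(n_photons), w_threshold, roulette_m,
                         specular, top_fresnel)
  dep <- array(res$deposited, dim = grid$dims)
  vvox <- grid$dx^3
  fl <- array(0, dim = grid$dims)
  nz <- grid$mua > 0
  fl[nz] <- dep[nz] / (grid$mua[nz] * vvox * n_photons)
  audit <- c(deposited = sum(dep), escaped_top = res$escaped_top,
             escaped_other = res$escaped_other, specular = res$specular,
             roulette_net = res$roulette_net)
  out <- list(values = fl, deposited = dep, audit = audit,
              dims = grid$dims, dx = grid$dx, n_photons = n_photons,
              seed = seed)
  class(out) <- "fluence_map"
  out
}

#' @export
print.fluence_map <- function(x, ...) {
  cat(sprintf(
    "fluence_map: %d x %d x %d voxels, %g photons, peak %.4g, deposited %.3f of launched\n",
    x$dims[1L], x$dims[2L], x$dims[3L], x$n_photons, max(x$values),
    x$audit[["deposited"]] / x$n_photons))
  invisible(x)
}

#' Sample Henyey-Greenstein scattering cosines
#'
#' Inverse-CDF draw of the polar scattering cosine for anisotropy g;
#' `E[cos theta] = g`, isotropic for g = 0, deterministic forward/backward
#' at |g| = 1.
#'
#' @param g anisotropy in \[-1, 1\].
#' @param n number of draws.
#' @param seed optional RNG seed.
#' @return numeric vector of cosines in \[-1, 1\].
#' @export
hg_sample <- function(g, n, seed = NULL) {
  if (abs(g) > 1) stop("g must lie in [-1, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (abs(g) == 1) return(rep(sign(g), n))
  cpp_hg_sample(g, as.integer(n))
}

#' Serialize a fluence map (array container + CSV mid-plane slice)
#'
#' Writes the full array with metadata to `<path>.rds` (with a JSON sidecar
#' carrying dims, dx, seed and photon count) and the mid-plane y-slice as a
#' CSV for quick inspection.
#'
#' @param fluence a `fluence_map`.
#' @param path output stem (no extension).
#' @return `path`, invisibly.
#' @export
write_fluence <- function(fluence, path) {
  stopifnot(inherits(fluence, "fluence_map"))
  saveRDS(fluence, paste0(path, ".rds"))
  meta <- list(dims = fluence$dims, dx = fluence$dx, seed = fluence$seed,
               n_photons = fluence$n_photons)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  mid <- fluence$values[, ceiling(fluence$dims[2L] / 2), ]
  utils::write.csv(mid, paste0(path, "_midplane.csv"), row.names = FALSE)
  invisible(path)
}
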