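# Shared fixtures and a memo cache so expensive simulations run once per
# suite invocation.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# noiseless desk-scale lysis series at the 700-905 nm pair (10 forward runs)
desk_series <- function() {
  fixture("desk_series", lysis_series(seed = 1))
}

# small sphere lattice shared by dipole-solver unit tests
small_sphere_fit <- function() {
  fixture("small_sphere_fit", {
    lat <- voxelize_sphere(1, 1 / 14)
    sys <- dipole_system(lat, 1.05 + 0i, k = 1)
    list(lat = lat, sys = sys, fit = solve_dipole_system(sys))
  })
}

# analytic outward spherical wave from a Gaussian-ball initial pressure
gaussian_ball_wave <- function(R, sigma, tt, c_cm) {
  rho <- c_cm * tt
  (1 / (2 * R)) * ((R - rho) * exp(-(R - rho)^2 / (2 * sigma^2)) +
                     (R + rho) * exp(-(R + rho)^2 / (2 * sigma^2)))
}

# single-point "sensor" helper for propagator tests
point_sensor <- function(xyz_cm) {
  out <- list(points = matrix(xyz_cm, ncol = 3L), n_points = nrow(matrix(xyz_cm, ncol = 3L)),
              radius = 0.05, f0 = 5e6, fractional_bw = 0.7,
              focal_length = 0.25)
  class(out) <- "transducer_spec"
  out
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
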