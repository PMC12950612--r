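# Discrete dipole solver: polarizability prescriptions, FFT vs dense
# products, efficiency factors, angular patterns, orientation averaging.

test_that("polarizability prescriptions agree with their closed forms", {
  m <- 1.05 + 0i
  d <- 0.1
  cm <- polarizability(m, d, k = 1, scheme = "CM")
  expect_equal(cm, 3 * d^3 / (4 * pi) * (m^2 - 1) / (m^2 + 2))
  expect_equal(polarizability(1, d, 1, "CM"), 0 + 0i)
  # the lattice correction vanishes with kd
  ldr <- polarizability(m, d, k = 1e-3, scheme = "LDR")
  expect_lt(Mod(ldr - cm) / Mod(cm), 1e-6)
  expect_error(polarizability(sqrt(-2 + 0i), d, 1), "resonant")
})

test_that("a single dipole carries the non-interacting solution", {
  lat <- list(sites = matrix(0L, 1L, 3L), spacing = 0.1, n_dipoles = 1L,
              volume = 1e-3, aeff = (3e-3 / (4 * pi))^(1 / 3), offset = 0.5,
              profile_coefficients = NULL, params = NULL)
  class(lat) <- "dipole_lattice"
  sys <- dipole_system(lat, 1.2 + 0.05i, k = 2)
  fit <- solve_dipole_system(sys)
  expect_equal(fit$P, sys$alpha * sys$e_inc)
  # fore-aft symmetric dipole pattern has zero asymmetry
  expect_lt(abs(asymmetry_g(fit, n_theta = 64L, n_phi = 96L)), 1e-10)
})

test_that("FFT-accelerated products match the dense solve", {
  lat <- voxelize_sphere(0.3, 0.12)
  sys <- dipole_system(lat, 1.2 + 0.01i, k = 2)
  fit_fft <- solve_dipole_system(sys, tol = 1e-12)
  fit_dense <- solve_dipole_system(sys, dense = TRUE)
  expect_lt(max(Mod(fit_fft$P - fit_dense$P)), 1e-10)
  expect_lte(fit_fft$residual, 1e-12)
})

test_that("solver honors its tolerance contract and failure mode", {
  fit <- small_sphere_fit()$fit
  expect_lte(fit$residual, 1e-5)
  sys <- small_sphere_fit()$sys
  expect_error(solve_dipole_system(sys, tol = 1e-14, max_iter = 1L),
               "did not converge")
})

test_that("sphere efficiencies track the Mie oracle", {
  fx <- small_sphere_fit()
  eff <- efficiencies(fx$fit, aeff = 1)
  mie <- mie_efficiencies(1.05 + 0i, 1)
  expect_lt(rel_err(eff$qext, mie$qext), 0.02)
  expect_lt(rel_err(eff$qsca, mie$qsca), 0.02)
  expect_lt(abs(eff$g - mie$g), 0.02)
  # lossless target dissipates nothing
  expect_lt(abs(eff$qabs), 1e-4 * eff$qext)
  # optical theorem and far-field quadrature agree
  expect_lt(abs(eff$qsca - eff$qsca_ot) / eff$qext, 0.01)
  expect_false(eff$quadrature_warning)
})

test_that("dimensionless scaling leaves efficiencies unchanged", {
  lat1 <- voxelize_sphere(0.5, 0.08)
  lat2 <- voxelize_sphere(5, 0.8)
  s <- 10
  f1 <- solve_dipole_system(dipole_system(lat1, 1.08 + 0.01i, k = 3))
  f2 <- solve_dipole_system(dipole_system(lat2, 1.08 + 0.01i, k = 3 / s))
  e1 <- efficiencies(f1)
  e2 <- efficiencies(f2)
  expect_lt(rel_err(e2$qext, e1$qext), 1e-6)
  expect_lt(rel_err(e2$qsca, e1$qsca), 1e-6)
  expect_lt(abs(e2$g - e1$g), 1e-6)
})

test_that("face-on illumination of the cell is polarization invariant", {
  lat <- orient_lattice(voxelize_cell(biconcave_params(), 0.35), "x")
  st <- blood_state(0.5, 0, 0.68, "PBS")
  ri <- relative_index(st, 1000)
  f1 <- solve_dipole_system(dipole_system(lat, ri$m_rel, ri$k_um,
                                          e0 = c(0, 1, 0)))
  f2 <- solve_dipole_system(dipole_system(lat, ri$m_rel, ri$k_um,
                                          e0 = c(0, 0, 1)))
  e1 <- efficiencies(f1)
  e2 <- efficiencies(f2)
  expect_lt(rel_err(e1$qext, e2$qext), 1e-6)
  expect_lt(rel_err(e1$qsca, e2$qsca), 1e-4)
})

test_that("angular pattern integrates back to the scattering efficiency", {
  fx <- small_sphere_fit()
  eff <- efficiencies(fx$fit, aeff = 1)
  # second orthogonal polarization completes the unpolarized pattern, which
  # for a sphere is azimuth independent: qsca = 4 int S11 dmu / aeff^2 with
  # the package's S11 normalization
  sys2 <- dipole_system(fx$lat, 1.05 + 0i, k = 1, e0 = c(0, 0, 1))
  fit2 <- solve_dipole_system(sys2)
  th <- seq(0, 180, by = 0.25)
  pat <- s11_pattern(fx$fit, fit2, "xy", th)
  mu <- cos(th * pi / 180)
  qsca_from_s11 <- -4 * pracma::trapz(mu, pat$s11) / 1^2
  expect_lt(rel_err(qsca_from_s11, eff$qsca), 0.02)
  expect_error(s11_pattern(fx$fit, fit2, "xy", c(-5, 10)), "theta")
})

test_that("orientation averaging is a no-op for spheres and validates n", {
  lat <- voxelize_sphere(0.4, 0.1)
  m <- 1.1 + 0.02i
  res <- orientation_average(lat, m, k = 2, n_orient = 8L)
  expect_equal(res$n_orient, 8L)
  # lattice spheres are rotation invariant up to discretization
  expect_lt(diff(range(res$per_orientation$qext)) / res$qext, 0.01)
  expect_lt(diff(range(res$per_orientation$g)), 0.01)
  single <- efficiencies(solve_dipole_system(dipole_system(lat, m, 2)))
  expect_lt(rel_err(res$qext, single$qext), 0.01)
  expect_error(orientation_average(lat, m, 2, n_orient = 100L),
               "perfect cube")
  expect_equal(formals(orientation_average)$n_orient, 125L)
})

test_that("a cell in a lysing medium loses scattering contrast", {
  # index matching with the hemoglobin-loaded medium lowers Qsca; the
  # near-infrared absorption ordering 905 > 1000 > 700 follows the
  # intracellular imaginary index
  lat <- orient_lattice(voxelize_cell(biconcave_params(), 0.25), "x")
  qabs <- qsca <- matrix(NA_real_, 2L, 3L,
                         dimnames = list(c("ll0", "ll30"),
                                         c("700", "905", "1000")))
  for (ll in c(0, 0.30)) {
    for (lam in c(700, 905, 1000)) {
      st <- blood_state(0.5, ll, 0.68, "PBS")
      ri <- relative_index(st, lam)
      fit <- solve_dipole_system(dipole_system(lat, ri$m_rel, ri$k_um))
      eff <- efficiencies(fit, aeff = lat$aeff, n_theta = 64L, n_phi = 96L)
      row <- if (ll == 0) "ll0" else "ll30"
      qabs[row, as.character(lam)] <- eff$qabs
      qsca[row, as.character(lam)] <- eff$qsca
    }
  }
  expect_true(all(qabs[, "905"] > qabs[, "1000"]))
  expect_true(all(qabs[, "1000"] > qabs[, "700"]))
  expect_true(all(qabs["ll30", ] < qabs["ll0", ]))
  expect_true(all(qsca["ll30", ] < qsca["ll0", ]))
})

test_that("forward-peaked scattering of a resolved cell gives g above 0.9", {
  lat <- orient_lattice(voxelize_cell(biconcave_params(), 0.2), "x")
  st <- blood_state(0.5, 0, 0.68, "PBS")
  ri <- relative_index(st, 1000)
  fit <- solve_dipole_system(dipole_system(lat, ri$m_rel, ri$k_um))
  expect_gt(asymmetry_g(fit), 0.9)
})
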