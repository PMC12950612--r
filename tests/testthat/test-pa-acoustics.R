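# Acoustic forward stage: grids, propagators, transducer, noise.

test_that("the CFL relation fixes the time step", {
  g <- acoustic_grid()  # reference settings: cfl 0.3, dx 0.005 cm, c 1500
  expect_equal(g$dt, 1e-8)
  g2 <- acoustic_grid(dims = c(64, 64, 64), dx = 0.01, pml_thickness = 0.08)
  expect_equal(g2$dt, 2e-8)
  expect_error(acoustic_grid(cfl = 1.5), "CFL")
  expect_error(acoustic_grid(dims = c(16, 16, 16), pml_thickness = 0.10),
               "PML does not fit")
})

test_that("the focused-cap sensor reproduces the reference point count", {
  sens <- transducer_spec(acoustic_grid())
  expect_equal(sens$n_points, 317L)
  expect_equal(sens$focal_length, 0.8)
  # cap points sit on the sphere around the focus, within the aperture
  d <- sqrt(rowSums(sweep(sens$points, 2L, c(120, 120, 100) * 0.005)^2))
  expect_true(all(abs(d - 0.8) <= 0.005 / 2))
  expect_error(transducer_spec(acoustic_grid(), focus = c(120, 120, 400)),
               "focus")
})

test_that("initial pressure is linear in fluence and registered at the focus", {
  fl <- structure(list(values = array(2, c(4, 4, 4)), dims = c(4L, 4L, 4L),
                       dx = 0.01, audit = c(deposited = 1), n_photons = 1,
                       seed = 1), class = "fluence_map")
  g <- acoustic_grid(dims = c(16, 16, 16), dx = 0.01, pml_thickness = 0.02)
  med <- acoustic_medium(grueneisen = 1)
  p0 <- initial_pressure(fl, 3, med, g, focus = c(8, 8, 8))
  expect_equal(sum(p0 != 0), 64L)
  expect_equal(max(p0), 6)
  # doubling fluence doubles p0; zero Grueneisen kills it
  fl2 <- fl; fl2$values <- fl$values * 2
  expect_equal(initial_pressure(fl2, 3, med, g, c(8, 8, 8)), 2 * p0)
  med0 <- acoustic_medium(grueneisen = 0)
  expect_true(all(initial_pressure(fl, 3, med0, g, c(8, 8, 8)) == 0))
  expect_error(initial_pressure(fl, array(1, c(3, 3, 3)), med, g, c(8, 8, 8)),
               "congruent")
})

test_that("spectral propagation matches the analytic spherical wave", {
  dx <- 0.01
  grid <- acoustic_grid(dims = c(64, 64, 64), dx = dx, pml_thickness = 0.06)
  x <- (0:63) * dx
  ctr <- 32 * dx
  r2 <- outer(outer((x - ctr)^2, (x - ctr)^2, "+"), (x - ctr)^2, "+")
  sigma <- 3 * dx
  p0 <- exp(-r2 / (2 * sigma^2))
  sensor <- point_sensor(c(32, 32, 57) * dx)
  nt <- 260
  tr <- kspace_propagate(p0, grid, sensor, nt, method = "spectral",
                         dt_record = 1e-8)
  tt <- (0:(nt - 1)) * 1e-8
  R <- 25 * dx
  ana <- gaussian_ball_wave(R, sigma, tt, 1.5e5)
  expect_lt(sqrt(sum((tr[, 1L] - ana)^2) / sum(ana^2)), 0.05)
  # arrival: the wave's zero crossing sits at R/c within a sample or two
  i0 <- which(diff(sign(tr[, 1L])) != 0)
  i0 <- i0[which.min(abs(tt[i0] - R / 1.5e5))]
  expect_lt(abs(tt[i0] - R / 1.5e5), 2.5e-8)
  # and no wrap artifact re-enters the recorded window (padding contract)
  late <- max(abs(tr[tt > (R + 4 * sigma) / 1.5e5, 1L]))
  expect_lt(late / max(abs(tr)), 10^(-40 / 20))
})

test_that("stepping propagator agrees with the exact spectral evolution", {
  dx <- 0.01
  grid <- acoustic_grid(dims = c(64, 64, 64), dx = dx, pml_thickness = 0.06)
  x <- (0:63) * dx
  ctr <- 32 * dx
  r2 <- outer(outer((x - ctr)^2, (x - ctr)^2, "+"), (x - ctr)^2, "+")
  sigma <- 3 * dx
  p0 <- exp(-r2 / (2 * sigma^2))
  sensor <- point_sensor(c(32, 32, 50) * dx)
  nt <- 120  # window closed before boundary interactions return
  tr_st <- kspace_propagate(p0, grid, sensor, nt, method = "stepping")
  tr_sp <- kspace_propagate(p0, grid, sensor, nt, method = "spectral",
                            dt_record = grid$dt)
  tt <- (0:(nt - 1)) * grid$dt
  R <- 18 * dx
  keep <- tt * 1.5e5 <= R + 4 * sigma
  expect_lt(sqrt(sum((tr_st[keep, 1L] - tr_sp[keep, 1L])^2) /
                   sum(tr_sp[keep, 1L]^2)), 0.05)
  ana <- gaussian_ball_wave(R, sigma, tt, 1.5e5)
  expect_lt(sqrt(sum((tr_st[keep, 1L] - ana[keep])^2) / sum(ana[keep]^2)),
            0.05)
})

test_that("mirror-symmetric sensors record identical traces", {
  dx <- 0.01
  grid <- acoustic_grid(dims = c(48, 48, 48), dx = dx, pml_thickness = 0.04)
  x <- (0:47) * dx
  ctr <- 24 * dx
  r2 <- outer(outer((x - ctr)^2, (x - ctr)^2, "+"), (x - ctr)^2, "+")
  p0 <- exp(-r2 / (2 * (2 * dx)^2))
  sensor <- point_sensor(rbind(c(10, 24, 24) * dx, c(38, 24, 24) * dx))
  tr <- kspace_propagate(p0, grid, sensor, 100, method = "spectral",
                         dt_record = grid$dt)
  expect_lt(max(abs(tr[, 1L] - tr[, 2L])) / max(abs(tr)), 1e-6)
})

test_that("end-to-end pressure scaling is exactly linear before noise", {
  dx <- 0.01
  grid <- acoustic_grid(dims = c(32, 32, 32), dx = dx, pml_thickness = 0.03)
  p0 <- array(0, c(32, 32, 32))
  p0[14:18, 14:18, 14:18] <- 1
  sensor <- point_sensor(c(16, 16, 27) * dx)
  tr1 <- kspace_propagate(p0, grid, sensor, 80, method = "spectral",
                          dt_record = grid$dt)
  tr2 <- kspace_propagate(3 * p0, grid, sensor, 80, method = "spectral",
                          dt_record = grid$dt)
  expect_equal(tr2, 3 * tr1, tolerance = 1e-12)
})

test_that("transducer band-pass is centered and rejects DC", {
  sens <- transducer_spec(acoustic_grid())
  dt <- 1e-8
  n <- 1024L
  mk <- function(v) matrix(rep(v, sens$n_points), ncol = sens$n_points)
  # DC input: stop-band rejection beyond 40 dB
  rf_dc <- apply_transducer(mk(rep(1, n)), sens, dt)
  expect_lt(max(abs(rf_dc$samples)), sens$n_points * 10^(-40 / 20))
  # the 5 MHz tone passes with the highest gain among 1/5/10 MHz
  tt <- (0:(n - 1)) * dt
  gains <- vapply(c(1e6, 5e6, 10e6), function(f) {
    rf <- apply_transducer(mk(sin(2 * pi * f * tt)), sens, dt)
    max(abs(rf$samples)) }, numeric(1L))
  expect_true(which.max(gains) == 2L)
  # white noise emerges band-limited around the center frequency
  # (mean power spectrum over realizations; a single draw is too ragged)
  set.seed(1)
  spec <- rowMeans(vapply(1:30, function(i) {
    rf_wn <- apply_transducer(mk(stats::rnorm(n)), sens, dt)
    Mod(stats::fft(rf_wn$samples))[1:(n / 2)]^2
  }, numeric(n / 2)))
  fgrid <- (0:(n / 2 - 1)) / (n * dt)
  expect_lt(abs(fgrid[which.max(spec)] - 5e6), 0.5e6)
})

test_that("additive noise hits the requested SNR and reproduces under seed", {
  tt <- (0:999) * 1e-8
  rf <- rf_signal(sin(2 * pi * 5e6 * tt), 1e-8)
  snrs <- vapply(1:100, function(s) {
    noisy <- add_noise(rf, 40, seed = s)
    10 * log10(mean(rf$samples^2) / mean((noisy$samples - rf$samples)^2))
  }, numeric(1L))
  expect_lt(abs(mean(snrs) - 40), 0.5)
  n1 <- add_noise(rf, 40, seed = 7)
  n2 <- add_noise(rf, 40, seed = 7)
  expect_identical(n1$samples, n2$samples)
  expect_identical(add_noise(rf, Inf)$samples, rf$samples)
  expect_error(add_noise(rf_signal(rep(0, 10), 1e-8), 40), "zero signal")
})

test_that("acoustic energy does not grow after source release", {
  # total (potential + kinetic) field energy under the stepping scheme with
  # the absorbing layer must be non-increasing up to start-up rounding
  dx <- 0.01
  grid <- acoustic_grid(dims = c(40, 40, 40), dx = dx, pml_thickness = 0.06)
  x <- (0:39) * dx
  ctr <- 20 * dx
  r2 <- outer(outer((x - ctr)^2, (x - ctr)^2, "+"), (x - ctr)^2, "+")
  p0 <- exp(-r2 / (2 * (2 * dx)^2))
  sensor <- point_sensor(c(20, 20, 30) * dx)
  tr <- kspace_propagate(p0, grid, sensor, 150, method = "stepping")
  en <- attr(tr, "energy")
  expect_false(is.null(en))
  # kinetic and potential parts are sampled half a step apart, so the
  # discrete energy wobbles at the few-percent level within a period; the
  # envelope must never exceed the initial energy and must decay into the
  # absorbing layer
  expect_lte(max(en), en[1L] * 1.03)
  expect_true(all(diff(en) <= 0.03 * en[1L]))
  expect_lt(en[length(en)], 0.05 * en[1L])
})

test_that("rf signals round-trip through columnar text", {
  rf <- rf_signal(sin(seq(0, 10, length.out = 200)), 2e-8,
                  metadata = list(lambda_nm = 700))
  path <- tempfile(fileext = ".csv")
  write_rf_csv(rf, path)
  back <- read_rf(path)
  expect_equal(back$samples, rf$samples, tolerance = 1e-12)
  expect_equal(back$dt, rf$dt, tolerance = 1e-12)
})
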