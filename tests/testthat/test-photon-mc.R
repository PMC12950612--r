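# Voxel Monte Carlo photon transport.

test_that("grids are built and validated from bulk optics", {
  b <- bulk_optics(700, 5.203, 1017.2, 0.991)
  g <- build_grid(b, dims = c(10, 10, 10), dx = 0.005)
  expect_true(all(g$mua == 5.203))
  expect_true(all(g$mus == 1017.2))
  expect_true(all(g$g == 0.991))
  # degenerate single-voxel grid is legal; bad inputs are not
  expect_s3_class(build_grid(b, dims = c(1, 1, 1)), "voxel_grid")
  expect_error(build_grid(b, dims = c(4, 4, 4), dx = 0), "dx")
  expect_error(build_grid(mua = -1, mus = 0, g = 0, dims = c(2, 2, 2)),
               "non-negative")
  expect_error(bulk_optics(700, 1, 1, 2), "g")
})

test_that("absorption perturbation alters the exact voxel count within bounds", {
  b <- bulk_optics(700, 5.203, 1017.2, 0.991)
  g <- build_grid(b, dims = c(50, 50, 50), dx = 0.005)
  g0 <- perturb_mua(g, fraction = 0)
  expect_identical(g0$mua, g$mua)
  gp <- perturb_mua(g, fraction = 0.10, amplitude = 0.01, seed = 11)
  changed <- which(gp$mua != g$mua)
  expect_equal(length(changed), round(0.10 * 50^3))
  ratio <- gp$mua[changed] / g$mua[changed]
  expect_true(all(ratio >= 0.99 & ratio <= 1.01))
  gp2 <- perturb_mua(g, fraction = 0.10, amplitude = 0.01, seed = 11)
  expect_identical(gp$mua, gp2$mua)
})

test_that("pure absorber reproduces Beer-Lambert decay with depth", {
  g <- build_grid(mua = 5, mus = 0, g = 0, dims = c(40, 40, 60), dx = 0.01,
                  n_medium = 1.0)
  bm <- beam(0.35)
  fl <- run_photons(g, bm, n_photons = 2e5, seed = 7, specular = FALSE,
                    top_fresnel = FALSE)
  prof <- apply(fl$values[11:30, 11:30, ], 3L, mean)
  z <- ((1:60) - 0.5) * 0.01
  area <- pi * (bm$diameter / 2)^2
  expected <- exp(-5 * z) / area
  sel <- z <= 3 / 5  # three mean free paths
  rms_rel <- sqrt(mean(((prof[sel] - expected[sel]) / expected[sel])^2))
  expect_lt(rms_rel, 0.05)
})

test_that("weight is conserved exactly by the transport ledger", {
  st <- blood_state(0.5, 0, 0.68, "PBS")
  g <- build_grid(tabulated_bulk_optics(st, 700), dims = c(30, 30, 30),
                  dx = 0.01, n_medium = 1.33)
  fl <- run_photons(g, beam(0.10), n_photons = 2e4, seed = 5)
  expect_equal(unname(sum(fl$audit)), 2e4, tolerance = 1e-12)
  # with roulette disabled the plain ledger closes without the net term
  fl2 <- run_photons(g, beam(0.10), n_photons = 5e3, seed = 5,
                     roulette_m = 1)
  expect_equal(unname(fl2$audit[["roulette_net"]]) +
                 unname(fl2$audit[["deposited"]]) +
                 unname(fl2$audit[["escaped_top"]]) +
                 unname(fl2$audit[["escaped_other"]]) +
                 unname(fl2$audit[["specular"]]), 5e3, tolerance = 1e-12)
})

test_that("identical seeds reproduce the fluence map bit for bit", {
  st <- blood_state(0.5, 0.14, 0.68, "PBS")
  g <- build_grid(tabulated_bulk_optics(st, 905), dims = c(20, 20, 20),
                  dx = 0.01)
  f1 <- run_photons(g, beam(0.10), 5e3, seed = 42)
  f2 <- run_photons(g, beam(0.10), 5e3, seed = 42)
  expect_identical(f1$values, f2$values)
  f3 <- run_photons(g, beam(0.10), 5e3, seed = 43)
  expect_false(identical(f1$values, f3$values))
})

test_that("fluence noise shrinks as one over the square root of n", {
  g <- build_grid(mua = 2, mus = 20, g = 0.9, dims = c(20, 20, 20),
                  dx = 0.01, n_medium = 1.0)
  se_at <- function(n, seeds) {
    v <- vapply(seeds, function(s)
      run_photons(g, beam(0.1), n, seed = s)$values[10, 10, 5], numeric(1L))
    stats::sd(v)
  }
  se1 <- se_at(1000, 1:16)
  se2 <- se_at(9000, 101:116)
  expect_gt(se1 / se2, 1.7)  # ideal ratio 3 under 1/sqrt(n) scaling
  expect_lt(se1 / se2, 5.5)
})

test_that("raising absorption monotonically cuts transmitted weight", {
  escaped <- vapply(c(1, 4, 10), function(mua) {
    g <- build_grid(mua = mua, mus = 50, g = 0.9, dims = c(20, 20, 20),
                    dx = 0.01, n_medium = 1.0)
    fl <- run_photons(g, beam(0.1), 2e4, seed = 3, specular = FALSE,
                      top_fresnel = FALSE)
    unname(fl$audit[["escaped_other"]])
  }, numeric(1L))
  expect_true(all(diff(escaped) < 0))
})

test_that("Henyey-Greenstein sampling has the right moments and symmetry", {
  # isotropic limit: uniform cosine distribution
  x0 <- hg_sample(0, 1e5, seed = 1)
  expect_gt(suppressWarnings(stats::ks.test(x0, "punif", -1, 1))$p.value, 0.01)
  # first moment equals g at the tabulated blood anisotropy
  x <- hg_sample(0.991, 1e6, seed = 2)
  expect_lt(abs(mean(x) - 0.991), 3 * stats::sd(x) / sqrt(1e6))
  # mirror symmetry between +g and -g
  xm <- hg_sample(-0.5, 5e4, seed = 3)
  xp <- hg_sample(0.5, 5e4, seed = 4)
  expect_gt(suppressWarnings(stats::ks.test(xm, -xp))$p.value, 0.01)
  # degenerate limits
  expect_equal(hg_sample(1, 5), rep(1, 5))
  expect_equal(hg_sample(-1, 5), rep(-1, 5))
  expect_error(hg_sample(1.5, 10), "g must")
})

test_that("beam wider than the grid and empty attenuation are flagged", {
  g <- build_grid(mua = 1, mus = 1, g = 0, dims = c(10, 10, 10), dx = 0.01)
  expect_error(run_photons(g, beam(0.5), 10), "beam diameter")
  g0 <- build_grid(mua = 0, mus = 0, g = 0, dims = c(10, 10, 10), dx = 0.01)
  expect_warning(run_photons(g0, beam(0.05), 10, seed = 1),
                 "zero total attenuation")
})

test_that("fluence containers serialize with metadata and mid-plane slice", {
  g <- build_grid(mua = 2, mus = 10, g = 0.5, dims = c(12, 12, 12),
                  dx = 0.01, n_medium = 1.0)
  fl <- run_photons(g, beam(0.05), 2e3, seed = 9)
  stem <- tempfile()
  write_fluence(fl, stem)
  expect_true(file.exists(paste0(stem, ".rds")))
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  expect_equal(meta$seed, 9)
  slice <- utils::read.csv(paste0(stem, "_midplane.csv"))
  expect_equal(dim(slice), c(12L, 12L))
})
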