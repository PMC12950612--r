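# Discrete dipole approximation: coupled point dipoles on a cubic lattice.
# The linear system  alpha^-1 P_j + sum_{m != j} A_jm P_m = E_inc,j  is
# solved iteratively with FFT-accelerated matrix-vector products on the
# lattice (dense assembly remains available as the small-system oracle).

#' Per-dipole polarizability
#'
#' Clausius-Mossotti prescription
#' `alpha_CM = (3 d^3 / 4 pi) (m^2 - 1)/(m^2 + 2)` or the lattice dispersion
#' relation (LDR) correction, which adds the O((kd)^2) lattice terms and the
#' radiative-reaction term `-(2/3) i (kd)^3` and reduces to CM as
#' `k d -> 0`.
#'
#' @param m_rel complex relative refractive index (target over host).
#' @param spacing lattice constant, micrometers.
#' @param k host-medium wavenumber, rad/micrometer.
#' @param scheme `"LDR"` (default) or `"CM"`.
#' @param e0 incident polarization unit vector (used by the LDR anisotropy
#'   term); real, length 3.
#' @param a_hat incident propagation unit vector, length 3.
#' @return complex scalar polarizability (micrometers^3).
#' @export
polarizability <- function(m_rel, spacing, k, scheme = c("LDR", "CM"),
                           e0 = c(0, 1, 0), a_hat = c(1, 0, 0)) {
  scheme <- match.arg(scheme)
  stopifnot(spacing > 0)
  m2 <- as.complex(m_rel)^2
  if (Mod(m2 + 2) < 1e-12) stop("resonant denominator: m^2 = -2")
  a_cm <- 3 * spacing^3 / (4 * pi) * (m2 - 1) / (m2 + 2)
  if (scheme == "CM") return(a_cm)
  b1 <- -1.8915316; b2 <- 0.1648469; b3 <- -1.7700004
  S <- sum((a_hat * Re(e0))^2)
  kd <- k * spacing
  corr <- (a_cm / spacing^3) *
    ((b1 + m2 * b2 + m2 * b3 * S) * kd^2 - (2 / 3) * 1i * kd^3)
  a_cm / (1 + corr)
}

#' Assemble a dipole system
#'
#' Bundles a lattice, the optical contrast and the incident plane wave into
#' the container consumed by the solver. A validity note is attached when
#' `|m| k d` exceeds 0.5 (the usual DDA discretization rule of thumb).
#'
#' @param lattice a `dipole_lattice` (see [voxelize_cell()]).
#' @param m_rel complex relative refractive index.
#' @param k host wavenumber, rad/micrometer.
#' @param e0 incident polarization (unit, perpendicular to `a_hat`).
#' @param a_hat propagation direction (unit).
#' @param scheme polarizability prescription, see [polarizability()].
#' @return object of class `dipole_system`.
#' @export
dipole_system <- function(lattice, m_rel, k, e0 = c(0, 1, 0),
                          a_hat = c(1, 0, 0), scheme = "LDR") {
  stopifnot(inherits(lattice, "dipole_lattice"), k > 0)
  if (!is.finite(Mod(as.complex(m_rel)))) stop("m_rel must be finite")
  a_hat <- a_hat / sqrt(sum(a_hat^2))
  if (abs(sqrt(sum(Mod(as.complex(e0))^2)) - 1) > 1e-8) {
    e0 <- e0 / sqrt(sum(Mod(as.complex(e0))^2))
  }
  if (abs(sum(Re(e0) * a_hat)) > 1e-8) {
    stop("incident polarization must be perpendicular to the propagation direction")
  }
  mkd <- Mod(as.complex(m_rel)) * k * lattice$spacing
  alpha <- polarizability(m_rel, lattice$spacing, k, scheme, Re(e0), a_hat)
  pos <- lattice_coordinates(lattice)
  e_inc <- incident_field(pos, k, e0, a_hat)
  out <- list(lattice = lattice, m_rel = as.complex(m_rel), k = k,
              e0 = as.complex(e0), a_hat = a_hat, alpha = alpha,
              scheme = scheme, positions = pos, e_inc = e_inc,
              mkd = mkd, valid = mkd < 0.5)
  class(out) <- "dipole_system"
  out
}

incident_field <- function(positions, k, e0, a_hat) {
  phase <- exp(1i * k * drop(positions %*% a_hat))
  outer(phase, as.complex(e0))
}

#' @export
print.dipole_system <- function(x, ...) {
  cat(sprintf(
    "dipole_system: N = %d, m_rel = %.4g%+.4gi, |m|kd = %.3f%s\n",
    x$lattice$n_dipoles, Re(x$m_rel), Im(x$m_rel), x$mkd,
    if (x$valid) "" else " (above the 0.5 validity threshold)"))
  invisible(x)
}

# 3x3 dipole interaction tensor A(s) for separation vector s (|s| > 0):
# A_ab = e^{ikr}/r^3 [ k^2 (s_a s_b - r^2 d_ab) + (1 - ikr)(d_ab - 3 s_a s_b / r^2) ]
interaction_tensor_grids <- function(nx, ny, nz, px, py, pz, spacing, k) {
  ox <- c(0:(nx - 1L), rep(0L, px - 2L * nx + 1L), -((nx - 1L):1L))
  oy <- c(0:(ny - 1L), rep(0L, py - 2L * ny + 1L), -((ny - 1L):1L))
  oz <- c(0:(nz - 1L), rep(0L, pz - 2L * nz + 1L), -((nz - 1L):1L))
  live_x <- c(rep(TRUE, nx), rep(FALSE, px - 2L * nx + 1L), rep(TRUE, nx - 1L))
  live_y <- c(rep(TRUE, ny), rep(FALSE, py - 2L * ny + 1L), rep(TRUE, ny - 1L))
  live_z <- c(rep(TRUE, nz), rep(FALSE, pz - 2L * nz + 1L), rep(TRUE, nz - 1L))
  sx <- array(ox * spacing, dim = c(px, py, pz))
  sy <- array(rep(oy * spacing, each = px), dim = c(px, py, pz))
  sz <- array(rep(oz * spacing, each = px * py), dim = c(px, py, pz))
  live <- array(live_x, dim = c(px, py, pz)) &
    array(rep(live_y, each = px), dim = c(px, py, pz)) &
    array(rep(live_z, each = px * py), dim = c(px, py, pz))
  r2 <- sx^2 + sy^2 + sz^2
  live[1L, 1L, 1L] <- FALSE  # self term handled by alpha^-1
  r <- sqrt(r2)
  C <- array(0i, dim = c(px, py, pz))
  C[live] <- exp(1i * k * r[live]) / r[live]^3
  t1 <- array(0i, dim = c(px, py, pz))
  t1[live] <- (1 - 1i * k * r[live]) / r2[live]
  comps <- list()
  pairs <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  svec <- list(sx, sy, sz)
  for (p in seq_along(pairs)) {
    a <- pairs[[p]][1L]; b <- pairs[[p]][2L]
    ss <- svec[[a]] * svec[[b]]
    del <- if (a == b) 1 else 0
    G <- C * (k^2 * (ss - r2 * del) + t1 * (r2 * del - 3 * ss))
    comps[[p]] <- fft(G)
  }
  names(comps) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  comps
}

# FFT-convolution operator: y = alpha^-1 P + sum_m A_jm P_m
dda_operator <- function(sys) {
  lat <- sys$lattice
  sites <- lat$sites
  mins <- apply(sites, 2L, min)
  nx <- max(sites[, 1L]) - mins[1L] + 1L
  ny <- max(sites[, 2L]) - mins[2L] + 1L
  nz <- max(sites[, 3L]) - mins[3L] + 1L
  px <- stats::nextn(2L * nx); py <- stats::nextn(2L * ny)
  pz <- stats::nextn(2L * nz)
  Ghat <- interaction_tensor_grids(nx, ny, nz, px, py, pz, lat$spacing, sys$k)
  lin <- 1L + (sites[, 1L] - mins[1L]) +
    px * ((sites[, 2L] - mins[2L]) + py * (sites[, 3L] - mins[3L]))
  npad <- px * py * pz
  inv_alpha <- 1 / sys$alpha
  grid_dim <- c(px, py, pz)
  idx <- c("xx", "xy", "xz", "xy", "yy", "yz", "xz", "yz", "zz")
  dim(idx) <- c(3L, 3L)
  function(P) {
    Fh <- vector("list", 3L)
    for (a in 1:3) {
      X <- array(0i, dim = grid_dim)
      X[lin] <- P[, a]
      Fh[[a]] <- fft(X)
    }
    out <- matrix(0i, nrow = nrow(P), ncol = 3L)
    for (b in 1:3) {
      Y <- Ghat[[idx[b, 1L]]] * Fh[[1L]] +
        Ghat[[idx[b, 2L]]] * Fh[[2L]] +
        Ghat[[idx[b, 3L]]] * Fh[[3L]]
      y <- fft(Y, inverse = TRUE) / npad
      out[, b] <- y[lin]
    }
    out + inv_alpha * P
  }
}

#' Dense interaction matrix (small-system oracle)
#'
#' Assembles the full 3N x 3N complex matrix of the dipole system. Intended
#' for N <= 500 as the independent check of the FFT-accelerated solver.
#'
#' @param sys a [dipole_system()].
#' @return complex matrix of dimension 3N x 3N.
#' @export
dda_dense_matrix <- function(sys) {
  pos <- sys$positions
  n <- nrow(pos)
  if (n > 500L) stop("dense assembly is restricted to N <= 500")
  k <- sys$k
  A <- matrix(0i, 3L * n, 3L * n)
  for (j in seq_len(n)) {
    for (m in seq_len(n)) {
      rows <- (3L * (j - 1L) + 1L):(3L * j)
      cols <- (3L * (m - 1L) + 1L):(3L * m)
      if (j == m) {
        A[rows, cols] <- diag(3L) / sys$alpha
      } else {
        s <- pos[j, ] - pos[m, ]
        r2 <- sum(s^2); r <- sqrt(r2)
        C <- exp(1i * k * r) / r^3
        ss <- outer(s, s)
        A[rows, cols] <- C * (k^2 * (ss - r2 * diag(3L)) +
                                (1 - 1i * k * r) / r2 * (r2 * diag(3L) - 3 * ss))
      }
    }
  }
  A
}

#' Solve the coupled dipole system
#'
#' BiCGSTAB iteration on `alpha^-1 P + sum A P = E_inc` with FFT-accelerated
#' products (identical to the dense product within solver tolerance). The
#' returned polarizations satisfy a relative residual
#' `||A P - E_inc|| / ||E_inc|| <= tol`.
#'
#' @param sys a [dipole_system()].
#' @param tol relative residual tolerance (default 1e-5).
#' @param max_iter maximum iterations (default 1000).
#' @param dense force the dense direct solve (N <= 500).
#' @return object of class `dda_fit`: fields `P` (N x 3 complex), `sys`,
#'   `n_iter`, `residual`.
#' @export
solve_dipole_system <- function(sys, tol = 1e-5, max_iter = 1000L,
                                dense = FALSE) {
  stopifnot(inherits(sys, "dipole_system"))
  n <- nrow(sys$positions)
  b <- sys$e_inc
  if (dense || n == 1L) {
    if (n == 1L) {
      P <- sys$alpha * b
      res <- 0; it <- 0L
    } else {
      A <- dda_dense_matrix(sys)
      x <- solve(A, as.vector(t(b)))
      P <- matrix(x, ncol = 3L, byrow = TRUE)
      res <- 0; it <- 0L
    }
  } else {
    op <- dda_operator(sys)
    cdot <- function(u, v) sum(Conj(u) * v)
    nb <- sqrt(Re(cdot(b, b)))
    x <- sys$alpha * b  # non-interacting start
    r <- b - op(x)
    r0 <- r
    rho <- alpha_s <- omega <- 1 + 0i
    v <- p <- matrix(0i, n, 3L)
    it <- 0L
    res <- sqrt(Re(cdot(r, r))) / nb
    while (res > tol && it < max_iter) {
      rho_new <- cdot(r0, r)
      if (Mod(rho_new) < 1e-300) break
      beta <- (rho_new / rho) * (alpha_s / omega)
      p <- r + beta * (p - omega * v)
      v <- op(p)
      alpha_s <- rho_new / cdot(r0, v)
      s <- r - alpha_s * v
      t <- op(s)
      omega <- cdot(t, s) / cdot(t, t)
      x <- x + alpha_s * p + omega * s
      r <- s - omega * t
      rho <- rho_new
      it <- it + 1L
      res <- sqrt(Re(cdot(r, r))) / nb
    }
    # residual via a fresh product (guards against drift in the recurrence)
    res <- sqrt(Re(cdot(b - op(x), b - op(x)))) / nb
    if (res > tol) {
      cond <- structure(class = c("dda_no_convergence", "error", "condition"),
                        list(message = sprintf(
                          "dipole solver did not converge: residual %.3g > tol %.3g after %d iterations",
                          res, tol, it), call = sys.call(), residual = res))
      stop(cond)
    }
    P <- x
  }
  out <- list(P = P, sys = sys, n_iter = it, residual = res)
  class(out) <- "dda_fit"
  out
}

# Product Gauss-Legendre (cos theta) x uniform (phi) far-field quadrature in
# the frame of the propagation direction.
farfield_quadrature <- function(a_hat, n_theta = 64L, n_phi = 96L) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  ct <- gl$x; wt <- gl$w
  phi <- 2 * pi * (seq_len(n_phi) - 0.5) / n_phi
  wphi <- 2 * pi / n_phi
  # orthonormal frame around a_hat
  ref <- if (abs(a_hat[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * a_hat) * a_hat
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a_hat[2L] * e1[3L] - a_hat[3L] * e1[2L],
          a_hat[3L] * e1[1L] - a_hat[1L] * e1[3L],
          a_hat[1L] * e1[2L] - a_hat[2L] * e1[1L])
  st <- sqrt(pmax(0, 1 - ct^2))
  dirs <- matrix(0, n_theta * n_phi, 3L)
  w <- numeric(n_theta * n_phi)
  mu <- numeric(n_theta * n_phi)
  row <- 1L
  for (i in seq_len(n_theta)) {
    for (j in seq_len(n_phi)) {
      dirs[row, ] <- ct[i] * a_hat + st[i] * (cos(phi[j]) * e1 +
                                                sin(phi[j]) * e2)
      w[row] <- wt[i] * wphi
      mu[row] <- ct[i]
      row <- row + 1L
    }
  }
  list(dirs = dirs, w = w, mu = mu)
}

farfield_intensity <- function(fit, dirs) {
  sys <- fit$sys
  V <- cpp_farfield_sums(sys$lattice$sites, sys$lattice$offset,
                         sys$lattice$spacing, fit$P, sys$k, dirs)
  proj2 <- numeric(nrow(dirs))
  for (d in seq_len(nrow(dirs))) {
    nh <- dirs[d, ]
    v <- V[d, ]
    vt <- v - nh * sum(nh * v)
    proj2[d] <- sum(Mod(vt)^2)
  }
  proj2
}

#' Efficiency factors of a solved dipole system
#'
#' Extinction from the optical theorem, absorption from per-dipole
#' dissipation with the radiative-reaction term, scattering both from the
#' far-field angular integral and as `qext - qabs`. A `quadrature_warning`
#' flag is set when the two scattering routes disagree by more than 5% of
#' qext.
#'
#' @param fit a `dda_fit` from [solve_dipole_system()].
#' @param aeff effective (equal-volume-sphere) radius, micrometers; default
#'   the lattice value.
#' @param n_theta,n_phi far-field quadrature resolution; by default scaled
#'   with the size parameter `x = k aeff` so the forward lobe (angular width
#'   ~ 1/x) stays resolved.
#' @return list `qext`, `qabs`, `qsca` (far-field integral),
#'   `qsca_ot` (= qext - qabs), `g`, `quadrature_warning`.
#' @export
efficiencies <- function(fit, aeff = NULL, n_theta = NULL, n_phi = NULL) {
  stopifnot(inherits(fit, "dda_fit"))
  sys <- fit$sys
  if (is.null(aeff)) aeff <- sys$lattice$aeff
  k <- sys$k
  if (is.null(n_theta)) n_theta <- max(64L, ceiling(6 * k * aeff))
  if (is.null(n_phi)) n_phi <- max(96L, ceiling(2 * k * aeff))
  e02 <- sum(Mod(sys$e0)^2)
  pref <- 4 * k / (aeff^2 * e02)
  qext <- pref * sum(Im(Conj(sys$e_inc) * fit$P))
  inv_a <- 1 / sys$alpha
  qabs <- pref * sum(Im(fit$P * Conj(inv_a * fit$P)) -
                       (2 / 3) * k^3 * Mod(fit$P)^2)
  # Im(P (alpha^-1 P)^*) summed over components
  quad <- farfield_quadrature(sys$a_hat, n_theta, n_phi)
  I <- farfield_intensity(fit, quad$dirs)
  qsca <- k^4 / (pi * aeff^2 * e02) * sum(quad$w * I)
  g <- if (qsca > 0) sum(quad$w * quad$mu * I) / sum(quad$w * I) else NA_real_
  warn <- is.finite(qext) && qext > 0 &&
    abs(qsca - (qext - qabs)) / qext > 0.05
  list(qext = qext, qabs = qabs, qsca = qsca, qsca_ot = qext - qabs,
       g = g, quadrature_warning = warn)
}

#' Asymmetry parameter of a solved dipole system
#'
#' Mean cosine of the scattering angle, `g = <cos theta>`, from the same
#' far-field quadrature that yields the scattering efficiency.
#'
#' @inheritParams efficiencies
#' @return g in \[-1, 1\].
#' @export
asymmetry_g <- function(fit, n_theta = NULL, n_phi = NULL) {
  x <- fit$sys$k * fit$sys$lattice$aeff
  if (is.null(n_theta)) n_theta <- max(64L, ceiling(6 * x))
  if (is.null(n_phi)) n_phi <- max(96L, ceiling(2 * x))
  quad <- farfield_quadrature(fit$sys$a_hat, n_theta, n_phi)
  I <- farfield_intensity(fit, quad$dirs)
  denom <- sum(quad$w * I)
  if (denom <= 0) stop("zero scattered power: asymmetry parameter undefined")
  sum(quad$w * quad$mu * I) / denom
}

#' Angular scattering pattern S11 in a detection plane
#'
#' Unpolarized angular intensity `S11(theta)` obtained by averaging the
#' far-field intensities of two orthogonal incident polarizations, along a
#' detection plane containing the incidence direction (x axis): `"xy"` scans
#' directions `(cos theta, sin theta, 0)`, `"zx"` scans
#' `(cos theta, 0, sin theta)`.
#'
#' @param fit1,fit2 `dda_fit` objects for the two orthogonal incident
#'   polarizations (same lattice and wavenumber, propagation along x).
#' @param plane `"xy"` or `"zx"`.
#' @param theta_deg scattering angles, degrees in \[0, 180\].
#' @return data.frame `theta_deg`, `s11`.
#' @export
s11_pattern <- function(fit1, fit2, plane = c("xy", "zx"),
                        theta_deg = seq(0, 180, by = 1)) {
  plane <- match.arg(plane)
  if (any(theta_deg < 0 | theta_deg > 180)) {
    stop("theta_deg must lie in [0, 180]")
  }
  th <- theta_deg * pi / 180
  dirs <- switch(plane,
                 xy = cbind(cos(th), sin(th), 0),
                 zx = cbind(cos(th), 0, sin(th)))
  k <- fit1$sys$k
  I <- (farfield_intensity(fit1, dirs) + farfield_intensity(fit2, dirs)) / 2
  data.frame(theta_deg = theta_deg, s11 = k^4 * I / 2)
}

#' Orientation-averaged efficiencies
#'
#' Averages efficiency factors and g over a deterministic 3-angle grid:
#' incidence direction uniform in (cos Theta, Phi) and polarization angle
#' beta uniform in \[0, pi), with `n_orient = n^3` (default 5 x 5 x 5 = 125).
#'
#' @param lattice a `dipole_lattice`.
#' @param m_rel complex relative refractive index.
#' @param k host wavenumber, rad/micrometer.
#' @param n_orient number of orientations; must be a perfect cube.
#' @param aeff effective radius override (default lattice aeff).
#' @param tol,max_iter solver settings.
#' @param n_theta,n_phi far-field quadrature resolution.
#' @param scheme polarizability prescription.
#' @return list of mean `qext`, `qabs`, `qsca`, `g`, plus `per_orientation`
#'   data.frame and `n_orient` (class `scattering_result`).
#' @export
orientation_average <- function(lattice, m_rel, k, n_orient = 125L,
                                aeff = NULL, tol = 1e-5, max_iter = 1000L,
                                n_theta = NULL, n_phi = NULL, scheme = "LDR") {
  n1 <- round(n_orient^(1 / 3))
  if (n1^3 != n_orient) stop("n_orient must be a perfect cube (n x n x n grid)")
  ct_grid <- -1 + (2 * seq_len(n1) - 1) / n1
  phi_grid <- 2 * pi * (seq_len(n1) - 0.5) / n1
  beta_grid <- pi * (seq_len(n1) - 0.5) / n1
  rows <- list()
  ri <- 1L
  for (ct in ct_grid) {
    st <- sqrt(max(0, 1 - ct^2))
    for (ph in phi_grid) {
      a_hat <- c(st * cos(ph), st * sin(ph), ct)
      ref <- if (abs(a_hat[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      e1 <- ref - sum(ref * a_hat) * a_hat
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(a_hat[2L] * e1[3L] - a_hat[3L] * e1[2L],
              a_hat[3L] * e1[1L] - a_hat[1L] * e1[3L],
              a_hat[1L] * e1[2L] - a_hat[2L] * e1[1L])
      for (be in beta_grid) {
        e0 <- cos(be) * e1 + sin(be) * e2
        sys <- dipole_system(lattice, m_rel, k, e0 = e0, a_hat = a_hat,
                             scheme = scheme)
        fit <- solve_dipole_system(sys, tol = tol, max_iter = max_iter)
        eff <- efficiencies(fit, aeff = aeff, n_theta = n_theta,
                            n_phi = n_phi)
        rows[[ri]] <- data.frame(cos_theta = ct, phi = ph, beta = be,
                                 qext = eff$qext, qabs = eff$qabs,
                                 qsca = eff$qsca, g = eff$g,
                                 n_iter = fit$n_iter,
                                 residual = fit$residual)
        ri <- ri + 1L
      }
    }
  }
  per <- do.call(rbind, rows)
  out <- list(qext = mean(per$qext), qabs = mean(per$qabs),
              qsca = mean(per$qsca), g = mean(per$g),
              n_orient = n_orient, per_orientation = per)
  class(out) <- "scattering_result"
  out
}

#' @export
print.scattering_result <- function(x, ...) {
  cat(sprintf(
    "scattering_result (%d orientations): qext = %.4g, qabs = %.4g, qsca = %.4g, g = %.4g\n",
    x$n_orient, x$qext, x$qabs, x$qsca, x$g))
  invisible(x)
}

#' Relative refractive index and host wavenumber of a blood state
#'
#' Convenience wrapper: runs the optics chain and forms
#' `m_rel = (nr_RBC + i ni_RBC) / (nr_LM + i ni_LM)` and the (transparent
#' host approximation) wavenumber `k = 2 pi nr_LM / lambda`.
#'
#' @param state a [blood_state()].
#' @param lambda_nm wavelength, nm.
#' @param table a [chromophore_table()].
#' @return list `m_rel` (complex), `k_um` (rad/micrometer), `optics` (the
#'   [blood_optics()] result).
#' @export
relative_index <- function(state, lambda_nm, table = chromophore_table()) {
  opt <- blood_optics(state, lambda_nm, table)
  m_cell <- complex(real = opt$nr_rbc, imaginary = opt$ni_rbc)
  m_host <- complex(real = opt$medium$nr_lm, imaginary = opt$medium$ni_lm)
  lambda_um <- lambda_nm / 1e3
  list(m_rel = m_cell / m_host,
       k_um = 2 * pi * opt$medium$nr_lm / lambda_um,
       optics = opt)
}

#' Rotate a lattice so its symmetry axis points along a coordinate axis
#'
#' The voxelized cell has its symmetry axis along z. Axis permutations are
#' exact lattice symmetries, so face-on/edge-on orientations with respect to
#' an x-propagating beam are obtained by permuting site coordinates.
#'
#' @param lattice a `dipole_lattice`.
#' @param axis `"x"`, `"y"` or `"z"`: where the symmetry axis should point.
#' @return a `dipole_lattice`.
#' @export
orient_lattice <- function(lattice, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  perm <- switch(axis, x = c(3L, 2L, 1L), y = c(1L, 3L, 2L), z = 1:3)
  out <- lattice
  out$sites <- lattice$sites[, perm, drop = FALSE]
  out
}
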