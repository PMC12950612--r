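#' Mie efficiencies for a homogeneous sphere
#'
#' Lorenz-Mie series for a sphere of relative refractive index `m_rel`
#' (possibly complex, target over host) and size parameter
#' `x = 2 pi a / lambda_host`. Used as the independent oracle for the dipole
#' solver on spherical targets. Series length `ceiling(x + 4 x^(1/3) + 2)`;
#' the logarithmic derivative is computed by downward recurrence.
#'
#' @param m_rel complex relative refractive index.
#' @param x size parameter (> 0).
#' @return named list `qext`, `qsca`, `qabs` (= qext - qsca), `g`.
#' @examples
#' mie_efficiencies(1.33 + 0i, 5)
#' @export
mie_efficiencies <- function(m_rel, x) {
  stopifnot(is.numeric(x), length(x) == 1L, x > 0)
  m <- as.complex(m_rel)
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  mx <- m * x

  # logarithmic derivative D_n(mx) by downward recurrence
  nstart <- nmax + max(15L, ceiling(abs(mx)))
  D <- complex(nstart + 1L)
  for (n in seq.int(nstart, 1L)) {
    D[n] <- n / mx - 1 / (D[n + 1L] + n / mx)
  }

  # Riccati-Bessel psi, chi by upward recurrence
  n_seq <- seq_len(nmax)
  psi <- numeric(nmax)
  chi <- numeric(nmax)
  psi_m1 <- cos(x)   # psi_{-1} -> psi_0 chain: psi_0 = sin x
  psi_0 <- sin(x)
  chi_m1 <- -sin(x)  # chi_0 = cos x
  chi_0 <- cos(x)
  psi_prev <- psi_m1; psi_cur <- psi_0
  chi_prev <- chi_m1; chi_cur <- chi_0
  for (n in n_seq) {
    psi[n] <- (2 * n - 1) / x * psi_cur - psi_prev
    chi[n] <- (2 * n - 1) / x * chi_cur - chi_prev
    psi_prev <- psi_cur; psi_cur <- psi[n]
    chi_prev <- chi_cur; chi_cur <- chi[n]
  }
  xi <- complex(real = psi, imaginary = -chi)
  psi_nm1 <- c(psi_0, psi[-nmax])          # psi_{n-1}
  xi_nm1 <- complex(real = psi_nm1,
                    imaginary = -c(chi_0, chi[-nmax]))

  Dn <- D[n_seq + 1L]   # D[k + 1] holds D_k
  ta <- Dn / m + n_seq / x
  tb <- Dn * m + n_seq / x
  a <- (ta * psi - psi_nm1) / (ta * xi - xi_nm1)
  b <- (tb * psi - psi_nm1) / (tb * xi - xi_nm1)

  two_n1 <- 2 * n_seq + 1
  qext <- 2 / x^2 * sum(two_n1 * Re(a + b))
  qsca <- 2 / x^2 * sum(two_n1 * (Mod(a)^2 + Mod(b)^2))
  # asymmetry parameter
  g_sum <- 0
  if (nmax > 1L) {
    nn <- n_seq[-nmax]
    g_sum <- sum(nn * (nn + 2) / (nn + 1) *
                   Re(a[nn] * Conj(a[nn + 1L]) + b[nn] * Conj(b[nn + 1L])))
  }
  g_sum <- g_sum + sum(two_n1 / (n_seq * (n_seq + 1)) * Re(a * Conj(b)))
  g <- if (qsca > 0) 4 / x^2 * g_sum / qsca else 0
  list(qext = qext, qsca = qsca, qabs = qext - qsca, g = g)
}
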