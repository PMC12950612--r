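#include <Rcpp.h>
#include <complex>
#include <vector>
using namespace Rcpp;

// Far-field dipole sums for the discrete dipole solver:
//   V(n_hat) = sum_j P_j exp(-i k n_hat . r_j)
// evaluated for many scattering directions. Positions sit on a cubic
// lattice, so the phase factorizes into per-axis tables, avoiding one
// complex exponential per (dipole, direction) pair.

// [[Rcpp::export]]
ComplexMatrix cpp_farfield_sums(IntegerMatrix sites, double offset,
                                double spacing, ComplexMatrix P,
                                double k, NumericMatrix dirs) {
  const int n = sites.nrow();
  const int m = dirs.nrow();
  ComplexMatrix out(m, 3);

  int imin[3], imax[3];
  for (int a = 0; a < 3; ++a) {
    int lo = sites(0, a), hi = sites(0, a);
    for (int j = 1; j < n; ++j) {
      int v = sites(j, a);
      if (v < lo) lo = v;
      if (v > hi) hi = v;
    }
    imin[a] = lo; imax[a] = hi;
  }

  std::vector<std::complex<double> > Pc(3 * (size_t)n);
  for (int a = 0; a < 3; ++a)
    for (int j = 0; j < n; ++j) {
      Rcomplex rc = P(j, a);
      Pc[(size_t)a * n + j] = std::complex<double>(rc.r, rc.i);
    }

  std::vector<std::complex<double> > tab[3];
  for (int a = 0; a < 3; ++a) tab[a].resize(imax[a] - imin[a] + 1);

  for (int d = 0; d < m; ++d) {
    for (int a = 0; a < 3; ++a) {
      double kc = -k * dirs(d, a) * spacing;  // exp(-i k n.r), r=(i+off)*d
      for (int i = imin[a]; i <= imax[a]; ++i) {
        double ph = kc * (i + offset);
        tab[a][i - imin[a]] = std::complex<double>(std::cos(ph), std::sin(ph));
      }
    }
    std::complex<double> s0(0, 0), s1(0, 0), s2(0, 0);
    for (int j = 0; j < n; ++j) {
      std::complex<double> phase =
        tab[0][sites(j, 0) - imin[0]] *
        tab[1][sites(j, 1) - imin[1]] *
        tab[2][sites(j, 2) - imin[2]];
      s0 += Pc[j] * phase;
      s1 += Pc[(size_t)n + j] * phase;
      s2 += Pc[2 * (size_t)n + j] * phase;
    }
    out(d, 0) = Rcomplex{s0.real(), s0.imag()};
    out(d, 1) = Rcomplex{s1.real(), s1.imag()};
    out(d, 2) = Rcomplex{s2.real(), s2.imag()};
  }
  return out;
}
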