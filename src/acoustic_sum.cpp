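#include <Rcpp.h>
#include <complex>
#include <vector>
using namespace Rcpp;

// Sensor-side reduction for the exact k-space propagator in a homogeneous
// medium. The analytic evolution p_hat(k, t) = p_hat0(k) cos(c|k|t) means a
// sensor trace is
//   p(x_s, t) = (1/N) sum_k p_hat0(k) exp(i k . x_s) cos(c |k| t).
// cos(c|k|t) depends on |k| only, so the sum collapses onto |k| bins:
// accumulate A[s, bin] = sum_{k in bin} p_hat0(k) exp(i k . x_s) here, and
// finish with A %*% cos(c kappa_bin t) in R. Phases factorize per axis.

// [[Rcpp::export]]
ComplexMatrix cpp_spectral_sensor_sums(ComplexVector p0hat, IntegerVector dims,
                                       NumericVector kx, NumericVector ky,
                                       NumericVector kz, IntegerVector binidx,
                                       int nbins, NumericMatrix sensor_xyz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ns = sensor_xyz.nrow();
  const size_t N = (size_t)nx * ny * nz;

  std::vector<std::complex<double> > ph(N);
  for (size_t i = 0; i < N; ++i) {
    Rcomplex rc = p0hat[i];
    ph[i] = std::complex<double>(rc.r, rc.i);
  }

  ComplexMatrix out(ns, nbins);
  std::vector<std::complex<double> > acc((size_t)nbins);
  std::vector<std::complex<double> > px(nx), py(ny), pz(nz);

  for (int s = 0; s < ns; ++s) {
    const double xs = sensor_xyz(s, 0), ysv = sensor_xyz(s, 1),
      zs = sensor_xyz(s, 2);
    for (int i = 0; i < nx; ++i)
      px[i] = std::complex<double>(std::cos(kx[i] * xs),
                                   std::sin(kx[i] * xs));
    for (int j = 0; j < ny; ++j)
      py[j] = std::complex<double>(std::cos(ky[j] * ysv),
                                   std::sin(ky[j] * ysv));
    for (int l = 0; l < nz; ++l)
      pz[l] = std::complex<double>(std::cos(kz[l] * zs),
                                   std::sin(kz[l] * zs));
    std::fill(acc.begin(), acc.end(), std::complex<double>(0, 0));
    size_t idx = 0;
    for (int l = 0; l < nz; ++l) {
      for (int j = 0; j < ny; ++j) {
        std::complex<double> pyz = py[j] * pz[l];
        for (int i = 0; i < nx; ++i, ++idx) {
          acc[binidx[idx]] += ph[idx] * (px[i] * pyz);
        }
      }
    }
    for (int b = 0; b < nbins; ++b)
      out(s, b) = Rcomplex{acc[b].real(), acc[b].imag()};
  }
  return out;
}
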