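#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;

// Parratt recursion for specular reflectivity of a micro-sliced SLD profile.
//
// rho:  SLD values (units 1e-6 A^-2) on a uniform grid; rho[0] is the
//       semi-infinite incident medium, rho[n-1] the semi-infinite backing.
// irho: imaginary SLD (absorption), same units/length; usually zero.
// step: slice thickness (A) of the interior layers.
// q:    momentum transfer values (A^-1), measured in the incident medium.
//
// Returns |r|^2 for each q. The recursion runs from the backing towards the
// incident medium. For purely real profiles the layer wavevectors are real
// or purely imaginary, which avoids complex square roots in the hot loop.
// [[Rcpp::export]]
NumericVector abeles_reflectivity(NumericVector q, NumericVector rho,
                                  NumericVector irho, double step) {
  const int nq = q.size();
  const int nl = rho.size();
  NumericVector out(nq);
  if (nl < 2) stop("profile needs at least two points (fronting and backing)");
  const double fourpi = 4.0 * M_PI;
  bool absorbing = false;
  for (int j = 0; j < nl; ++j)
    if (irho[j] != irho[0]) { absorbing = true; break; }
  std::vector<std::complex<double>> k(nl);
  for (int iq = 0; iq < nq; ++iq) {
    const double qv = q[iq];
    const double kz0sq = qv * qv / 4.0;
    if (absorbing) {
      for (int j = 0; j < nl; ++j)
        k[j] = std::sqrt(std::complex<double>(
            kz0sq - fourpi * (rho[j] - rho[0]) * 1e-6,
            -fourpi * (irho[j] - irho[0]) * 1e-6));
    } else {
      for (int j = 0; j < nl; ++j) {
        double ksq = kz0sq - fourpi * (rho[j] - rho[0]) * 1e-6;
        k[j] = (ksq >= 0.0)
                   ? std::complex<double>(std::sqrt(ksq), 0.0)
                   : std::complex<double>(0.0, std::sqrt(-ksq));
      }
    }
    // Parratt recursion from the backing
    std::complex<double> r(0.0, 0.0);
    for (int j = nl - 2; j >= 0; --j) {
      std::complex<double> kj = k[j], kj1 = k[j + 1];
      std::complex<double> rj = (kj - kj1) / (kj + kj1);
      if (j == nl - 2) {
        r = rj;
      } else {
        // phase across layer j+1 (thickness = step)
        std::complex<double> ph = std::exp(std::complex<double>(0.0, 2.0) *
                                           kj1 * step);
        r = (rj + r * ph) / (1.0 + rj * r * ph);
      }
    }
    double R = std::norm(r);
    if (R > 1.0 && !absorbing) R = 1.0; // clamp rounding above total reflection
    out[iq] = R;
  }
  return out;
}
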