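#include <Rcpp.h>
#include <complex>
#include <cmath>

using namespace Rcpp;

// Bistatic SFCW MIMO received-signal model.
//
// For each frame t, tone l, RX element m and TX element n the sample is the
// coherent sum over scatterers of
//   w * exp(-i k_f (Rt + Rr)) / (16 pi^2 Rt Rr),
// with k_f = 2 pi f_l / c0, Rt/Rr the exact Euclidean TX/RX distances and w
// the per-frame scatterer weight (reflectivity times aspect factor).
//
// The per-tone factor is separable in (m, n) and the SFCW tone grid is
// uniform, so the per-element phasors for successive tones follow by one
// complex multiplication (exp(-i k_{l+1} R) = exp(-i k_l R) exp(-i dk R)),
// leaving only 2 (M + N) trigonometric evaluations per scatterer and
// frame. Accumulation runs in a small contiguous per-frame buffer.
//
// pos:     T x S x 3 array of scatterer positions [m], radar frame
// wt:      T x S matrix of nonnegative weights
// rx_x:    x-coordinates of the M RX elements (on the x-axis)
// tx_z:    z-coordinates of the N TX elements (on the z-axis)
// freqs:   L instantaneous frequencies [Hz], uniformly spaced
// Returns a complex array with dim (T, L, M, N).
// [[Rcpp::export]]
ComplexVector simulate_raw_cpp(NumericVector pos, NumericMatrix wt,
                               NumericVector rx_x, NumericVector tx_z,
                               NumericVector freqs, double c0) {
  IntegerVector pd = pos.attr("dim");
  if (pd.size() != 3 || pd[2] != 3)
    stop("pos must be a T x S x 3 array");
  const int T = pd[0], S = pd[1];
  const int M = rx_x.size(), N = tx_z.size(), L = freqs.size();
  if (wt.nrow() != T || wt.ncol() != S)
    stop("wt must be a T x S matrix");
  const double df = L > 1 ? freqs[1] - freqs[0] : 0.0;
  for (int l = 1; l < L; ++l)
    if (std::abs(freqs[l] - freqs[0] - l * df) > 1e-3)
      stop("freqs must be a uniform grid");
  const double k1 = 2.0 * M_PI * freqs[0] / c0;   // first tone
  const double dk = 2.0 * M_PI * df / c0;         // tone-to-tone step
  const double fourpi = 4.0 * M_PI;

  ComplexVector res((R_xlen_t)T * L * M * N);
  res.attr("dim") = IntegerVector::create(T, L, M, N);
  // per-frame accumulator, layout [m + M*(n + N*l)] (contiguous in m)
  std::vector<std::complex<double> > acc((size_t)L * M * N);
  std::vector<std::complex<double> > ar(M), sr(M), at(N), st(N);

  for (int t = 0; t < T; ++t) {
    std::fill(acc.begin(), acc.end(), std::complex<double>(0.0, 0.0));
    for (int s = 0; s < S; ++s) {
      const double w = wt(t, s);
      if (w == 0.0) continue;
      const double x = pos[t + (size_t)T * s];
      const double y = pos[t + (size_t)T * (s + (size_t)S)];
      const double z = pos[t + (size_t)T * (s + 2 * (size_t)S)];
      for (int m = 0; m < M; ++m) {
        const double dx = x - rx_x[m];
        const double R = std::sqrt(dx * dx + y * y + z * z);
        if (R <= 0.0) stop("scatterer coincides with an RX element");
        ar[m] = std::polar(w / (fourpi * R), -k1 * R);
        sr[m] = std::polar(1.0, -dk * R);
      }
      for (int n = 0; n < N; ++n) {
        const double dz = z - tx_z[n];
        const double R = std::sqrt(x * x + y * y + dz * dz);
        if (R <= 0.0) stop("scatterer coincides with a TX element");
        at[n] = std::polar(1.0 / (fourpi * R), -k1 * R);
        st[n] = std::polar(1.0, -dk * R);
      }
      for (int l = 0; l < L; ++l) {
        std::complex<double> *al = &acc[(size_t)l * M * N];
        for (int n = 0; n < N; ++n) {
          const std::complex<double> bn = at[n];
          std::complex<double> *row = al + (size_t)n * M;
          for (int m = 0; m < M; ++m) row[m] += ar[m] * bn;
        }
        if (l + 1 < L) {
          for (int m = 0; m < M; ++m) ar[m] *= sr[m];
          for (int n = 0; n < N; ++n) at[n] *= st[n];
        }
      }
    }
    // scatter the frame into the (T, L, M, N) output
    for (int l = 0; l < L; ++l)
      for (int n = 0; n < N; ++n)
        for (int m = 0; m < M; ++m) {
          const std::complex<double> v = acc[m + (size_t)M * (n + (size_t)N * l)];
          const size_t o = t + (size_t)T * (l + (size_t)L * (m + (size_t)M * n));
          res[o].r = v.real();
          res[o].i = v.imag();
        }
  }
  return res;
}
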