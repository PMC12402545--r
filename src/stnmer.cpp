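#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gaussian background noise with spike waveforms added at given sample indices.
// idx is 1-based (centre sample of each spike); wav is the waveform, centred.
// env_coarse, when non-empty, is a slow amplitude-gain process sampled every
// `step` output samples; it is linearly interpolated and multiplies the noise.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector cpp_noise_spikes(int n, double sd, IntegerVector idx,
                               NumericVector amp, NumericVector wav,
                               NumericVector env_coarse, double step) {
  NumericVector x(n);
  int ne = env_coarse.size();
  bool has_env = ne > 1 && step > 0;
  const double* ec = has_env ? &env_coarse[0] : (double*)0;
  // polar Box-Muller on R's uniform stream (reproducible under set.seed)
  int i = 0;
  while (i < n) {
    double u = 2.0 * R::unif_rand() - 1.0;
    double v = 2.0 * R::unif_rand() - 1.0;
    double s = u * u + v * v;
    if (s >= 1.0 || s == 0.0) continue;
    double f = std::sqrt(-2.0 * std::log(s) / s) * sd;
    for (int rep = 0; rep < 2 && i < n; ++rep) {
      double g = 1.0;
      if (has_env) {
        double pos = i / step;
        int i0 = (int)pos;
        if (i0 >= ne - 1) g = ec[ne - 1];
        else g = ec[i0] + (ec[i0 + 1] - ec[i0]) * (pos - i0);
      }
      x[i] = (rep == 0 ? u : v) * f * g;
      ++i;
    }
  }
  int wl = wav.size();
  int off = (wl - 1) / 2;
  int ns = idx.size();
  for (int s = 0; s < ns; ++s) {
    int c = idx[s] - 1 - off;
    double a = amp[s];
    for (int k = 0; k < wl; ++k) {
      int p = c + k;
      if (p >= 0 && p < n) x[p] += a * wav[k];
    }
  }
  return x;
}

// Direct-form II transposed IIR filter pass over x with initial state z.
static void df2t_filter(const std::vector<double>& b, const std::vector<double>& a,
                        const double* x, double* y, int n, std::vector<double>& z) {
  int m = (int)b.size() - 1; // state length
  if (m == 4) { // unrolled fourth-order path (the common case here)
    double b0 = b[0], b1 = b[1], b2 = b[2], b3 = b[3], b4 = b[4];
    double a1 = a[1], a2 = a[2], a3 = a[3], a4 = a[4];
    double z0 = z[0], z1 = z[1], z2 = z[2], z3 = z[3];
    for (int i = 0; i < n; ++i) {
      double xi = x[i];
      double yi = b0 * xi + z0;
      z0 = b1 * xi + z1 - a1 * yi;
      z1 = b2 * xi + z2 - a2 * yi;
      z2 = b3 * xi + z3 - a3 * yi;
      z3 = b4 * xi - a4 * yi;
      y[i] = yi;
    }
    z[0] = z0; z[1] = z1; z[2] = z2; z[3] = z3;
    return;
  }
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + (m > 0 ? z[0] : 0.0);
    for (int k = 0; k < m - 1; ++k)
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    if (m > 0) z[m - 1] = b[m] * xi - a[m] * yi;
    y[i] = yi;
  }
}

// Steady-state initial filter state for a unit step input (per-sample state
// such that a constant input produces a constant output from the first sample).
static std::vector<double> lfilter_zi(const std::vector<double>& b,
                                      const std::vector<double>& a) {
  int m = (int)b.size() - 1;
  // Solve (I - A^T) zi = B with A the companion matrix of a.
  std::vector<std::vector<double> > M(m, std::vector<double>(m, 0.0));
  std::vector<double> B(m);
  for (int i = 0; i < m; ++i) {
    M[i][0] = (i == 0 ? 1.0 : 0.0) + a[i + 1];
    if (i >= 1) M[i][i] = 1.0;
    if (i + 1 < m) M[i][i + 1] = -1.0;
    B[i] = b[i + 1] - a[i + 1] * b[0];
  }
  // Gaussian elimination with partial pivoting (m <= 8)
  std::vector<double> zi(m, 0.0);
  for (int col = 0; col < m; ++col) {
    int piv = col;
    for (int r = col + 1; r < m; ++r)
      if (std::fabs(M[r][col]) > std::fabs(M[piv][col])) piv = r;
    std::swap(M[col], M[piv]);
    std::swap(B[col], B[piv]);
    double d = M[col][col];
    for (int r = col + 1; r < m; ++r) {
      double f = M[r][col] / d;
      for (int c2 = col; c2 < m; ++c2) M[r][c2] -= f * M[col][c2];
      B[r] -= f * B[col];
    }
  }
  for (int r = m - 1; r >= 0; --r) {
    double s = B[r];
    for (int c2 = r + 1; c2 < m; ++c2) s -= M[r][c2] * zi[c2];
    zi[r] = s / M[r][r];
  }
  return zi;
}

// Zero-phase (forward-backward) IIR filtering with odd-reflection padding and
// steady-state initial conditions, matching common scientific practice.
// [[Rcpp::export]]
NumericVector cpp_filtfilt(NumericVector bv, NumericVector av, NumericVector xv) {
  int nb = bv.size(), na = av.size();
  int nf = std::max(nb, na);
  std::vector<double> b(nf, 0.0), a(nf, 0.0);
  for (int i = 0; i < nb; ++i) b[i] = bv[i];
  for (int i = 0; i < na; ++i) a[i] = av[i];
  if (a[0] == 0.0) stop("a[1] must be non-zero");
  for (int i = 0; i < nf; ++i) { b[i] /= a[0] == 1.0 ? 1.0 : av[0]; }
  if (av[0] != 1.0) { for (int i = 0; i < nf; ++i) a[i] /= av[0]; a[0] = 1.0; }

  int n = xv.size();
  int padlen = 3 * (nf - 1) * 4; // generous edge padding
  if (padlen >= n) padlen = n - 1;
  int ext_n = n + 2 * padlen;
  std::vector<double> ext(ext_n), tmp(ext_n);
  for (int i = 0; i < padlen; ++i) ext[i] = 2.0 * xv[0] - xv[padlen - i];
  for (int i = 0; i < n; ++i) ext[padlen + i] = xv[i];
  for (int i = 0; i < padlen; ++i) ext[padlen + n + i] = 2.0 * xv[n - 1] - xv[n - 2 - i];

  std::vector<double> zi = lfilter_zi(b, a);
  int m = (int)zi.size();
  std::vector<double> z(m);

  for (int k = 0; k < m; ++k) z[k] = zi[k] * ext[0];
  df2t_filter(b, a, ext.data(), tmp.data(), ext_n, z);
  std::reverse(tmp.begin(), tmp.end());
  for (int k = 0; k < m; ++k) z[k] = zi[k] * tmp[0];
  df2t_filter(b, a, tmp.data(), ext.data(), ext_n, z);
  std::reverse(ext.begin(), ext.end());

  NumericVector y(n);
  for (int i = 0; i < n; ++i) y[i] = ext[padlen + i];
  return y;
}
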