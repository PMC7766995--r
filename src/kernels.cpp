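#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// exact small rotation of unit vector u by Gaussian transverse increments
// (variance 2*Dr*dt per transverse component)
static inline void rotdiff_step(double *u, double s) {
  double g1 = R::norm_rand() * s, g2 = R::norm_rand() * s;
  // orthonormal transverse basis
  double ax = 0, ay = 0, az = 0;
  if (std::fabs(u[0]) <= std::fabs(u[1]) && std::fabs(u[0]) <= std::fabs(u[2]))
    ax = 1;
  else if (std::fabs(u[1]) <= std::fabs(u[2]))
    ay = 1;
  else
    az = 1;
  double e1x = u[1] * az - u[2] * ay;
  double e1y = u[2] * ax - u[0] * az;
  double e1z = u[0] * ay - u[1] * ax;
  double n1 = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
  e1x /= n1; e1y /= n1; e1z /= n1;
  double e2x = u[1] * e1z - u[2] * e1y;
  double e2y = u[2] * e1x - u[0] * e1z;
  double e2z = u[0] * e1y - u[1] * e1x;
  double beta = std::sqrt(g1 * g1 + g2 * g2);
  if (beta < 1e-300) return;
  double dx = (g1 * e1x + g2 * e2x) / beta;
  double dy = (g1 * e1y + g2 * e2y) / beta;
  double dz = (g1 * e1z + g2 * e2z) / beta;
  double cb = std::cos(beta), sb = std::sin(beta);
  double vx = cb * u[0] + sb * dx;
  double vy = cb * u[1] + sb * dy;
  double vz = cb * u[2] + sb * dz;
  double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
  u[0] = vx / nv; u[1] = vy / nv; u[2] = vz / nv;
}

// [[Rcpp::export]]
NumericVector cpp_rotdiff(int n_steps, double dr, double dt,
                          NumericMatrix u0) {
  int m = u0.ncol();
  double s = std::sqrt(2.0 * dr * dt);
  NumericVector out(Dimension(n_steps, 3, m));
  RNGScope scope;
  for (int i = 0; i < m; ++i) {
    double u[3] = {u0(0, i), u0(1, i), u0(2, i)};
    for (int t = 0; t < n_steps; ++t) {
      if (t > 0) rotdiff_step(u, s);
      out[t + n_steps * (0 + 3 * i)] = u[0];
      out[t + n_steps * (1 + 3 * i)] = u[1];
      out[t + n_steps * (2 + 3 * i)] = u[2];
    }
  }
  return out;
}

// streaming P1/P2 accumulation at a sparse lag set (ring buffer per vector)
// [[Rcpp::export]]
List cpp_rotdiff_stream(double n_steps, double dr, double dt,
                        NumericMatrix u0, IntegerVector lags) {
  int m = u0.ncol(), nl = lags.size();
  long long n = (long long)n_steps;
  int maxlag = 0;
  for (int k = 0; k < nl; ++k) if (lags[k] > maxlag) maxlag = lags[k];
  int L = maxlag + 1;
  double s = std::sqrt(2.0 * dr * dt);
  std::vector<double> s1(nl, 0.0), s2(nl, 0.0), counts(nl, 0.0);
  std::vector<double> buf(3 * (size_t)L);
  RNGScope scope;
  for (int i = 0; i < m; ++i) {
    double u[3] = {u0(0, i), u0(1, i), u0(2, i)};
    for (long long t = 0; t < n; ++t) {
      if (t > 0) rotdiff_step(u, s);
      size_t pos = 3 * (size_t)(t % L);
      buf[pos] = u[0]; buf[pos + 1] = u[1]; buf[pos + 2] = u[2];
      for (int k = 0; k < nl; ++k) {
        long long lag = lags[k];
        if (lag > t) continue;
        size_t pp = 3 * (size_t)((t - lag) % L);
        double c = u[0] * buf[pp] + u[1] * buf[pp + 1] + u[2] * buf[pp + 2];
        s1[k] += c; s2[k] += c * c; counts[k] += 1.0;
      }
    }
  }
  return List::create(_["s1"] = NumericVector(s1.begin(), s1.end()),
                      _["s2"] = NumericVector(s2.begin(), s2.end()),
                      _["counts"] = NumericVector(counts.begin(), counts.end()));
}

// direct multi-origin P1/P2 sums at a lag subset for a stored series
// u has dim (n, 3, m)
// [[Rcpp::export]]
List cpp_vector_acf_lags(NumericVector u, IntegerVector lags) {
  IntegerVector dims = u.attr("dim");
  int n = dims[0], m = dims[2], nl = lags.size();
  std::vector<double> s1(nl, 0.0), s2(nl, 0.0), counts(nl, 0.0);
  const double *p = REAL(u);
  for (int i = 0; i < m; ++i) {
    const double *ux = p + (size_t)n * (0 + 3 * (size_t)i);
    const double *uy = p + (size_t)n * (1 + 3 * (size_t)i);
    const double *uz = p + (size_t)n * (2 + 3 * (size_t)i);
    for (int k = 0; k < nl; ++k) {
      int lag = lags[k];
      double a1 = 0, a2 = 0;
      for (int t = lag; t < n; ++t) {
        double c = ux[t] * ux[t - lag] + uy[t] * uy[t - lag] +
                   uz[t] * uz[t - lag];
        a1 += c; a2 += c * c;
      }
      s1[k] += a1; s2[k] += a2; counts[k] += n - lag;
    }
  }
  return List::create(_["s1"] = NumericVector(s1.begin(), s1.end()),
                      _["s2"] = NumericVector(s2.begin(), s2.end()),
                      _["counts"] = NumericVector(counts.begin(), counts.end()));
}

// overdamped Brownian dynamics of the coarse-grained toy dendrimer:
// harmonic bonds, soft pair repulsion, screened Coulomb, soft spherical wall
// [[Rcpp::export]]
NumericVector cpp_brownian(NumericMatrix x0, IntegerMatrix bonds,
                           NumericVector charge, int n_steps, double dt,
                           int save_every, double kT, double bond_r0,
                           double bond_k, double rep_rcut, double rep_k,
                           double coul_lambda, double coul_kappa,
                           double wall_r, double wall_k) {
  int n = x0.nrow(), nb = bonds.nrow();
  int n_saved = n_steps / save_every;
  NumericVector out(Dimension(n_saved, n, 3));
  std::vector<double> x(3 * (size_t)n), f(3 * (size_t)n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = x0(i, c);
  double noise = std::sqrt(2.0 * kT * dt);
  double cutoff = std::max(rep_rcut, 4.0 * coul_kappa);
  double cut2 = cutoff * cutoff;
  RNGScope scope;
  int saved = 0;
  for (int t = 0; t < n_steps; ++t) {
    std::fill(f.begin(), f.end(), 0.0);
    // bonds
    for (int b = 0; b < nb; ++b) {
      int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
      double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
             dz = x[3 * i + 2] - x[3 * j + 2];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-9) continue;
      double fm = -bond_k * (r - bond_r0) / r;
      f[3 * i] += fm * dx; f[3 * i + 1] += fm * dy; f[3 * i + 2] += fm * dz;
      f[3 * j] -= fm * dx; f[3 * j + 1] -= fm * dy; f[3 * j + 2] -= fm * dz;
    }
    // non-bonded pairs within cutoff
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
               dz = x[3 * i + 2] - x[3 * j + 2];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 > cut2 || r2 < 1e-18) continue;
        double r = std::sqrt(r2);
        double fm = 0.0;
        if (r < rep_rcut) fm += rep_k * (rep_rcut - r) / r;
        double qq = charge[i] * charge[j];
        if (qq != 0.0) {
          // soft-core screened Coulomb: U = l*qq*exp(-r/k)/sqrt(r^2+s^2)
          double s2 = 0.15 * 0.15;
          double rs2 = r2 + s2, srs = std::sqrt(rs2);
          double e = std::exp(-r / coul_kappa);
          fm += coul_lambda * qq * e *
                (r / (rs2 * srs) + 1.0 / (coul_kappa * srs)) / r;
        }
        f[3 * i] += fm * dx; f[3 * i + 1] += fm * dy; f[3 * i + 2] += fm * dz;
        f[3 * j] -= fm * dx; f[3 * j + 1] -= fm * dy; f[3 * j + 2] -= fm * dz;
      }
    }
    // container wall
    for (int i = 0; i < n; ++i) {
      double r = std::sqrt(x[3 * i] * x[3 * i] + x[3 * i + 1] * x[3 * i + 1] +
                           x[3 * i + 2] * x[3 * i + 2]);
      if (r > wall_r) {
        double fm = -wall_k * (r - wall_r) / r;
        f[3 * i] += fm * x[3 * i];
        f[3 * i + 1] += fm * x[3 * i + 1];
        f[3 * i + 2] += fm * x[3 * i + 2];
      }
    }
    // Euler-Maruyama update with blow-up guard
    for (int i = 0; i < n; ++i) {
      for (int c = 0; c < 3; ++c) {
        double step = f[3 * i + c] * dt + noise * R::norm_rand();
        if (std::fabs(step) > 1.0)
          stop("integrator blow-up: displacement %f nm at step %d atom %d",
               std::fabs(step), t, i + 1);
        x[3 * i + c] += step;
      }
    }
    if ((t + 1) % save_every == 0 && saved < n_saved) {
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c)
          out[saved + n_saved * ((size_t)i + (size_t)n * c)] = x[3 * i + c];
      ++saved;
    }
  }
  return out;
}
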