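// Compiled numerical core: forced Jansen-Rit right-hand side and analytic
// tangent-space Jacobian, adaptive Dormand-Prince 4(5) integration with
// uniform output sampling, fixed-step RK4 tangent integration with QR
// reorthonormalization for Lyapunov spectra, and the Wolf fixed-evolution-time
// estimator of the largest Lyapunov exponent from a delay-embedded series.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Par {
  double a13, a23, a31, a32, beta, gamma, x1T, x3T, zeta, eta, delta;
};

static Par unpack(const NumericVector& p) {
  Par q;
  q.a13 = p[0]; q.a23 = p[1]; q.a31 = p[2]; q.a32 = p[3];
  q.beta = p[4]; q.gamma = p[5]; q.x1T = p[6]; q.x3T = p[7];
  q.zeta = p[8]; q.eta = p[9]; q.delta = p[10];
  return q;
}

inline double sig(double x, double g) { return 1.0 / (1.0 + g * std::exp(-x)); }

inline double stim(double theta, const Par& p) {
  double c = std::cos(theta);
  return p.zeta * std::exp(-2.0 * p.delta * c * c);
}

// State layout: x03, x31, x32, y30, y31, y32, theta
inline void rhs(const double* x, double* dx, const Par& p, double stim_extra) {
  double S3 = sig(x[1] + x[2] + p.x3T, p.gamma);
  double S1 = sig(p.a13 * x[0] + p.x1T, p.gamma);
  double x2T = stim(x[6], p) + stim_extra;
  double S2 = sig(p.a23 * x[0] + x2T, p.gamma);
  dx[0] = x[3];
  dx[1] = x[4];
  dx[2] = x[5];
  dx[3] = S3 - 2.0 * x[3] - x[0];
  dx[4] = p.a31 * S1 - 2.0 * x[4] - x[1];
  dx[5] = p.a32 * S2 - 2.0 * p.beta * x[5] - p.beta * p.beta * x[2];
  dx[6] = M_PI * p.eta;
}

// 6x6 Jacobian of the neural subsystem; stimulus phase enters as explicit
// time dependence through S2. Row-major J[r*6+c].
inline void jac(const double* x, double* J, const Par& p) {
  for (int i = 0; i < 36; ++i) J[i] = 0.0;
  double S3 = sig(x[1] + x[2] + p.x3T, p.gamma);
  double S1 = sig(p.a13 * x[0] + p.x1T, p.gamma);
  double x2T = stim(x[6], p);
  double S2 = sig(p.a23 * x[0] + x2T, p.gamma);
  double S3p = S3 * (1.0 - S3), S1p = S1 * (1.0 - S1), S2p = S2 * (1.0 - S2);
  J[0 * 6 + 3] = 1.0;
  J[1 * 6 + 4] = 1.0;
  J[2 * 6 + 5] = 1.0;
  J[3 * 6 + 0] = -1.0;
  J[3 * 6 + 1] = S3p;
  J[3 * 6 + 2] = S3p;
  J[3 * 6 + 3] = -2.0;
  J[4 * 6 + 0] = p.a31 * p.a13 * S1p;
  J[4 * 6 + 1] = -1.0;
  J[4 * 6 + 4] = -2.0;
  J[5 * 6 + 0] = p.a32 * p.a23 * S2p;
  J[5 * 6 + 2] = -p.beta * p.beta;
  J[5 * 6 + 5] = -2.0 * p.beta;
}

// [[Rcpp::export]]
NumericVector cpp_rhs(NumericVector state, NumericVector par,
                      double stim_extra = 0.0) {
  Par p = unpack(par);
  NumericVector out(7);
  rhs(REAL(state), REAL(out), p, stim_extra);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_jacobian(NumericVector state, NumericVector par) {
  Par p = unpack(par);
  std::vector<double> J(36);
  jac(REAL(state), J.data(), p);
  NumericMatrix out(6, 6);
  for (int r = 0; r < 6; ++r)
    for (int c = 0; c < 6; ++c) out(r, c) = J[r * 6 + c];
  return out;
}

// Dormand-Prince 4(5) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31c = 3.0 / 40, a32c = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// Adaptive DP45 from kappa0 to each entry of kappa_out (ascending, first entry
// = kappa0 returns the initial state). Steps never cross an output time, so a
// piecewise-constant stimulus noise sequence (one value per output interval)
// is handled exactly. Throws on blow-up with the kappa reached.
// [[Rcpp::export]]
NumericMatrix cpp_integrate(NumericVector y0, NumericVector par,
                            NumericVector kappa_out, double rel_tol,
                            double abs_tol, NumericVector stim_noise) {
  Par p = unpack(par);
  const int n = 7;
  int nout = kappa_out.size();
  NumericMatrix out(nout, n);
  double y[7], k1[7], k2[7], k3[7], k4[7], k5[7], k6[7], k7[7], yt[7], y5[7];
  for (int j = 0; j < n; ++j) { y[j] = y0[j]; out(0, j) = y[j]; }
  double t = kappa_out[0];
  bool have_noise = stim_noise.size() > 0;
  double h = 1e-4;
  bool fsal_valid = false;
  for (int i = 1; i < nout; ++i) {
    double t_end = kappa_out[i];
    double extra = have_noise ? stim_noise[i - 1] : 0.0;
    if (have_noise) fsal_valid = false;  // noise value changed
    while (t < t_end) {
      if (h > t_end - t) h = t_end - t;
      if (!fsal_valid) rhs(y, k1, p, extra);
      for (int j = 0; j < n; ++j) yt[j] = y[j] + h * a21 * k1[j];
      rhs(yt, k2, p, extra);
      for (int j = 0; j < n; ++j)
        yt[j] = y[j] + h * (a31c * k1[j] + a32c * k2[j]);
      rhs(yt, k3, p, extra);
      for (int j = 0; j < n; ++j)
        yt[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
      rhs(yt, k4, p, extra);
      for (int j = 0; j < n; ++j)
        yt[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] +
                            a54 * k4[j]);
      rhs(yt, k5, p, extra);
      for (int j = 0; j < n; ++j)
        yt[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                            a64 * k4[j] + a65 * k5[j]);
      rhs(yt, k6, p, extra);
      for (int j = 0; j < n; ++j)
        y5[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] + b5 * k5[j] +
                            b6 * k6[j]);
      rhs(y5, k7, p, extra);
      double err = 0.0;
      for (int j = 0; j < n; ++j) {
        double ej = h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] + e5 * k5[j] +
                         e6 * k6[j] + e7 * k7[j]);
        double sc = abs_tol + rel_tol * std::max(std::fabs(y[j]),
                                                 std::fabs(y5[j]));
        double r = ej / sc;
        err += r * r;
      }
      err = std::sqrt(err / n);
      if (!std::isfinite(err)) stop("integration blow-up at kappa = %f", t);
      if (err <= 1.0) {
        t += h;
        for (int j = 0; j < n; ++j) { y[j] = y5[j]; k1[j] = k7[j]; }
        fsal_valid = true;
        if (!std::isfinite(y[0]))
          stop("integration blow-up at kappa = %f", t);
      } else {
        fsal_valid = fsal_valid;  // k1 still valid at unchanged y
      }
      double fac = 0.9 * std::pow(err > 1e-300 ? err : 1e-300, -0.2);
      if (fac > 5.0) fac = 5.0;
      if (fac < 0.2) fac = 0.2;
      h *= fac;
      if (h < 1e-14)
        stop("step size underflow (stiff or discontinuous) at kappa = %f", t);
    }
    for (int j = 0; j < n; ++j) out(i, j) = y[j];
  }
  return out;
}

// Modified Gram-Schmidt on 6 x k column set Q (column-major), returns log of
// the diagonal scale factors in lognorm.
static void mgs(double* Q, int k, double* lognorm) {
  for (int c = 0; c < k; ++c) {
    double* qc = Q + 6 * c;
    for (int b = 0; b < c; ++b) {
      double* qb = Q + 6 * b;
      double dot = 0.0;
      for (int r = 0; r < 6; ++r) dot += qb[r] * qc[r];
      for (int r = 0; r < 6; ++r) qc[r] -= dot * qb[r];
    }
    double nrm = 0.0;
    for (int r = 0; r < 6; ++r) nrm += qc[r] * qc[r];
    nrm = std::sqrt(nrm);
    lognorm[c] = std::log(nrm);
    double inv = 1.0 / nrm;
    for (int r = 0; r < 6; ++r) qc[r] *= inv;
  }
}

// Tangent-variational Jacobian-matrix product: R = J * Q, exploiting the
// fixed sparsity of J (identity block onto the currents, three sigmoid
// coupling terms, constant damping diagonals).
struct JacSparse {
  double s3p, g41, g52, beta, beta2;
};

static inline void jac_sparse(const double* x, JacSparse& J, const Par& p) {
  double S3 = sig(x[1] + x[2] + p.x3T, p.gamma);
  double S1 = sig(p.a13 * x[0] + p.x1T, p.gamma);
  double x2T = stim(x[6], p);
  double S2 = sig(p.a23 * x[0] + x2T, p.gamma);
  J.s3p = S3 * (1.0 - S3);
  J.g41 = p.a31 * p.a13 * S1 * (1.0 - S1);
  J.g52 = p.a32 * p.a23 * S2 * (1.0 - S2);
  J.beta = p.beta;
  J.beta2 = p.beta * p.beta;
}

static inline void jmul(const JacSparse& J, const double* Q, double* R,
                        int k) {
  for (int c = 0; c < k; ++c) {
    const double* q = Q + 6 * c;
    double* r = R + 6 * c;
    r[0] = q[3];
    r[1] = q[4];
    r[2] = q[5];
    r[3] = -q[0] + J.s3p * (q[1] + q[2]) - 2.0 * q[3];
    r[4] = J.g41 * q[0] - q[1] - 2.0 * q[4];
    r[5] = J.g52 * q[0] - J.beta2 * q[2] - 2.0 * J.beta * q[5];
  }
}

// One classical RK4 step of state (7) plus tangent matrix Q (6 x k).
// work: caller-provided scratch of size >= 5 * 6 * k.
static void rk4_tangent_step(double* y, double* Q, int k, double h,
                             const Par& p, double* work) {
  double f1[7], f2[7], f3[7], f4[7], yt[7];
  JacSparse J;
  double* K1 = work;
  double* K2 = work + 6 * k;
  double* K3 = work + 12 * k;
  double* K4 = work + 18 * k;
  double* Qt = work + 24 * k;
  rhs(y, f1, p, 0.0);
  jac_sparse(y, J, p);
  jmul(J, Q, K1, k);
  for (int j = 0; j < 7; ++j) yt[j] = y[j] + 0.5 * h * f1[j];
  for (int j = 0; j < 6 * k; ++j) Qt[j] = Q[j] + 0.5 * h * K1[j];
  rhs(yt, f2, p, 0.0);
  jac_sparse(yt, J, p);
  jmul(J, Qt, K2, k);
  for (int j = 0; j < 7; ++j) yt[j] = y[j] + 0.5 * h * f2[j];
  for (int j = 0; j < 6 * k; ++j) Qt[j] = Q[j] + 0.5 * h * K2[j];
  rhs(yt, f3, p, 0.0);
  jac_sparse(yt, J, p);
  jmul(J, Qt, K3, k);
  for (int j = 0; j < 7; ++j) yt[j] = y[j] + h * f3[j];
  for (int j = 0; j < 6 * k; ++j) Qt[j] = Q[j] + h * K3[j];
  rhs(yt, f4, p, 0.0);
  jac_sparse(yt, J, p);
  jmul(J, Qt, K4, k);
  for (int j = 0; j < 7; ++j)
    y[j] += h / 6.0 * (f1[j] + 2.0 * f2[j] + 2.0 * f3[j] + f4[j]);
  for (int j = 0; j < 6 * k; ++j)
    Q[j] += h / 6.0 * (K1[j] + 2.0 * K2[j] + 2.0 * K3[j] + K4[j]);
}

// Tangent-space Lyapunov spectrum: k exponents from accumulated QR diagonal
// growth. discard: kappa span excluded from accumulation (transient, still
// renormalized). Returns exponents, a trailing-window drift estimate (max
// absolute difference between full-window and second-half-window exponents)
// and the time-averaged Jacobian trace along the same trajectory.
// [[Rcpp::export]]
List cpp_lyapunov(NumericVector y0, NumericVector par, double span,
                  double step, int renorm_every, int k, double discard) {
  Par p = unpack(par);
  double y[7];
  for (int j = 0; j < 7; ++j) y[j] = y0[j];
  std::vector<double> Q(6 * k, 0.0);
  for (int c = 0; c < k; ++c) Q[6 * c + c] = 1.0;
  std::vector<double> lognorm(k), sums(k, 0.0), sums_half(k, 0.0);
  long n_steps = (long)std::ceil(span / step);
  long n_discard = (long)std::ceil(discard / step);
  long n_acc = n_steps - n_discard;
  long half_mark = n_discard + n_acc / 2;
  double trace_sum = 0.0;
  long trace_n = 0;
  std::vector<double> work(30 * k);
  for (long s = 0; s < n_steps; ++s) {
    rk4_tangent_step(y, Q.data(), k, step, p, work.data());
    if (!std::isfinite(y[0]))
      stop("divergent trajectory at kappa = %f", (s + 1) * step);
    if ((s + 1) % renorm_every == 0 || s == n_steps - 1) {
      mgs(Q.data(), k, lognorm.data());
      if (s >= n_discard) {
        for (int c = 0; c < k; ++c) {
          sums[c] += lognorm[c];
          if (s >= half_mark) sums_half[c] += lognorm[c];
        }
      }
    }
    if (s >= n_discard) {
      trace_sum += -4.0 - 2.0 * p.beta;  // analytic Jacobian trace (constant)
      ++trace_n;
    }
  }
  double T_acc = n_acc * step;
  double T_half = (n_steps - half_mark) * step;
  NumericVector lam(k), lam_half(k);
  for (int c = 0; c < k; ++c) {
    lam[c] = sums[c] / T_acc;
    lam_half[c] = sums_half[c] / T_half;
  }
  double drift = 0.0;
  for (int c = 0; c < k; ++c)
    drift = std::max(drift, std::fabs(lam[c] - lam_half[c]));
  return List::create(_["exponents"] = lam, _["drift"] = drift,
                      _["mean_trace"] = trace_sum / std::max(trace_n, 1L),
                      _["final_state"] = NumericVector(y, y + 7));
}

// Wolf fixed-evolution-time estimator on a delay embedding.
// Returns mean log separation growth per evolution sample (natural log per
// sample), plus bookkeeping. dmin/dmax: admissible neighbor distance bounds;
// theiler: temporal exclusion window (samples). On neighbor exhaustion the
// upper bound is doubled; only total exhaustion is an error.
// [[Rcpp::export]]
List cpp_wolf(NumericVector series, int m, int delay, int evolve, int theiler,
              double dmin, double dmax) {
  int n = series.size();
  int N = n - (m - 1) * delay;
  if (N <= evolve + 1) stop("series too short for embedding");
  const double* s = REAL(series);
  auto dist2 = [&](int i, int j) {
    double d = 0.0;
    for (int c = 0; c < m; ++c) {
      double diff = s[i + c * delay] - s[j + c * delay];
      d += diff * diff;
    }
    return d;
  };
  int fid = 0;
  // initial neighbor
  double sum_log = 0.0;
  long n_evol = 0;
  int nbr = -1;
  double dmax_cur = dmax;
  auto find_neighbor = [&](int i, double lo, double hi) {
    double best = R_PosInf;
    int best_j = -1;
    double lo2 = lo * lo, hi2 = hi * hi;
    for (int j = 0; j < N - evolve; ++j) {
      if (std::abs(j - i) <= theiler) continue;
      double d2 = dist2(i, j);
      if (d2 < lo2 || d2 > hi2) continue;
      if (d2 < best) { best = d2; best_j = j; }
    }
    return best_j;
  };
  while (nbr < 0 && dmax_cur < 1e12) {
    nbr = find_neighbor(fid, dmin, dmax_cur);
    if (nbr < 0) dmax_cur *= 2.0;
  }
  if (nbr < 0) stop("no admissible neighbors for Wolf estimation");
  while (fid + evolve < N) {
    double d0 = std::sqrt(dist2(fid, nbr));
    int fid2 = fid + evolve, nbr2 = nbr + evolve;
    if (nbr2 >= N) break;
    double d1 = std::sqrt(dist2(fid2, nbr2));
    if (d0 > 0.0 && d1 > 0.0) {
      sum_log += std::log(d1 / d0);
      ++n_evol;
    }
    fid = fid2;
    // replacement: nearest admissible point to the evolved fiducial
    dmax_cur = dmax;
    int cand = -1;
    while (cand < 0 && dmax_cur < 1e12) {
      cand = find_neighbor(fid, dmin, dmax_cur);
      if (cand < 0) dmax_cur *= 2.0;
    }
    if (cand < 0) break;
    nbr = cand;
  }
  if (n_evol == 0) stop("no admissible neighbors for Wolf estimation");
  return List::create(_["lambda_per_sample"] = sum_log / (n_evol * evolve),
                      _["n_evolutions"] = (double)n_evol);
}
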