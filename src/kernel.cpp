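#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Quaternion convention: q = (A, B, C, D) = (n * sin(theta/2), cos(theta/2)).
// Composition "first p, then q" is the Hamilton product q (x) p, linear in p:
//   out = R(q) p with R(q) the 4x4 composition matrix.
static inline void qmul(const double* q, const double* p, double* out) {
  out[0] =  q[3] * p[0] - q[2] * p[1] + q[1] * p[2] + q[0] * p[3];
  out[1] =  q[2] * p[0] + q[3] * p[1] - q[0] * p[2] + q[1] * p[3];
  out[2] = -q[1] * p[0] + q[0] * p[1] + q[3] * p[2] + q[2] * p[3];
  out[3] = -q[0] * p[0] - q[1] * p[1] - q[2] * p[2] + q[3] * p[3];
}

// step quaternion of one piecewise-constant control step; ue = effective
// (B1-scaled) controls, off in Hz, a = 2*pi*dt.  f = sin(theta/2)/theta and
// g2 = d(f)/d(theta)/theta are series-expanded near theta = 0.
static inline void step_quat(double uex, double uey, double off, double a,
                             double* q, double* f_out, double* g2_out) {
  double r = std::sqrt(uex * uex + uey * uey + off * off);
  double th = a * r;
  double f, g2;
  if (th < 1e-6) {
    f = 0.5 - th * th / 48.0;
    g2 = -1.0 / 24.0 + th * th / 480.0;
  } else {
    double s = std::sin(0.5 * th), c = std::cos(0.5 * th);
    f = s / th;
    g2 = (0.5 * th * c - s) / (th * th * th);
  }
  q[0] = a * uex * f;
  q[1] = a * uey * f;
  q[2] = a * off * f;
  q[3] = std::cos(0.5 * th);
  if (f_out) *f_out = f;
  if (g2_out) *g2_out = g2;
}

// Final propagator quaternions of a shaped pulse over an ensemble of
// (offset, B1-scale) isochromats.  Returns an M x 4 matrix (A, B, C, D).
// [[Rcpp::export]]
NumericMatrix cpp_propagate_final(NumericVector ux, NumericVector uy,
                                  double dt, NumericVector off,
                                  NumericVector b1) {
  const int N = ux.size(), M = off.size();
  if (b1.size() != M) stop("off and b1 must have equal length");
  const double a = 2.0 * M_PI * dt;
  NumericMatrix X(M, 4);
  for (int i = 0; i < M; ++i) {
    double x[4] = {0.0, 0.0, 0.0, 1.0};
    double q[4], t[4];
    for (int k = 0; k < N; ++k) {
      step_quat(b1[i] * ux[k], b1[i] * uy[k], off[i], a, q, nullptr, nullptr);
      qmul(q, x, t);
      x[0] = t[0]; x[1] = t[1]; x[2] = t[2]; x[3] = t[3];
    }
    for (int c = 0; c < 4; ++c) X(i, c) = x[c];
  }
  return X;
}

// Cost and (optionally) analytic gradient of the band-selective UR cost.
//
//   Phi = (1/n_b1) [ w_sel/(2 n) sum_pass |X_N - U_F|^2
//                  + w_0  /(2 m) sum_stop (A^2 + B^2) ]
//
// Gradients are assembled from backpropagated costates paired with the
// exact derivative of each step quaternion with respect to its controls.
// region: 0 = passband, 1 = stopband, per isochromat.
// [[Rcpp::export]]
List cpp_cost_grad(NumericVector ux, NumericVector uy, double dt,
                   NumericVector off, NumericVector b1,
                   IntegerVector region, int n_pass, int n_stop, int n_b1,
                   double w_sel, double w_0, NumericVector UF,
                   bool want_grad) {
  const int N = ux.size(), M = off.size();
  if (uy.size() != N) stop("ux and uy must have equal length");
  if (b1.size() != M || region.size() != M) stop("ensemble vectors mismatch");
  if (UF.size() != 4) stop("target quaternion needs 4 components");
  const double a = 2.0 * M_PI * dt;
  const double wp_cost = w_sel / (2.0 * n_pass * n_b1);
  const double ws_cost = w_0 / (2.0 * n_stop * n_b1);
  const double wp_grad = 1.0 / (2.0 * n_pass * n_b1);
  const double ws_grad = 1.0 / (2.0 * n_stop * n_b1);

  double cost = 0.0;
  NumericVector gx(want_grad ? N : 0), gy(want_grad ? N : 0);
  // forward states X_0..X_N for one isochromat at a time
  std::vector<double> Xs;
  if (want_grad) Xs.resize(4 * (N + 1));

  for (int i = 0; i < M; ++i) {
    const double bi = b1[i], offi = off[i];
    double x[4] = {0.0, 0.0, 0.0, 1.0};
    double q[4], t[4];
    if (want_grad) { Xs[0] = 0; Xs[1] = 0; Xs[2] = 0; Xs[3] = 1; }
    for (int k = 0; k < N; ++k) {
      step_quat(bi * ux[k], bi * uy[k], offi, a, q, nullptr, nullptr);
      qmul(q, x, t);
      x[0] = t[0]; x[1] = t[1]; x[2] = t[2]; x[3] = t[3];
      if (want_grad)
        for (int c = 0; c < 4; ++c) Xs[4 * (k + 1) + c] = x[c];
    }
    // terminal cost and costate (the costate carries 2*w already)
    double P[4];
    if (region[i] == 0) {
      double d0 = x[0] - UF[0], d1 = x[1] - UF[1],
             d2 = x[2] - UF[2], d3 = x[3] - UF[3];
      cost += wp_cost * (d0 * d0 + d1 * d1 + d2 * d2 + d3 * d3);
      P[0] = 2.0 * w_sel * d0; P[1] = 2.0 * w_sel * d1;
      P[2] = 2.0 * w_sel * d2; P[3] = 2.0 * w_sel * d3;
    } else {
      cost += ws_cost * (x[0] * x[0] + x[1] * x[1]);
      P[0] = 2.0 * w_0 * x[0]; P[1] = 2.0 * w_0 * x[1];
      P[2] = 0.0; P[3] = 0.0;
    }
    if (!want_grad) continue;
    const double wg = (region[i] == 0) ? wp_grad : ws_grad;
    // backward sweep: at step k use P_k, then P_{k-1} = conj(q_k) (x) P_k
    for (int k = N - 1; k >= 0; --k) {
      double f, g2;
      const double uex = bi * ux[k], uey = bi * uy[k];
      step_quat(uex, uey, offi, a, q, &f, &g2);
      const double* xm = &Xs[4 * k];  // X_{k-1}
      const double a3 = a * a * a;
      // d(step quaternion)/d(ux[k]) -- chain rule through the B1 scale
      double dqx[4] = {
        bi * (a * f + a3 * uex * uex * g2),
        bi * (a3 * uex * uey * g2),
        bi * (a3 * uex * offi * g2),
        bi * (-0.5 * a * a * uex * f)
      };
      double dqy[4] = {
        bi * (a3 * uey * uex * g2),
        bi * (a * f + a3 * uey * uey * g2),
        bi * (a3 * uey * offi * g2),
        bi * (-0.5 * a * a * uey * f)
      };
      qmul(dqx, xm, t);
      gx[k] += wg * (P[0] * t[0] + P[1] * t[1] + P[2] * t[2] + P[3] * t[3]);
      qmul(dqy, xm, t);
      gy[k] += wg * (P[0] * t[0] + P[1] * t[1] + P[2] * t[2] + P[3] * t[3]);
      // transport the costate one step back: P_{k-1} = P_k R_k
      double qc[4] = {-q[0], -q[1], -q[2], q[3]};
      qmul(qc, P, t);
      P[0] = t[0]; P[1] = t[1]; P[2] = t[2]; P[3] = t[3];
    }
  }
  if (want_grad)
    return List::create(_["cost"] = cost, _["gx"] = gx, _["gy"] = gy);
  return List::create(_["cost"] = cost);
}
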