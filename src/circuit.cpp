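// Two-qubit statevector simulation of the metric-learning embedding circuit
// and the analytic gradient of the Hilbert-Schmidt batch cost.
//
// Amplitude order: |00>, |01>, |10>, |11>; the left bit is qubit 1.
// Conventions: Rx(phi) = exp(-i phi/2 X), Ry(phi) = exp(-i phi/2 Y),
//              ZZ(th)  = exp(-i th/2 Z (x) Z).
// Gradients use forward-mode tangents: each embedded state carries
// d|psi>/dp for p in (x1, x2, theta_1..theta_{3L}); a gate G with its own
// parameter p adds (dG/dp) psi_old = Gen * psi_new to the p-tangent because
// every generator commutes with its gate.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cd;

static inline void mix(cd &u, cd &v, const cd &m00, const cd &m01,
                       const cd &m10, const cd &m11) {
  cd u0 = u, v0 = v;
  u = m00 * u0 + m01 * v0;
  v = m10 * u0 + m11 * v0;
}

// single-qubit rotations on qubit 1 (index pairs 0-2, 1-3) and
// qubit 2 (pairs 0-1, 2-3)
static void apply_rx_q1(cd *v, double c, double s) {
  cd m00(c, 0), m01(0, -s), m10(0, -s), m11(c, 0);
  mix(v[0], v[2], m00, m01, m10, m11);
  mix(v[1], v[3], m00, m01, m10, m11);
}
static void apply_rx_q2(cd *v, double c, double s) {
  cd m00(c, 0), m01(0, -s), m10(0, -s), m11(c, 0);
  mix(v[0], v[1], m00, m01, m10, m11);
  mix(v[2], v[3], m00, m01, m10, m11);
}
static void apply_ry_q1(cd *v, double c, double s) {
  cd m00(c, 0), m01(-s, 0), m10(s, 0), m11(c, 0);
  mix(v[0], v[2], m00, m01, m10, m11);
  mix(v[1], v[3], m00, m01, m10, m11);
}
static void apply_ry_q2(cd *v, double c, double s) {
  cd m00(c, 0), m01(-s, 0), m10(s, 0), m11(c, 0);
  mix(v[0], v[1], m00, m01, m10, m11);
  mix(v[2], v[3], m00, m01, m10, m11);
}
static void apply_zz(cd *v, double th) {
  cd p = std::exp(cd(0.0, -th / 2.0));
  cd q = std::conj(p);
  v[0] *= p; v[1] *= q; v[2] *= q; v[3] *= p;
}

// generator contributions (-i/2 * Pauli applied to the post-gate state)
static void gen_x_q1(const cd *psi, cd *t) {
  const cd h(0.0, -0.5);
  t[0] += h * psi[2]; t[2] += h * psi[0];
  t[1] += h * psi[3]; t[3] += h * psi[1];
}
static void gen_x_q2(const cd *psi, cd *t) {
  const cd h(0.0, -0.5);
  t[0] += h * psi[1]; t[1] += h * psi[0];
  t[2] += h * psi[3]; t[3] += h * psi[2];
}
static void gen_y_q1(const cd *psi, cd *t) {
  t[0] += -0.5 * psi[2]; t[2] += 0.5 * psi[0];
  t[1] += -0.5 * psi[3]; t[3] += 0.5 * psi[1];
}
static void gen_y_q2(const cd *psi, cd *t) {
  t[0] += -0.5 * psi[1]; t[1] += 0.5 * psi[0];
  t[2] += -0.5 * psi[3]; t[3] += 0.5 * psi[2];
}
static void gen_zz(const cd *psi, cd *t) {
  const cd h(0.0, -0.5);
  t[0] += h * psi[0]; t[1] -= h * psi[1];
  t[2] -= h * psi[2]; t[3] += h * psi[3];
}

// Embed one sample; tan may be NULL. tan holds ntan = 2 + 3*layers tangent
// vectors of length 4, ordered (x1, x2, theta_1, ..., theta_{3L}).
static void embed_one(double x1, double x2, const double *th, int layers,
                      bool final_encoding, cd *psi, cd *tan, int ntan) {
  psi[0] = cd(1, 0); psi[1] = psi[2] = psi[3] = cd(0, 0);
  if (tan) std::fill(tan, tan + 4 * ntan, cd(0, 0));

  double c1 = std::cos(x1 / 2.0), s1 = std::sin(x1 / 2.0);
  double c2 = std::cos(x2 / 2.0), s2 = std::sin(x2 / 2.0);

  for (int l = 0; l <= layers; ++l) {
    // data-encoding Rx pair (also the closing re-encoding when l == layers)
    if (l == layers && !final_encoding) break;
    if (tan) {
      for (int p = 0; p < ntan; ++p) {
        apply_rx_q1(tan + 4 * p, c1, s1);
        apply_rx_q2(tan + 4 * p, c2, s2);
      }
    }
    apply_rx_q1(psi, c1, s1);
    apply_rx_q2(psi, c2, s2);
    if (tan) {
      gen_x_q1(psi, tan + 0);
      gen_x_q2(psi, tan + 4);
    }
    if (l == layers) break;

    // trainable block: ZZ entangler then Ry pair
    double tz = th[3 * l], ta = th[3 * l + 1], tb = th[3 * l + 2];
    if (tan) for (int p = 0; p < ntan; ++p) apply_zz(tan + 4 * p, tz);
    apply_zz(psi, tz);
    if (tan) gen_zz(psi, tan + 4 * (2 + 3 * l));

    double ca = std::cos(ta / 2.0), sa = std::sin(ta / 2.0);
    double cb = std::cos(tb / 2.0), sb = std::sin(tb / 2.0);
    if (tan) {
      for (int p = 0; p < ntan; ++p) {
        apply_ry_q1(tan + 4 * p, ca, sa);
        apply_ry_q2(tan + 4 * p, cb, sb);
      }
    }
    apply_ry_q1(psi, ca, sa);
    apply_ry_q2(psi, cb, sb);
    if (tan) {
      gen_y_q1(psi, tan + 4 * (2 + 3 * l + 1));
      gen_y_q2(psi, tan + 4 * (2 + 3 * l + 2));
    }
  }
}

// [[Rcpp::export]]
ComplexMatrix qml_embed_cpp(NumericMatrix x12, NumericVector theta,
                            int layers, bool final_encoding) {
  if (x12.ncol() != 2) stop("x12 must have two columns (x1, x2)");
  if ((int)theta.size() != 3 * layers)
    stop("theta must have length 3 * layers");
  int m = x12.nrow();
  ComplexMatrix out(4, m);
  cd psi[4];
  for (int i = 0; i < m; ++i) {
    embed_one(x12(i, 0), x12(i, 1), theta.begin(), layers, final_encoding,
              psi, (cd *)0, 0);
    for (int k = 0; k < 4; ++k) {
      out(k, i).r = psi[k].real();
      out(k, i).i = psi[k].imag();
    }
  }
  return out;
}

// Batch Hilbert-Schmidt cost C = 1 - Dhs/2 over two class batches, with the
// gradient wrt the 2 x n linear weights and the 3L circuit angles.
// fa, fb: per-class feature matrices (rows = samples); w: 2 x n.
// [[Rcpp::export]]
List qml_cost_grad_cpp(NumericMatrix fa, NumericMatrix fb, NumericMatrix w,
                       NumericVector theta, int layers, bool final_encoding,
                       bool want_grad) {
  int ma = fa.nrow(), mb = fb.nrow(), n = w.ncol();
  if (w.nrow() != 2) stop("w must have 2 rows");
  if (fa.ncol() != n || fb.ncol() != n)
    stop("feature dimension does not match the linear weights");
  if (ma == 0 || mb == 0) stop("both class batches must be non-empty");
  if ((int)theta.size() != 3 * layers)
    stop("theta must have length 3 * layers");

  int m = ma + mb;
  int ntan = want_grad ? (2 + 3 * layers) : 0;
  std::vector<cd> states(4 * m);
  std::vector<cd> tans(want_grad ? (size_t)4 * ntan * m : 0);

  for (int i = 0; i < m; ++i) {
    const NumericMatrix &f = (i < ma) ? fa : fb;
    int r = (i < ma) ? i : i - ma;
    double x1 = 0, x2 = 0;
    for (int j = 0; j < n; ++j) {
      x1 += w(0, j) * f(r, j);
      x2 += w(1, j) * f(r, j);
    }
    embed_one(x1, x2, theta.begin(), layers, final_encoding, &states[4 * i],
              want_grad ? &tans[(size_t)4 * ntan * i] : (cd *)0, ntan);
  }

  double wa = 1.0 / ((double)ma * ma);
  double wb = 1.0 / ((double)mb * mb);
  double wab = -1.0 / ((double)ma * mb);  // each ordered cross pair once

  double D = 0.0;
  NumericVector gtheta(3 * layers);
  NumericMatrix gx(m, 2);

  for (int u = 0; u < m; ++u) {
    const cd *pu = &states[4 * u];
    for (int v = 0; v < m; ++v) {
      const cd *pv = &states[4 * v];
      double wt = (u < ma) == (v < ma) ? ((u < ma) ? wa : wb) : wab;
      cd s(0, 0);
      for (int k = 0; k < 4; ++k) s += std::conj(pu[k]) * pv[k];
      D += wt * std::norm(s);
      if (!want_grad) continue;
      cd cs = std::conj(s);
      const cd *tu = &tans[(size_t)4 * ntan * u];
      const cd *tv = &tans[(size_t)4 * ntan * v];
      for (int p = 0; p < ntan; ++p) {
        cd du(0, 0), dv(0, 0);
        for (int k = 0; k < 4; ++k) {
          du += std::conj(tu[4 * p + k]) * pv[k];
          dv += std::conj(pu[k]) * tv[4 * p + k];
        }
        double cu = 2.0 * wt * (cs * du).real();
        double cv = 2.0 * wt * (cs * dv).real();
        if (p < 2) {
          gx(u, p) += cu;
          gx(v, p) += cv;
        } else {
          gtheta[p - 2] += cu + cv;
        }
      }
    }
  }

  double cost = 1.0 - 0.5 * D;
  if (!want_grad)
    return List::create(Named("cost") = cost);

  // dC/d. = -1/2 dD/d.; chain x-gradients through x = W f
  NumericMatrix gw(2, n);
  for (int u = 0; u < m; ++u) {
    const NumericMatrix &f = (u < ma) ? fa : fb;
    int r = (u < ma) ? u : u - ma;
    for (int q = 0; q < 2; ++q) {
      double g = -0.5 * gx(u, q);
      for (int j = 0; j < n; ++j) gw(q, j) += g * f(r, j);
    }
  }
  for (int p = 0; p < 3 * layers; ++p) gtheta[p] *= -0.5;

  return List::create(Named("cost") = cost, Named("grad_weights") = gw,
                      Named("grad_thetas") = gtheta);
}
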