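// Exact statevector simulation of few-qubit circuits.
//
// Conventions (match the R layer):
//  - qubit 0 is the MOST significant bit of the basis index;
//    for n qubits, wire w corresponds to bit (n-1-w) of the index.
//  - gate codes: 1 X, 2 Y, 3 Z, 4 H, 5 S, 6 RX, 7 RY, 8 RZ, 9 U3, 10 CNOT
//  - angles: one row per op, 3 columns (unused columns ignored).
//  - CNOT: w1 = control, w2 = target.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cd;

static const cd IU(0.0, 1.0);

// row-major 2x2: U[0]=u00 U[1]=u01 U[2]=u10 U[3]=u11
static void gate2x2(int code, const double* th, cd* U) {
  switch (code) {
  case 1: U[0] = 0; U[1] = 1; U[2] = 1; U[3] = 0; break;                  // X
  case 2: U[0] = 0; U[1] = -IU; U[2] = IU; U[3] = 0; break;               // Y
  case 3: U[0] = 1; U[1] = 0; U[2] = 0; U[3] = -1; break;                 // Z
  case 4: { double s = 1.0 / std::sqrt(2.0);
            U[0] = s; U[1] = s; U[2] = s; U[3] = -s; } break;             // H
  case 5: U[0] = 1; U[1] = 0; U[2] = 0; U[3] = IU; break;                 // S
  case 6: { double c = std::cos(th[0] / 2), s = std::sin(th[0] / 2);
            U[0] = c; U[1] = -IU * s; U[2] = -IU * s; U[3] = c; } break;  // RX
  case 7: { double c = std::cos(th[0] / 2), s = std::sin(th[0] / 2);
            U[0] = c; U[1] = -s; U[2] = s; U[3] = c; } break;             // RY
  case 8: U[0] = std::exp(-IU * (th[0] / 2)); U[1] = 0; U[2] = 0;
          U[3] = std::exp(IU * (th[0] / 2)); break;                       // RZ
  case 9: { double c = std::cos(th[0] / 2), s = std::sin(th[0] / 2);
            U[0] = c;
            U[1] = -std::exp(IU * th[2]) * s;
            U[2] = std::exp(IU * th[1]) * s;
            U[3] = std::exp(IU * (th[1] + th[2])) * c; } break;           // U3
  default: stop("unknown gate code");
  }
}

// derivative of the 2x2 gate w.r.t. angle k (0-based); false if the gate has
// no angle at that position
static bool dgate2x2(int code, const double* th, int k, cd* D) {
  double c, s;
  switch (code) {
  case 6:  // RX
    if (k != 0) return false;
    c = std::cos(th[0] / 2); s = std::sin(th[0] / 2);
    D[0] = -0.5 * s; D[1] = -0.5 * IU * c; D[2] = -0.5 * IU * c; D[3] = -0.5 * s;
    return true;
  case 7:  // RY
    if (k != 0) return false;
    c = std::cos(th[0] / 2); s = std::sin(th[0] / 2);
    D[0] = -0.5 * s; D[1] = -0.5 * c; D[2] = 0.5 * c; D[3] = -0.5 * s;
    return true;
  case 8:  // RZ
    if (k != 0) return false;
    D[0] = -0.5 * IU * std::exp(-IU * (th[0] / 2)); D[1] = 0; D[2] = 0;
    D[3] = 0.5 * IU * std::exp(IU * (th[0] / 2));
    return true;
  case 9:  // U3(theta, phi, lambda)
    c = std::cos(th[0] / 2); s = std::sin(th[0] / 2);
    if (k == 0) {
      D[0] = -0.5 * s;
      D[1] = -0.5 * std::exp(IU * th[2]) * c;
      D[2] = 0.5 * std::exp(IU * th[1]) * c;
      D[3] = -0.5 * std::exp(IU * (th[1] + th[2])) * s;
      return true;
    } else if (k == 1) {
      D[0] = 0; D[1] = 0;
      D[2] = IU * std::exp(IU * th[1]) * s;
      D[3] = IU * std::exp(IU * (th[1] + th[2])) * c;
      return true;
    } else if (k == 2) {
      D[0] = 0;
      D[1] = -IU * std::exp(IU * th[2]) * s;
      D[2] = 0;
      D[3] = IU * std::exp(IU * (th[1] + th[2])) * c;
      return true;
    }
    return false;
  default:
    return false;
  }
}

static void apply1q(std::vector<cd>& v, int n, int wire, const cd* U) {
  size_t stride = (size_t)1 << (n - 1 - wire);
  size_t N = v.size();
  for (size_t base = 0; base < N; base += 2 * stride) {
    for (size_t i = base; i < base + stride; ++i) {
      cd a = v[i], b = v[i + stride];
      v[i]          = U[0] * a + U[1] * b;
      v[i + stride] = U[2] * a + U[3] * b;
    }
  }
}

static void applyCNOT(std::vector<cd>& v, int n, int ctrl, int tgt) {
  size_t cm = (size_t)1 << (n - 1 - ctrl);
  size_t tm = (size_t)1 << (n - 1 - tgt);
  size_t N = v.size();
  for (size_t i = 0; i < N; ++i)
    if ((i & cm) && !(i & tm)) std::swap(v[i], v[i | tm]);
}

static void apply_op(std::vector<cd>& v, int n, int code, int w1, int w2,
                     const double* th, bool dagger) {
  if (code == 10) { applyCNOT(v, n, w1, w2); return; }  // self-inverse
  cd U[4];
  gate2x2(code, th, U);
  if (dagger) {
    cd Ud[4] = { std::conj(U[0]), std::conj(U[2]),
                 std::conj(U[1]), std::conj(U[3]) };
    apply1q(v, n, w1, Ud);
  } else {
    apply1q(v, n, w1, U);
  }
}

static std::vector<cd> as_state(const ComplexVector& x) {
  std::vector<cd> v(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) v[i] = cd(x[i].r, x[i].i);
  return v;
}

static ComplexVector as_rcomplex(const std::vector<cd>& v) {
  ComplexVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    out[i].r = v[i].real(); out[i].i = v[i].imag();
  }
  return out;
}

// [[Rcpp::export]]
ComplexVector cpp_run_circuit(ComplexVector init, int n, IntegerVector codes,
                              IntegerVector w1, IntegerVector w2,
                              NumericMatrix angles) {
  std::vector<cd> v = as_state(init);
  int m = codes.size();
  for (int k = 0; k < m; ++k) {
    double th[3] = { angles(k, 0), angles(k, 1), angles(k, 2) };
    apply_op(v, n, codes[k], w1[k], w2[k], th, false);
  }
  return as_rcomplex(v);
}

// [[Rcpp::export]]
double cpp_expval_z(ComplexVector state, int n, int wire) {
  size_t mask = (size_t)1 << (n - 1 - wire);
  double e = 0.0;
  for (R_xlen_t i = 0; i < state.size(); ++i) {
    double p = state[i].r * state[i].r + state[i].i * state[i].i;
    e += (((size_t)i & mask) ? -p : p);
  }
  return e;
}

// [[Rcpp::export]]
NumericVector cpp_forward_expvals(ComplexVector init, int n, IntegerVector codes,
                                  IntegerVector w1, IntegerVector w2,
                                  NumericMatrix angles) {
  ComplexVector fin = cpp_run_circuit(init, n, codes, w1, w2, angles);
  NumericVector out(n);
  for (int w = 0; w < n; ++w) out[w] = cpp_expval_z(fin, n, w);
  return out;
}

// Adjoint-mode gradient of sum_w zcoef[w] * <Z_w> with respect to every angle
// position of every op. Returns the per-wire expectations of the forward pass
// and an n_ops x 3 gradient matrix.
// [[Rcpp::export]]
List cpp_adjoint_grad(ComplexVector init, int n, IntegerVector codes,
                      IntegerVector w1, IntegerVector w2, NumericMatrix angles,
                      NumericVector zcoef) {
  int m = codes.size();
  size_t N = (size_t)1 << n;
  std::vector<cd> psi = as_state(init);
  for (int k = 0; k < m; ++k) {
    double th[3] = { angles(k, 0), angles(k, 1), angles(k, 2) };
    apply_op(psi, n, codes[k], w1[k], w2[k], th, false);
  }

  NumericVector expvals(n);
  for (int w = 0; w < n; ++w) {
    size_t mask = (size_t)1 << (n - 1 - w);
    double e = 0.0;
    for (size_t i = 0; i < N; ++i) {
      double p = std::norm(psi[i]);
      e += (((i & mask) != 0) ? -p : p);
    }
    expvals[w] = e;
  }

  // lambda = O |psi>, O = sum_w zcoef[w] Z_w (diagonal)
  std::vector<cd> lam(N);
  for (size_t i = 0; i < N; ++i) {
    double d = 0.0;
    for (int w = 0; w < n; ++w) {
      size_t mask = (size_t)1 << (n - 1 - w);
      d += ((i & mask) ? -zcoef[w] : zcoef[w]);
    }
    lam[i] = d * psi[i];
  }

  NumericMatrix grad(m, 3);
  std::vector<cd> tmp;
  for (int k = m - 1; k >= 0; --k) {
    double th[3] = { angles(k, 0), angles(k, 1), angles(k, 2) };
    // undo gate on psi: psi <- U_k^dag psi
    apply_op(psi, n, codes[k], w1[k], w2[k], th, true);
    // d<O>/dtheta = 2 Re <lam | dU | psi_before>
    cd D[4];
    for (int kk = 0; kk < 3; ++kk) {
      if (!dgate2x2(codes[k], th, kk, D)) continue;
      tmp = psi;
      apply1q(tmp, n, w1[k], D);
      cd acc(0.0, 0.0);
      for (size_t i = 0; i < N; ++i) acc += std::conj(lam[i]) * tmp[i];
      grad(k, kk) = 2.0 * acc.real();
    }
    // move lambda back: lam <- U_k^dag lam
    apply_op(lam, n, codes[k], w1[k], w2[k], th, true);
  }

  return List::create(Named("expvals") = expvals, Named("grad") = grad);
}
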