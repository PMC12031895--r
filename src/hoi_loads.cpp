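// Fast triple-sum contractions of the higher-order interaction tensors.
// These duplicate the closed forms of eff_epsilon()/sel_epsilon() (R side)
// for the inner loop of the ODE right-hand side, where the S^3 sums
// dominate; the test suite checks them against the R tensor route.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// growth load G_i = sum_jk N_j N_k eps(i,j,k) and selection load
// H_i = sum_jk N_j N_k sel_eps(i,j,k) for the Gaussian three-way kernel.
// s2 are the trait variances; s2f the focal-role variances used by the
// selection integrals (they differ from s2 only for frozen traits).
// [[Rcpp::export]]
List hoi_loads_gauss(NumericVector u, NumericVector s2, NumericVector s2f,
                     NumericVector N, double kC, double t2, bool want_sel) {
  const int S = u.size();
  NumericVector G(S), H(S);
  std::vector<double> d2(S * S);
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < S; ++j) {
      double d = u[i] - u[j];
      d2[i * S + j] = d * d;
    }
  for (int i = 0; i < S; ++i) {
    double a = s2[i], af = s2f[i];
    bool same = (af == a);
    double g = 0.0, h = 0.0;
    for (int j = 0; j < S; ++j) {
      if (N[j] == 0.0) continue;
      double b = s2[j];
      for (int k = 0; k < S; ++k) {
        double w = N[j] * N[k];
        if (w == 0.0) continue;
        double c = s2[k];
        double dij = d2[i * S + j], djk = d2[j * S + k], dki = d2[k * S + i];
        double D = 1.0 + 2.0 * t2 * (a + b + c) +
                   3.0 * t2 * t2 * (a * b + a * c + b * c);
        double Qn = dij + djk + dki + 3.0 * t2 * (a * djk + b * dki + c * dij);
        double eps = kC / std::sqrt(D) * std::exp(-0.5 * t2 * Qn / D);
        g += w * eps;
        if (want_sel) {
          double Df = D, epsf = eps;
          if (!same) {
            Df = 1.0 + 2.0 * t2 * (af + b + c) +
                 3.0 * t2 * t2 * (af * b + af * c + b * c);
            double Qf = dij + djk + dki +
                        3.0 * t2 * (af * djk + b * dki + c * dij);
            epsf = kC / std::sqrt(Df) * std::exp(-0.5 * t2 * Qf / Df);
          }
          double dQ = (6.0 * t2 * (b * (u[i] - u[k]) + c * (u[i] - u[j])) +
                       2.0 * (2.0 * u[i] - u[j] - u[k])) / Df;
          h += w * af * epsf * (-0.5 * t2 * dQ);
        }
      }
    }
    G[i] = g;
    H[i] = h;
  }
  return List::create(_["G"] = G, _["H"] = H);
}

// same contractions for the hierarchical sigmoid three-way kernel
// [[Rcpp::export]]
List hoi_loads_hier(NumericVector u, NumericVector s2, NumericVector s2f,
                    NumericVector N, double kappa, double Omega, double z0,
                    bool want_sel) {
  const int S = u.size();
  NumericVector G(S), H(S);
  const double Om2 = Omega * Omega;
  const double sqrt_pi = std::sqrt(M_PI);
  for (int i = 0; i < S; ++i) {
    double a = s2[i], af = s2f[i];
    double g = 0.0, h = 0.0;
    for (int j = 0; j < S; ++j) {
      if (N[j] == 0.0) continue;
      double b = s2[j];
      for (int k = 0; k < S; ++k) {
        double w = N[j] * N[k];
        if (w == 0.0) continue;
        double c = s2[k];
        double m = z0 + u[i] - 0.5 * (u[j] + u[k]);
        double v = Om2 + 2.0 * a + 0.5 * (b + c);
        g += w * 0.5 * kappa * (std::erf(m / std::sqrt(v)) + 1.0);
        if (want_sel) {
          double vf = Om2 + 2.0 * af + 0.5 * (b + c);
          h += w * kappa * af / (sqrt_pi * std::sqrt(vf)) *
               std::exp(-m * m / vf);
        }
      }
    }
    G[i] = g;
    H[i] = h;
  }
  return List::create(_["G"] = G, _["H"] = H);
}
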