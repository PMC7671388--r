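#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// P(t) = U diag(exp(lambda * t)) Uinv for the reversible rate matrix whose
// eigendecomposition (U, lambda, Uinv) is precomputed in R. Entries are
// clamped at 0 to absorb tiny negative round-off.
static void trans_prob(const double* U, const double* Uinv,
                       const double* lambda, double t, double* P) {
  double e[4];
  for (int k = 0; k < 4; ++k) e[k] = std::exp(lambda[k] * t);
  for (int i = 0; i < 4; ++i) {
    for (int j = 0; j < 4; ++j) {
      double s = 0.0;
      for (int k = 0; k < 4; ++k)
        s += U[i + 4 * k] * e[k] * Uinv[k + 4 * j];
      P[i + 4 * j] = s > 0.0 ? s : 0.0;
    }
  }
}

// Log-likelihood of a 4-leaf unrooted tree by Felsenstein pruning with a
// discrete-Gamma rate mixture.
//
// states:  4 x npat integer matrix (0..3), rows = leaves in tree order:
//          rows 1,2 join at internal node u; rows 3,4 at node v.
// counts:  npat site-pattern counts.
// bl:      5 branch lengths (leaf1, leaf2, leaf3, leaf4, internal u-v).
// U, Uinv, lambda: eigensystem of the normalized rate matrix Q.
// pi:      stationary base frequencies.
// rates:   gamma category rates (mean 1), equal weights 1/ncat.
// [[Rcpp::export]]
double quartet_loglik_cpp(const IntegerMatrix& states,
                          const NumericVector& counts,
                          const NumericVector& bl,
                          const NumericMatrix& U,
                          const NumericMatrix& Uinv,
                          const NumericVector& lambda,
                          const NumericVector& pi,
                          const NumericVector& rates) {
  const int npat = states.ncol();
  const int ncat = rates.size();
  const double wcat = 1.0 / ncat;
  std::vector<double> site(npat, 0.0);
  double P1[16], P2[16], P3[16], P4[16], P5[16];

  for (int c = 0; c < ncat; ++c) {
    const double r = rates[c];
    trans_prob(U.begin(), Uinv.begin(), lambda.begin(), bl[0] * r, P1);
    trans_prob(U.begin(), Uinv.begin(), lambda.begin(), bl[1] * r, P2);
    trans_prob(U.begin(), Uinv.begin(), lambda.begin(), bl[2] * r, P3);
    trans_prob(U.begin(), Uinv.begin(), lambda.begin(), bl[3] * r, P4);
    trans_prob(U.begin(), Uinv.begin(), lambda.begin(), bl[4] * r, P5);
    for (int p = 0; p < npat; ++p) {
      const int s1 = states(0, p), s2 = states(1, p);
      const int s3 = states(2, p), s4 = states(3, p);
      double lv[4];
      for (int y = 0; y < 4; ++y)
        lv[y] = P3[y + 4 * s3] * P4[y + 4 * s4];
      double tot = 0.0;
      for (int x = 0; x < 4; ++x) {
        double m = 0.0;
        for (int y = 0; y < 4; ++y) m += P5[x + 4 * y] * lv[y];
        tot += pi[x] * P1[x + 4 * s1] * P2[x + 4 * s2] * m;
      }
      site[p] += wcat * tot;
    }
  }

  double ll = 0.0;
  for (int p = 0; p < npat; ++p) {
    double s = site[p];
    if (s < 1e-300) s = 1e-300;
    ll += counts[p] * std::log(s);
  }
  return ll;
}
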