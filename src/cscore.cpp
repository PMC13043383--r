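#include <Rcpp.h>
using namespace Rcpp;

// Per-gene IRLS moment estimation under the Poisson measurement model
//   X_ij | z_ij ~ Poisson(s_i z_ij),  E z_ij = mu_j,  Var z_ij = sigma_jj.
// Moment conditions (per gene j):
//   E[X_ij - s_i mu_j]                                   = 0
//   E[(X_ij - s_i mu_j)^2 - s_i mu_j - s_i^2 sigma_jj]   = 0
// solved by weighted least squares with weights 1/h_ij and 1/h_ij^2 where
// h_ij = s_i mu_j + s_i^2 sigma_jj is the count variance, iterated to
// convergence. h is floored at 1e-10 so weights stay finite.
// [[Rcpp::export]]
List cscore_moments_cpp(NumericMatrix X, NumericVector s, int max_iter,
                        double tol) {
  const int n = X.nrow(), G = X.ncol();
  std::vector<double> s2(n), s4(n);
  double ss2 = 0.0, ss4 = 0.0;
  for (int i = 0; i < n; ++i) {
    s2[i] = s[i] * s[i];
    s4[i] = s2[i] * s2[i];
    ss2 += s2[i];
    ss4 += s4[i];
  }
  NumericVector mu(G), sig(G);
  IntegerVector iters(G);
  LogicalVector conv(G);
  for (int j = 0; j < G; ++j) {
    // unit-weight initialisation
    double a = 0.0;
    for (int i = 0; i < n; ++i) a += X(i, j) * s[i];
    double m = a / ss2;
    double b = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = X(i, j) - s[i] * m;
      b += (e * e - s[i] * m) * s2[i];
    }
    double v = b / ss4;
    bool ok = false;
    int it = 0;
    while (it < max_iter) {
      ++it;
      const double vp = v > 0.0 ? v : 0.0;
      double n1 = 0.0, d1 = 0.0;
      for (int i = 0; i < n; ++i) {
        double h = s[i] * m + s2[i] * vp;
        double w = 1.0 / (h > 1e-10 ? h : 1e-10);
        n1 += X(i, j) * w * s[i];
        d1 += w * s2[i];
      }
      const double m_new = n1 / d1;
      double n2 = 0.0, d2 = 0.0;
      for (int i = 0; i < n; ++i) {
        double h = s[i] * m + s2[i] * vp;
        h = h > 1e-10 ? h : 1e-10;
        double w2 = 1.0 / (h * h);
        double e = X(i, j) - s[i] * m_new;
        n2 += (e * e - s[i] * m_new) * w2 * s2[i];
        d2 += w2 * s4[i];
      }
      const double v_new = n2 / d2;
      const double dm =
          std::abs(m_new - m) / std::max(std::abs(m), 1e-12);
      const double dv =
          std::abs(v_new - v) / std::max(std::abs(v), 1e-12);
      m = m_new;
      v = v_new;
      if (std::max(dm, dv) < tol) {
        ok = true;
        break;
      }
    }
    mu[j] = m;
    sig[j] = v;
    iters[j] = it;
    conv[j] = ok;
  }
  return List::create(_["mu"] = mu, _["sigma"] = sig,
                      _["iterations"] = iters, _["converged"] = conv);
}

// Weighted pair covariance and its null z given converged per-gene moments.
// Covariance moment E[(X_ij - s_i mu_j)(X_ik - s_i mu_k) - s_i^2 sigma_jk] = 0
// solved in one WLS step with weights 1/(h_ij h_ik). With those weights the
// slope variance under sigma_jk = 0 collapses to 1/sum(w s^4), so
// z = theta * sqrt(sum(w s^4)).  j1/j2 are 0-based column indices.
// [[Rcpp::export]]
List cscore_pairs_cpp(NumericMatrix X, NumericVector s, NumericVector mu,
                      NumericVector sig, IntegerVector j1, IntegerVector j2) {
  const int n = X.nrow(), P = j1.size();
  NumericVector theta(P), z(P);
  for (int p = 0; p < P; ++p) {
    const int a = j1[p], b = j2[p];
    const double va = sig[a] > 0.0 ? sig[a] : 0.0;
    const double vb = sig[b] > 0.0 ? sig[b] : 0.0;
    double num = 0.0, den = 0.0;
    for (int i = 0; i < n; ++i) {
      const double s2i = s[i] * s[i];
      double ha = s[i] * mu[a] + s2i * va;
      double hb = s[i] * mu[b] + s2i * vb;
      ha = ha > 1e-10 ? ha : 1e-10;
      hb = hb > 1e-10 ? hb : 1e-10;
      const double w = 1.0 / (ha * hb);
      const double ea = X(i, a) - s[i] * mu[a];
      const double eb = X(i, b) - s[i] * mu[b];
      // (ea * eb) first keeps the accumulation exactly symmetric in (a, b)
      num += w * s2i * (ea * eb);
      den += w * s2i * s2i;
    }
    theta[p] = num / den;
    z[p] = theta[p] * std::sqrt(den);
  }
  return List::create(_["theta"] = theta, _["z"] = z);
}
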