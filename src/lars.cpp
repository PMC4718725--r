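// Least-angle regression with the lasso modification, reduced to the one
// question stability selection asks: which q variables enter the
// regularization path first. Columns are standardized and the response
// centered internally, matching the usual lasso preprocessing.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// [[Rcpp::export(name = ".lars_first_q")]]
Rcpp::IntegerVector lars_first_q_cpp(const arma::mat& X0,
                                     const arma::vec& y0, int q) {
  const int n = X0.n_rows, p = X0.n_cols;
  mat X = X0;
  vec y = y0 - mean(y0);

  // standardize columns; constant columns are ignored
  std::vector<bool> usable(p, true);
  for (int j = 0; j < p; ++j) {
    double mu = mean(X.col(j));
    X.col(j) -= mu;
    double sd = norm(X.col(j));
    if (sd <= 1e-12) { usable[j] = false; continue; }
    X.col(j) /= sd;
  }

  std::vector<int> entry_order;
  std::vector<bool> entered(p, false), active(p, false);
  std::vector<int> act;           // active indices in join order
  vec beta = zeros<vec>(p);
  vec r = y;
  const double eps = 1e-10;
  const double tss = dot(y, y);
  int max_steps = 8 * q + 16;

  for (int step = 0; step < max_steps; ++step) {
    if ((int)entry_order.size() >= q) break;
    // stop once the fit is essentially perfect (dev.ratio > 0.999); further
    // path entries would only chase numerical noise
    if (tss > 0 && dot(r, r) / tss < 1e-3) break;
    vec c = X.t() * r;
    // candidate with maximal absolute correlation among inactive
    double C = -1.0; int jmax = -1;
    for (int j = 0; j < p; ++j) {
      if (!usable[j] || active[j]) continue;
      double a = std::fabs(c(j));
      if (a > C + 1e-14) { C = a; jmax = j; }
    }
    double Cact = act.empty() ? -1.0 : std::fabs(c(act[0]));
    if (act.empty()) {
      if (jmax < 0 || C < eps) break;
      active[jmax] = true; act.push_back(jmax);
      if (!entered[jmax]) { entered[jmax] = true; entry_order.push_back(jmax); }
      continue;
    }
    C = std::max(C, Cact);
    if (C < eps) break;

    const int k = act.size();
    mat XA(n, k); vec s(k);
    for (int i = 0; i < k; ++i) {
      XA.col(i) = X.col(act[i]);
      s(i) = (c(act[i]) >= 0) ? 1.0 : -1.0;
    }
    mat G = XA.t() * XA;
    G.diag() += 1e-10;
    vec w0;
    if (!solve(w0, G, s)) break;
    double Anorm = 1.0 / std::sqrt(std::max(dot(s, w0), 1e-12));
    vec w = Anorm * w0;            // step direction for beta over act
    vec u = XA * w;                // equiangular direction
    vec a = X.t() * u;

    // step length to the next entering variable
    double gamma = C / Anorm;      // full step (hits zero correlation)
    int jenter = -1;
    for (int j = 0; j < p; ++j) {
      if (!usable[j] || active[j]) continue;
      double g1 = (C - c(j)) / (Anorm - a(j));
      double g2 = (C + c(j)) / (Anorm + a(j));
      if (g1 > eps && g1 < gamma - 1e-14) { gamma = g1; jenter = j; }
      if (g2 > eps && g2 < gamma - 1e-14) { gamma = g2; jenter = j; }
    }
    // lasso modification: drop a variable whose coefficient hits zero
    double gdrop = datum::inf; int idrop = -1;
    for (int i = 0; i < k; ++i) {
      if (std::fabs(w(i)) < 1e-14) continue;
      double g = -beta(act[i]) / w(i);
      if (g > eps && g < gdrop) { gdrop = g; idrop = i; }
    }
    bool dropping = (idrop >= 0 && gdrop < gamma - 1e-14);
    if (dropping) gamma = gdrop;

    for (int i = 0; i < k; ++i) beta(act[i]) += gamma * w(i);
    r -= gamma * u;

    if (dropping) {
      int j = act[idrop];
      beta(j) = 0.0;
      active[j] = false;
      act.erase(act.begin() + idrop);
    } else if (jenter >= 0) {
      active[jenter] = true; act.push_back(jenter);
      if (!entered[jenter]) {
        entered[jenter] = true; entry_order.push_back(jenter);
      }
    } else {
      break;                       // reached the unconstrained fit
    }
  }

  const int m = std::min<int>(q, entry_order.size());
  Rcpp::IntegerVector out(m);
  for (int i = 0; i < m; ++i) out[i] = entry_order[i] + 1;  // 1-based
  return out;
}
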