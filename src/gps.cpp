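// Inner generalized path-seeking loop on the working least-squares problem
//   R(beta) = (1/2n) (z - X beta)' M (z - X beta),   M = A + eps I = C'C,
// so that g_j = -dR/dbeta_j = (1/n) xhat_j' (yhat - Xhat beta) without ever
// forming Xhat = C X. Each step moves a single coordinate by at most deltaV;
// the gradient is maintained incrementally through lazily cached Gram
// columns G_j = (1/n) X' M x_j.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline double sgn(double x) { return (x > 0) - (x < 0); }

// [[Rcpp::export(name = ".gps_inner_cpp")]]
Rcpp::List gps_inner_cpp(const arma::mat& X, const arma::mat& M,
                         const arma::vec& z, const arma::vec& beta0,
                         double a, double deltaV, double tauTol,
                         int maxSteps, double vStart, double vMax) {
  const uword n = X.n_rows, p = X.n_cols;
  const double q = 2.0 / (a * (a - 1.0));
  const double c2 = std::pow((2.0 - a) / (a - 1.0), 2);

  vec beta = beta0;
  vec r = z - X * beta;
  vec g = X.t() * (M * r) / double(n);

  std::vector<vec> gram(p);
  std::vector<bool> haveGram(p, false);

  std::vector<double> recV, recVal;
  std::vector<int> recCoord, recNnz;
  recV.reserve(maxSteps); recVal.reserve(maxSteps);
  recCoord.reserve(maxSteps); recNnz.reserve(maxSteps);

  int nnz = 0;
  for (uword j = 0; j < p; ++j) if (beta[j] != 0.0) ++nnz;

  // penalty slopes P'(|beta_j|): only the moved coordinate changes per
  // step, so maintain the vector instead of recomputing p sqrts per step
  vec pslope(p);
  for (uword j = 0; j < p; ++j)
    pslope[j] = q / (2.0 * std::sqrt(q * std::abs(beta[j]) + c2));

  double v = vStart;
  bool converged = false;
  int steps = 0;

  while (steps < maxSteps && v < vMax) {
    // tau_j = g_j / P'(|beta_j|); pick j* from the sign-mismatch set S
    // if nonempty, else globally; lowest index wins ties
    double best = -1.0, bestS = -1.0;
    uword jbest = 0, jbestS = 0;
    bool anyS = false;
    const double* gp = g.memptr();
    const double* pp = pslope.memptr();
    const double* bp = beta.memptr();
    for (uword j = 0; j < p; ++j) {
      double tau = gp[j] / pp[j];
      double at = std::abs(tau);
      if (at > best) { best = at; jbest = j; }
      // ratios inside the stopping tolerance are numerically zero and
      // carry no sign: excluding them from S prevents a livelock of
      // full-size corrections on coordinates already at their optimum
      if (at > tauTol && tau * bp[j] < 0.0 && at > bestS) {
        bestS = at; jbestS = j; anyS = true;
      }
    }
    if (best <= tauTol) { converged = true; break; }
    uword jstar = anyS ? jbestS : jbest;

    double tau = g[jstar] / pslope[jstar];
    double old = beta[jstar];
    double prop = old + deltaV * sgn(tau);
    // zero-crossing clamp: never step across zero, land on it instead
    if (old != 0.0 && prop * old < 0.0) prop = 0.0;
    double d = prop - old;

    if (old == 0.0 && prop != 0.0) ++nnz;
    if (old != 0.0 && prop == 0.0) --nnz;
    beta[jstar] = prop;
    pslope[jstar] = q / (2.0 * std::sqrt(q * std::abs(prop) + c2));

    if (!haveGram[jstar]) {
      gram[jstar] = X.t() * (M * X.col(jstar)) / double(n);
      haveGram[jstar] = true;
    }
    g -= d * gram[jstar];

    v += deltaV;
    ++steps;
    recV.push_back(v);
    recCoord.push_back(int(jstar) + 1);
    recVal.push_back(prop);
    recNnz.push_back(nnz);
  }

  return Rcpp::List::create(
    Rcpp::Named("v") = recV,
    Rcpp::Named("coord") = recCoord,
    Rcpp::Named("value") = recVal,
    Rcpp::Named("nnz") = recNnz,
    Rcpp::Named("beta") = beta,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("steps") = steps,
    Rcpp::Named("vEnd") = v);
}
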