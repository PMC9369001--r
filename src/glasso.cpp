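#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Graphical lasso by block coordinate descent (Banerjee/Friedman scheme).
// Off-diagonal L1 penalty only, so W_ii = S_ii at the optimum (the same
// convention as scikit-learn's graphical_lasso); lambda = 0 reduces to the
// direct inverse.  Each column update solves an L1 regression against the
// current working covariance W11 by cyclic coordinate descent.
//
// Returns Theta (precision), W (working covariance), iteration count and a
// convergence flag.  Outer convergence: mean absolute change of the
// off-diagonal of W over one sweep below tol * mean |S_offdiag|.
// [[Rcpp::export(name = ".glassoCpp")]]
Rcpp::List glassoCpp(const arma::mat& S, double lambda, double tol = 1e-4,
                     int maxIter = 200) {
  const int p = S.n_rows;
  if (p == 1) {
    mat Theta(1, 1); Theta(0, 0) = 1.0 / S(0, 0);
    return Rcpp::List::create(Rcpp::Named("theta") = Theta,
                              Rcpp::Named("w") = S,
                              Rcpp::Named("iterations") = 0,
                              Rcpp::Named("converged") = true);
  }

  mat W = S;                       // working covariance, diag fixed at S_ii
  mat B(p - 1, p, fill::zeros);    // per-column lasso coefficients

  double offAbs = 0.0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) offAbs += std::fabs(S(i, j));
  offAbs /= (double)(p * (p - 1));
  if (offAbs <= 0) offAbs = 1.0;   // diagonal input: converges immediately

  const double innerTol = std::max(1e-9, tol * 1e-3 * offAbs);
  const int maxInner = 1000;
  bool converged = false;
  int iter = 0;

  uvec all = regspace<uvec>(0, p - 1);

  for (iter = 1; iter <= maxIter; ++iter) {
    double sweepDelta = 0.0;
    for (int j = 0; j < p; ++j) {
      uvec idx = find(all != (unsigned)j);
      mat V = W.submat(idx, idx);       // (p-1) x (p-1), symmetric
      vec s12 = S.col(j); s12 = s12.elem(idx);
      vec beta = B.col(j);

      for (int inner = 0; inner < maxInner; ++inner) {
        double d = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          const double vkk = V(k, k);
          double r = s12(k) - dot(V.col(k), beta) + vkk * beta(k);
          double bnew = soft(r, lambda) / vkk;
          double ch = std::fabs(bnew - beta(k));
          if (ch > d) d = ch;
          beta(k) = bnew;
        }
        if (d < innerTol) break;
      }

      vec w12 = V * beta;
      vec old = W.col(j); old = old.elem(idx);
      sweepDelta += mean(abs(w12 - old));
      for (int k = 0; k < p - 1; ++k) {
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
      B.col(j) = beta;
    }
    sweepDelta /= (double)p;
    if (sweepDelta < tol * offAbs) { converged = true; break; }
  }

  // Recover Theta from the final (W, B) blocks.
  mat Theta(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    uvec idx = find(all != (unsigned)j);
    vec beta = B.col(j);
    vec w12 = W.col(j); w12 = w12.elem(idx);
    double th = 1.0 / (W(j, j) - dot(w12, beta));
    Theta(j, j) = th;
    for (int k = 0; k < p - 1; ++k) Theta(idx(k), j) = -beta(k) * th;
  }
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(Rcpp::Named("theta") = Theta,
                            Rcpp::Named("w") = W,
                            Rcpp::Named("iterations") = iter,
                            Rcpp::Named("converged") = converged);
}
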