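#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft_threshold(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Block coordinate-descent graphical lasso (Friedman-style sweeps) with an
// unpenalized diagonal: maximizes
//   log det(Theta) - tr(S Theta) - lambda * sum_{i != j} |theta_ij|.
// Each sweep solves, for every column j, the lasso subproblem
//   min_b  0.5 b' W11 b - b' s12 + lambda |b|_1
// by cyclic coordinate descent, then updates the working covariance W.
// The precision matrix is recovered from the regression coefficients, so
// entries zeroed by the soft threshold are exact zeros.
//
// sigma_init / beta_init allow warm starts along a penalty path.
// [[Rcpp::export]]
Rcpp::List glasso_cd(const arma::mat& S, const double lambda,
                     const double tol, const int max_sweeps,
                     Rcpp::Nullable<Rcpp::NumericMatrix> sigma_init = R_NilValue,
                     Rcpp::Nullable<Rcpp::NumericMatrix> beta_init = R_NilValue) {
  const uword p = S.n_rows;
  mat W(p, p);
  mat B(p, p, fill::zeros);
  if (sigma_init.isNotNull()) {
    W = Rcpp::as<mat>(sigma_init.get());
    W.diag() = S.diag();  // diagonal is never penalized: sigma_ii = s_ii
  } else {
    W = S;
  }
  if (beta_init.isNotNull()) B = Rcpp::as<mat>(beta_init.get());

  const int max_inner = 1000;
  double delta = 0.0;
  bool converged = false;
  int sweeps_used = 0;
  vec c(p);  // running W11 * beta for the active column

  for (int sweep = 1; sweep <= max_sweeps; ++sweep) {
    sweeps_used = sweep;
    delta = 0.0;
    for (uword j = 0; j < p; ++j) {
      // c_k = sum_l W(k, l) B(l, j); B(j, j) stays 0 so l = j drops out.
      // Kept incrementally: each coefficient change is an axpy update,
      // and coordinates left unchanged cost O(1).
      c = W * B.col(j);
      for (int it = 0; it < max_inner; ++it) {
        double dmax = 0.0;
        // glmnet-style: sweep all coordinates first, then iterate the
        // active (nonzero) set only, re-checking the full set on exit
        const bool full_pass = (it == 0);
        bool any_active = false;
        for (uword k = 0; k < p; ++k) {
          if (k == j) continue;
          const double bold = B(k, j);
          if (!full_pass && bold == 0.0) continue;
          const double grad = S(k, j) - c(k) + W(k, k) * bold;
          const double bnew = soft_threshold(grad, lambda) / W(k, k);
          const double diff = std::abs(bnew - bold);
          if (diff > dmax) dmax = diff;
          if (bnew != bold) {
            B(k, j) = bnew;
            c += (bnew - bold) * W.col(k);
            any_active = true;
          }
        }
        if (dmax < tol) {
          if (full_pass) break;
          // converged on the active set: one confirming full pass
          double dfull = 0.0;
          for (uword k = 0; k < p; ++k) {
            if (k == j) continue;
            const double bold = B(k, j);
            const double grad = S(k, j) - c(k) + W(k, k) * bold;
            const double bnew = soft_threshold(grad, lambda) / W(k, k);
            const double diff = std::abs(bnew - bold);
            if (diff > dfull) dfull = diff;
            if (bnew != bold) {
              B(k, j) = bnew;
              c += (bnew - bold) * W.col(k);
            }
          }
          if (dfull < tol) break;
        }
        (void)any_active;
      }
      for (uword k = 0; k < p; ++k) {  // c now equals W11 * beta
        if (k == j) continue;
        const double diff = std::abs(c(k) - W(k, j));
        if (diff > delta) delta = diff;
        W(k, j) = c(k);
        W(j, k) = c(k);
      }
    }
    if (delta < tol) {
      converged = true;
      break;
    }
  }

  // Recover Theta from the per-column regressions:
  //   theta_jj = 1 / (w_jj - w12' beta),  theta_12 = -beta * theta_jj
  mat theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    const double denom = W(j, j) - dot(W.col(j), B.col(j));
    theta(j, j) = 1.0 / denom;
    for (uword k = 0; k < p; ++k) {
      if (k == j) continue;
      theta(k, j) = -B(k, j) * theta(j, j);
    }
  }
  // Symmetrize; keep entries that were soft-thresholded to zero exact
  for (uword j = 0; j < p; ++j) {
    for (uword k = j + 1; k < p; ++k) {
      if (B(k, j) == 0.0 && B(j, k) == 0.0) {
        theta(k, j) = 0.0;
        theta(j, k) = 0.0;
      } else {
        const double m = 0.5 * (theta(k, j) + theta(j, k));
        theta(k, j) = m;
        theta(j, k) = m;
      }
    }
  }

  return Rcpp::List::create(Rcpp::Named("theta") = theta,
                            Rcpp::Named("sigma") = W,
                            Rcpp::Named("beta") = B,
                            Rcpp::Named("sweeps") = sweeps_used,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("max_change") = delta);
}
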