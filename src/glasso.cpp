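#include <Rcpp.h>
using namespace Rcpp;

// Graphical lasso by block coordinate descent over columns of the
// covariance estimate W, with an active-set coordinate-descent lasso
// solve for each column. Maximizes
//   log det(Theta) - tr(S Theta) - lambda * sum_{i != j} |Theta_ij|.
// Convergence: max absolute change of any W entry in a full sweep < tol,
// or max_sweeps sweeps. Warm starts pass the previous W and B (per-column
// regression coefficients) along a lambda path.

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// [[Rcpp::export]]
List glasso_cd(NumericMatrix Sin, double lambda,
               Nullable<NumericMatrix> W0 = R_NilValue,
               Nullable<NumericMatrix> B0 = R_NilValue,
               double tol = 1e-6, int max_sweeps = 10000) {
  const int p = Sin.ncol();
  std::vector<double> S(p * p), W(p * p), B(p * p, 0.0);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < p; ++i) S[i + j * p] = Sin(i, j);

  if (W0.isNotNull()) {
    NumericMatrix Wi(W0.get());
    for (int j = 0; j < p; ++j)
      for (int i = 0; i < p; ++i) W[i + j * p] = Wi(i, j);
  } else {
    W = S;
  }
  // off-diagonal penalty only: the diagonal of W stays at S's diagonal
  for (int i = 0; i < p; ++i) W[i + i * p] = S[i + i * p];

  if (B0.isNotNull()) {
    NumericMatrix Bi(B0.get());
    for (int j = 0; j < p; ++j)
      for (int i = 0; i < p; ++i) B[i + j * p] = Bi(i, j);
  }

  std::vector<double> beta(p);
  std::vector<char> isact(p);
  std::vector<int> act;
  act.reserve(p);
  double inner_tol = tol * 0.1;
  if (inner_tol <= 0) inner_tol = 1e-8;

  int sweeps = 0;
  bool converged = false;

  for (sweeps = 0; sweeps < max_sweeps; ++sweeps) {
    double max_change = 0.0;
    for (int j = 0; j < p; ++j) {
      const double *Sj = &S[j * p];
      for (int k = 0; k < p; ++k) {
        beta[k] = B[k + j * p];
        isact[k] = (k != j && beta[k] != 0.0);
      }
      beta[j] = 0.0;

      bool full_pass = true;
      for (int it = 0; it < 1000; ++it) {
        act.clear();
        for (int k = 0; k < p; ++k)
          if (isact[k]) act.push_back(k);
        double max_db = 0.0;
        if (full_pass) {
          for (int k = 0; k < p; ++k) {
            if (k == j) continue;
            const double *Wk = &W[k * p];
            double g = Sj[k];
            for (int a : act)
              if (a != k) g -= Wk[a] * beta[a];
            double bnew = soft(g, lambda) / Wk[k];
            double db = std::abs(bnew - beta[k]);
            if (db > max_db) max_db = db;
            if (bnew != beta[k]) {
              if (beta[k] == 0.0 && bnew != 0.0) {
                isact[k] = 1;
                act.push_back(k);
              } else if (bnew == 0.0) {
                isact[k] = 0;
                act.erase(std::find(act.begin(), act.end(), k));
              }
              beta[k] = bnew;
            }
          }
        } else {
          for (size_t ai = 0; ai < act.size(); ++ai) {
            int k = act[ai];
            const double *Wk = &W[k * p];
            double g = Sj[k];
            for (int a : act)
              if (a != k) g -= Wk[a] * beta[a];
            double bnew = soft(g, lambda) / Wk[k];
            double db = std::abs(bnew - beta[k]);
            if (db > max_db) max_db = db;
            if (bnew == 0.0 && beta[k] != 0.0) isact[k] = 0;
            beta[k] = bnew;
          }
        }
        if (max_db < inner_tol) {
          if (full_pass) break;   // verified on a full pass
          full_pass = true;       // active set stable; verify
        } else {
          full_pass = false;      // keep refining the active set
        }
      }

      // w12 = W11 beta (sum over nonzero beta only)
      act.clear();
      for (int k = 0; k < p; ++k)
        if (k != j && beta[k] != 0.0) act.push_back(k);
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        const double *Wk = &W[k * p];
        double w = 0.0;
        for (int a : act) w += Wk[a] * beta[a];
        double ch = std::abs(w - W[k + j * p]);
        if (ch > max_change) max_change = ch;
        W[k + j * p] = w;
        W[j + k * p] = w;
        B[k + j * p] = beta[k];
      }
      // clear stale coefficients
      for (int k = 0; k < p; ++k)
        if (k != j && beta[k] == 0.0) B[k + j * p] = 0.0;
    }
    if (max_change < tol) { converged = true; ++sweeps; break; }
  }

  // Recover Theta from final W and B:
  //   theta_jj = 1 / (w_jj - w12' beta_j);  theta_12 = -beta_j * theta_jj
  NumericMatrix Theta(p, p), Wout(p, p), Bout(p, p);
  for (int j = 0; j < p; ++j) {
    double q = W[j + j * p];
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      q -= W[k + j * p] * B[k + j * p];
    }
    double tjj = 1.0 / q;
    Theta(j, j) = tjj;
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      Theta(k, j) = -B[k + j * p] * tjj;
    }
  }
  // symmetrize; keep exact zeros where both directions are zero
  for (int i = 0; i < p; ++i) {
    for (int j = i + 1; j < p; ++j) {
      if (B[i + j * p] == 0.0 && B[j + i * p] == 0.0) {
        Theta(i, j) = 0.0;
        Theta(j, i) = 0.0;
      } else {
        double v = 0.5 * (Theta(i, j) + Theta(j, i));
        Theta(i, j) = v;
        Theta(j, i) = v;
      }
    }
  }
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < p; ++i) {
      Wout(i, j) = W[i + j * p];
      Bout(i, j) = B[i + j * p];
    }

  return List::create(_["theta"] = Theta, _["w"] = Wout, _["beta"] = Bout,
                      _["sweeps"] = sweeps, _["converged"] = converged);
}
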