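#include <Rcpp.h>
using namespace Rcpp;

// Piecewise-linear expected trajectories at integer stages 0..E.
//
// pos: B x L matrix of 1-based event positions (column l = threshold level l,
//      increasing within each row). thresholds: length-L z values.
// Trajectory anchors per biomarker: (0,0), (pos[b,l], z_l), (E, z_max);
// later anchors win on ties (possible only at t = E).
// Returns (E+1) x B matrix.
// [[Rcpp::export]]
NumericMatrix traj_matrix_cpp(IntegerMatrix pos, NumericVector thresholds,
                              double z_max, int E) {
  const int B = pos.nrow(), L = pos.ncol();
  NumericMatrix G(E + 1, B);
  std::vector<double> xs(L + 2), ys(L + 2);
  for (int b = 0; b < B; ++b) {
    xs[0] = 0.0; ys[0] = 0.0;
    for (int l = 0; l < L; ++l) {
      xs[l + 1] = pos(b, l);
      ys[l + 1] = thresholds[l];
    }
    xs[L + 1] = E; ys[L + 1] = z_max;
    int m = L + 2;
    // drop anchors sharing x with a later anchor (last one wins)
    std::vector<double> x2, y2;
    for (int i = 0; i < m; ++i) {
      if (i + 1 < m && xs[i + 1] == xs[i]) continue;
      x2.push_back(xs[i]); y2.push_back(ys[i]);
    }
    int seg = 0, ms = (int)x2.size();
    for (int k = 0; k <= E; ++k) {
      while (seg + 2 < ms && x2[seg + 1] < k) ++seg;
      const double x0 = x2[seg], x1 = x2[seg + 1];
      G(k, b) = (k <= x0) ? y2[seg]
        : y2[seg] + (y2[seg + 1] - y2[seg]) * (k - x0) / (x1 - x0);
    }
  }
  return G;
}

// Per-subject, per-stage Gaussian log-likelihood.
// X: n x B z-scores; G: (E+1) x B expected values; sigma: length B.
// M(i,k) = sum_j log N(X(i,j); G(k,j), sigma(j)).
// [[Rcpp::export]]
NumericMatrix stage_loglik_cpp(NumericMatrix X, NumericMatrix G, NumericVector sigma) {
  const int n = X.nrow(), B = X.ncol(), K = G.nrow();
  if (G.ncol() != B) stop("X and G must have the same number of biomarkers");
  if (sigma.size() != B) stop("sigma must have one entry per biomarker");
  NumericMatrix M(n, K);
  std::vector<double> inv2(B);
  double base = 0.0;
  for (int j = 0; j < B; ++j) {
    if (!(sigma[j] > 0)) stop("sigma must be positive");
    inv2[j] = 0.5 / (sigma[j] * sigma[j]);
    base += -0.5 * std::log(2.0 * M_PI) - std::log(sigma[j]);
  }
  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < n; ++i) {
      double s = base;
      for (int j = 0; j < B; ++j) {
        const double d = X(i, j) - G(k, j);
        s -= d * d * inv2[j];
      }
      M(i, k) = s;
    }
  }
  return M;
}

// Log marginal likelihood per subject under a uniform stage prior:
// log( (1/(E+1)) sum_k exp(M(i,k)) ), computed stably.
// [[Rcpp::export]]
NumericVector seq_logmarg_cpp(NumericMatrix X, NumericMatrix G, NumericVector sigma) {
  NumericMatrix M = stage_loglik_cpp(X, G, sigma);
  const int n = M.nrow(), K = M.ncol();
  const double logK = std::log((double)K);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double mx = M(i, 0);
    for (int k = 1; k < K; ++k) mx = std::max(mx, M(i, k));
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += std::exp(M(i, k) - mx);
    out[i] = mx + std::log(s) - logK;
  }
  return out;
}

// Weighted data log-likelihood sum_i w_i log P(x_i | S).
// [[Rcpp::export]]
double wseq_loglik_cpp(NumericMatrix X, NumericMatrix G, NumericVector sigma,
                       NumericVector w) {
  if (w.size() != X.nrow()) stop("one weight per subject is required");
  NumericVector lm = seq_logmarg_cpp(X, G, sigma);
  double s = 0.0;
  for (int i = 0; i < lm.size(); ++i) s += w[i] * lm[i];
  return s;
}
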