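// Coordinate-descent LASSO with an unpenalized intercept (via centering),
// solved along a descending lambda path with warm starts. Covariance updates
// (precomputed X'X, X'y on the centered data) keep each sweep O(p^2), which
// is what makes the 100-run stability selection and 500-fit bootstrap cheap
// enough to run per RNA.
//
// Objective: (1/2n) * ||y - b0 - X b||^2 + lambda * ||b||_1

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct CenteredStats {
  int p;
  int n;
  std::vector<double> XtX;  // p x p, centered crossprod / n (column-major)
  std::vector<double> Xy;   // centered X'y / n
  std::vector<double> xbar;
  double ybar;
};

CenteredStats make_stats(const NumericMatrix& X, const NumericVector& y,
                         const std::vector<int>& rows) {
  const int p = X.ncol();
  const int n = static_cast<int>(rows.size());
  CenteredStats s;
  s.p = p;
  s.n = n;
  s.xbar.assign(p, 0.0);
  s.ybar = 0.0;
  for (int r : rows) {
    s.ybar += y[r];
    for (int j = 0; j < p; ++j) s.xbar[j] += X(r, j);
  }
  s.ybar /= n;
  for (int j = 0; j < p; ++j) s.xbar[j] /= n;
  s.XtX.assign(static_cast<size_t>(p) * p, 0.0);
  s.Xy.assign(p, 0.0);
  std::vector<double> xc(p);
  for (int r : rows) {
    const double yc = y[r] - s.ybar;
    for (int j = 0; j < p; ++j) xc[j] = X(r, j) - s.xbar[j];
    for (int j = 0; j < p; ++j) {
      s.Xy[j] += xc[j] * yc;
      for (int k = j; k < p; ++k) s.XtX[j * p + k] += xc[j] * xc[k];
    }
  }
  for (int j = 0; j < p; ++j) {
    s.Xy[j] /= n;
    for (int k = j; k < p; ++k) {
      const double v = s.XtX[j * p + k] / n;
      s.XtX[j * p + k] = v;
      s.XtX[k * p + j] = v;
    }
  }
  return s;
}

inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Solve the path for all lambdas (descending), warm-starting each from the
// previous solution. beta_out is column-major p x L.
void cd_path(const CenteredStats& s, const std::vector<double>& lambda,
             std::vector<double>& beta_out, double tol, int maxit) {
  const int p = s.p;
  const int L = static_cast<int>(lambda.size());
  std::vector<double> b(p, 0.0);
  std::vector<char> active(p, 0);
  beta_out.assign(static_cast<size_t>(p) * L, 0.0);
  auto sweep = [&](const double lam, bool full) -> double {
    double maxdel = 0.0;
    for (int j = 0; j < p; ++j) {
      if (!full && !active[j]) continue;
      const double v = s.XtX[j * p + j];
      if (v <= 0.0) { b[j] = 0.0; continue; }
      double rho = s.Xy[j] + v * b[j];
      for (int k = 0; k < p; ++k) rho -= s.XtX[j * p + k] * b[k];
      const double nb = soft_threshold(rho, lam) / v;
      const double d = std::fabs(nb - b[j]);
      if (d > maxdel) maxdel = d;
      b[j] = nb;
      if (nb != 0.0) active[j] = 1;
    }
    return maxdel;
  };
  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l];
    // glmnet-style: full sweep to refresh the active set, then iterate the
    // active set to convergence; repeat until a full sweep changes nothing.
    int it = 0;
    while (it < maxit) {
      ++it;
      const double full_del = sweep(lam, true);
      if (full_del < tol) break;
      while (it < maxit) {
        ++it;
        if (sweep(lam, false) < tol) break;
      }
    }
    // KKT boundary cases can leave +-1e-16 residue from the soft threshold;
    // record exact zeros so that selection counts are well defined
    for (int j = 0; j < p; ++j) {
      const double bj = (std::fabs(b[j]) < 1e-10) ? 0.0 : b[j];
      beta_out[static_cast<size_t>(l) * p + j] = bj;
    }
  }
}

// Per-lambda validation MSE for one CV split.
void fold_mse(const NumericMatrix& X, const NumericVector& y,
              const std::vector<int>& train, const std::vector<int>& val,
              const std::vector<double>& lambda, double tol, int maxit,
              std::vector<double>& mse_out) {
  const int p = X.ncol();
  const int L = static_cast<int>(lambda.size());
  CenteredStats s = make_stats(X, y, train);
  std::vector<double> beta;
  cd_path(s, lambda, beta, tol, maxit);
  mse_out.assign(L, 0.0);
  for (int l = 0; l < L; ++l) {
    const double* b = &beta[static_cast<size_t>(l) * p];
    double acc = 0.0;
    for (int r : val) {
      double pred = s.ybar;
      for (int j = 0; j < p; ++j) pred += b[j] * (X(r, j) - s.xbar[j]);
      const double e = y[r] - pred;
      acc += e * e;
    }
    mse_out[l] = acc / val.size();
  }
}

// One-SE rule: smallest index (largest lambda, grid descending) whose mean CV
// error is within one standard error of the minimum mean CV error.
int one_se_index(const std::vector<double>& mse, int L, int K) {
  std::vector<double> cvm(L, 0.0);
  for (int l = 0; l < L; ++l) {
    for (int k = 0; k < K; ++k) cvm[l] += mse[static_cast<size_t>(k) * L + l];
    cvm[l] /= K;
  }
  int imin = 0;
  for (int l = 1; l < L; ++l)
    if (cvm[l] < cvm[imin]) imin = l;
  double ss = 0.0;
  for (int k = 0; k < K; ++k) {
    const double d = mse[static_cast<size_t>(k) * L + imin] - cvm[imin];
    ss += d * d;
  }
  const double se = (K > 1) ? std::sqrt(ss / (K - 1)) / std::sqrt(static_cast<double>(K)) : 0.0;
  const double thr = cvm[imin] + se;
  for (int l = 0; l < L; ++l)
    if (cvm[l] <= thr) return l;
  return imin;  // unreachable
}

// lambda_max on the centered data: the smallest penalty with an all-zero
// solution when the intercept is unpenalized.
std::vector<double> lambda_grid_rows(const NumericMatrix& X, const NumericVector& y,
                                     const std::vector<int>& rows, int nlambda,
                                     double min_ratio) {
  const int p = X.ncol();
  const int n = static_cast<int>(rows.size());
  double ybar = 0.0;
  for (int r : rows) ybar += y[r];
  ybar /= n;
  double lmax = 0.0;
  for (int j = 0; j < p; ++j) {
    double xbar = 0.0;
    for (int r : rows) xbar += X(r, j);
    xbar /= n;
    double dot = 0.0;
    for (int r : rows) dot += (X(r, j) - xbar) * (y[r] - ybar);
    dot = std::fabs(dot) / n;
    if (dot > lmax) lmax = dot;
  }
  if (lmax <= 0.0) lmax = 1e-12;
  std::vector<double> lam(nlambda);
  const double lmin = lmax * min_ratio;
  const double step = (std::log(lmax) - std::log(lmin)) / (nlambda - 1);
  for (int l = 0; l < nlambda; ++l) lam[l] = std::exp(std::log(lmax) - step * l);
  return lam;
}

std::vector<int> all_rows(int n) {
  std::vector<int> r(n);
  for (int i = 0; i < n; ++i) r[i] = i;
  return r;
}

}  // namespace

// [[Rcpp::export]]
List cpp_lasso_path(NumericMatrix X, NumericVector y, NumericVector lambda,
                    double tol = 1e-7, int maxit = 100000) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  if (y.size() != n) stop("length(y) != nrow(X)");
  CenteredStats s = make_stats(X, y, all_rows(n));
  std::vector<double> lam(lambda.begin(), lambda.end());
  std::vector<double> beta;
  cd_path(s, lam, beta, tol, maxit);
  NumericMatrix bmat(p, L);
  NumericVector b0(L);
  for (int l = 0; l < L; ++l) {
    double icept = s.ybar;
    for (int j = 0; j < p; ++j) {
      bmat(j, l) = beta[static_cast<size_t>(l) * p + j];
      icept -= bmat(j, l) * s.xbar[j];
    }
    b0[l] = icept;
  }
  return List::create(Named("beta") = bmat, Named("intercept") = b0);
}

// [[Rcpp::export]]
NumericMatrix cpp_cv_mse(NumericMatrix X, NumericVector y, IntegerVector foldid,
                         NumericVector lambda, double tol = 1e-7,
                         int maxit = 100000) {
  const int n = X.nrow(), L = lambda.size();
  if (foldid.size() != n) stop("length(foldid) != nrow(X)");
  int K = 0;
  for (int i = 0; i < n; ++i) K = std::max(K, foldid[i]);
  std::vector<double> lam(lambda.begin(), lambda.end());
  NumericMatrix mse(L, K);
  std::vector<double> fm;
  for (int k = 1; k <= K; ++k) {
    std::vector<int> train, val;
    for (int i = 0; i < n; ++i) (foldid[i] == k ? val : train).push_back(i);
    if (val.empty() || train.empty()) stop("fold ", k, " is empty");
    fold_mse(X, y, train, val, lam, tol, maxit, fm);
    for (int l = 0; l < L; ++l) mse(l, k - 1) = fm[l];
  }
  return mse;
}

// Stability selection: the full-data path is fixed; each run re-randomizes
// only the CV fold assignment (column of foldmat) and picks its own one-SE
// lambda, whose full-data coefficients are recorded.
// [[Rcpp::export]]
List cpp_stability(NumericMatrix X, NumericVector y, IntegerMatrix foldmat,
                   NumericVector lambda, double tol = 1e-7,
                   int maxit = 100000) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  const int R = foldmat.ncol();
  if (foldmat.nrow() != n) stop("nrow(foldmat) != nrow(X)");
  std::vector<double> lam(lambda.begin(), lambda.end());
  CenteredStats s = make_stats(X, y, all_rows(n));
  std::vector<double> full_beta;
  cd_path(s, lam, full_beta, tol, maxit);
  NumericMatrix coefs(p, R);
  IntegerVector lambda_index(R);
  std::vector<double> mse_all, fm;
  for (int r = 0; r < R; ++r) {
    int K = 0;
    for (int i = 0; i < n; ++i) K = std::max(K, foldmat(i, r));
    mse_all.assign(static_cast<size_t>(L) * K, 0.0);
    for (int k = 1; k <= K; ++k) {
      std::vector<int> train, val;
      for (int i = 0; i < n; ++i) (foldmat(i, r) == k ? val : train).push_back(i);
      if (val.empty() || train.empty()) stop("empty fold in run ", r + 1);
      fold_mse(X, y, train, val, lam, tol, maxit, fm);
      for (int l = 0; l < L; ++l) mse_all[static_cast<size_t>(k - 1) * L + l] = fm[l];
    }
    const int idx = one_se_index(mse_all, L, K);
    lambda_index[r] = idx + 1;
    for (int j = 0; j < p; ++j)
      coefs(j, r) = full_beta[static_cast<size_t>(idx) * p + j];
  }
  return List::create(Named("coefficients") = coefs,
                      Named("lambda_index") = lambda_index);
}

// Bootstrap refits: each resample (column of idxmat, 1-based row indices) gets
// its own lambda grid (recomputed lambda_max), its own CV fold assignment
// (column of foldmat) and its own one-SE pick, i.e. the full procedure is
// refit on each resample.
// [[Rcpp::export]]
NumericMatrix cpp_bootstrap(NumericMatrix X, NumericVector y,
                            IntegerMatrix idxmat, IntegerMatrix foldmat,
                            int nlambda = 100, double min_ratio = 1e-3,
                            double tol = 1e-7, int maxit = 100000) {
  const int n = X.nrow(), p = X.ncol();
  const int B = idxmat.ncol();
  if (idxmat.nrow() != n || foldmat.nrow() != n)
    stop("idxmat and foldmat must be n x B");
  NumericMatrix coefs(p, B);
  std::vector<double> mse_all, fm, beta;
  for (int b = 0; b < B; ++b) {
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) {
      const int r = idxmat(i, b) - 1;
      if (r < 0 || r >= n) stop("idxmat entry out of range");
      rows[i] = r;
    }
    // Resampled design: view rows through an index map. Build explicit copies
    // of the resampled X and y once per resample (cheap at these sizes).
    NumericMatrix Xb(n, p);
    NumericVector yb(n);
    for (int i = 0; i < n; ++i) {
      yb[i] = y[rows[i]];
      for (int j = 0; j < p; ++j) Xb(i, j) = X(rows[i], j);
    }
    std::vector<double> lam = lambda_grid_rows(Xb, yb, all_rows(n), nlambda, min_ratio);
    const int L = static_cast<int>(lam.size());
    int K = 0;
    for (int i = 0; i < n; ++i) K = std::max(K, foldmat(i, b));
    mse_all.assign(static_cast<size_t>(L) * K, 0.0);
    for (int k = 1; k <= K; ++k) {
      std::vector<int> train, val;
      for (int i = 0; i < n; ++i) (foldmat(i, b) == k ? val : train).push_back(i);
      if (val.empty() || train.empty()) stop("empty fold in bootstrap ", b + 1);
      fold_mse(Xb, yb, train, val, lam, tol, maxit, fm);
      for (int l = 0; l < L; ++l) mse_all[static_cast<size_t>(k - 1) * L + l] = fm[l];
    }
    const int idx = one_se_index(mse_all, L, K);
    CenteredStats s = make_stats(Xb, yb, all_rows(n));
    std::vector<double> lam_trunc(lam.begin(), lam.begin() + idx + 1);
    cd_path(s, lam_trunc, beta, tol, maxit);
    for (int j = 0; j < p; ++j)
      coefs(j, b) = beta[static_cast<size_t>(idx) * p + j];
  }
  return coefs;
}
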