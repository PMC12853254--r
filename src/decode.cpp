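// Temporal-generalization decoding core: one-vs-all ridge logistic
// regression (IRLS) trained at each time sample, scored with AUC at
// every test time on held-out folds.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Area under the ROC curve via midranks; scores s, binary labels y.
// Returns NA if a class is absent.
static double auc_rank(const vec& s, const uvec& y1, const uvec& y0) {
  const uword n1 = y1.n_elem, n0 = y0.n_elem;
  if (n1 == 0 || n0 == 0) return datum::nan;
  const uword n = n1 + n0;
  vec all(n);
  // concatenate: positives first
  for (uword i = 0; i < n1; ++i) all[i] = s[y1[i]];
  for (uword i = 0; i < n0; ++i) all[n1 + i] = s[y0[i]];
  uvec ord = sort_index(all);
  vec rank(n);
  uword i = 0;
  while (i < n) {
    uword j = i;
    while (j + 1 < n && all[ord[j + 1]] == all[ord[i]]) ++j;
    double r = 0.5 * (double)(i + j) + 1.0;  // midrank (1-based)
    for (uword k = i; k <= j; ++k) rank[ord[k]] = r;
    i = j + 1;
  }
  double rsum = 0.0;
  for (uword k = 0; k < n1; ++k) rsum += rank[k];
  return (rsum - 0.5 * n1 * (n1 + 1.0)) / ((double)n1 * (double)n0);
}

// Ridge-penalized logistic regression by IRLS.  X: n x c (no intercept
// column), y in {0,1}. Intercept unpenalized. w has length c+1, with
// w[0] the intercept; used as warm start and overwritten.
static void ridge_logistic(const mat& X, const vec& y, double lambda,
                           vec& w, int max_iter, double tol) {
  const uword n = X.n_rows, c = X.n_cols;
  mat Q(c + 1, c + 1);
  vec g(c + 1), eta(n), p(n), wt(n), z(n);
  for (int it = 0; it < max_iter; ++it) {
    eta = w[0] + X * w.subvec(1, c);
    p = 1.0 / (1.0 + exp(-eta));
    p = clamp(p, 1e-10, 1.0 - 1e-10);
    wt = p % (1.0 - p);
    z = eta + (y - p) / wt;
    // Build weighted normal equations [1 X]' W [1 X] + lambda*diag(0,1..)
    mat Xw = X.each_col() % wt;
    Q(0, 0) = accu(wt);
    rowvec cw = sum(Xw, 0);
    Q.submat(0, 1, 0, c) = cw;
    Q.submat(1, 0, c, 0) = cw.t();
    Q.submat(1, 1, c, c) = X.t() * Xw;
    for (uword j = 1; j <= c; ++j) Q(j, j) += lambda;
    g[0] = dot(wt, z);
    g.subvec(1, c) = Xw.t() * z;
    vec w_new;
    bool ok = solve(w_new, Q, g, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) { solve(w_new, Q, g); }
    double delta = norm(w_new - w, "inf");
    w = w_new;
    if (delta < tol) break;
  }
}

// X: cube n_events x n_channels x n_times (epochs).
// y: binary labels; fold: 1..K fold id per event.
// subset: integer per event, 0 = unlabeled; levels 1..L get their own
// test-set AUC while training is shared (level 0 events still train).
// Returns list(overall = T x T AUC matrix, levels = list of L matrices,
//              n_cells = folds contributing per matrix).
// [[Rcpp::export]]
Rcpp::List cpp_tg_decode(const arma::cube& X, const arma::vec& y,
                         const arma::ivec& fold, const arma::ivec& subset,
                         int n_levels, double lambda, int max_iter,
                         double tol) {
  const uword n = X.n_rows, c = X.n_cols, T = X.n_slices;
  const int K = fold.max();
  mat overall(T, T, fill::zeros);
  mat overall_n(T, T, fill::zeros);
  std::vector<mat> lev(n_levels, mat(T, T, fill::zeros));
  std::vector<mat> lev_n(n_levels, mat(T, T, fill::zeros));

  for (int k = 1; k <= K; ++k) {
    uvec tr = find(fold != k);
    uvec te = find(fold == k);
    const uword ntr = tr.n_elem, nte = te.n_elem;
    vec ytr = y(tr);
    if (ytr.max() == ytr.min())
      Rcpp::stop("training fold %d contains a single class; stratify folds", k);
    // test-set class index caches
    uvec te_pos_all = find(y(te) == 1), te_neg_all = find(y(te) == 0);
    std::vector<uvec> lv_pos(n_levels), lv_neg(n_levels);
    for (int l = 0; l < n_levels; ++l) {
      uvec in_l = find(subset(te) == l + 1);
      vec yl = y(te);
      uvec pos, neg;
      std::vector<uword> p_, n_;
      for (uword i = 0; i < in_l.n_elem; ++i) {
        if (yl[in_l[i]] == 1) p_.push_back(in_l[i]); else n_.push_back(in_l[i]);
      }
      lv_pos[l] = uvec(p_); lv_neg[l] = uvec(n_);
    }
    // gather train/test cubes once (contiguous for speed)
    cube Xtr(ntr, c, T), Xte(nte, c, T);
    for (uword t = 0; t < T; ++t) {
      Xtr.slice(t) = X.slice(t).rows(tr);
      Xte.slice(t) = X.slice(t).rows(te);
    }
    // fit at each train time (warm start from neighbour), store weights
    mat W(c + 1, T);
    vec w(c + 1, fill::zeros);
    for (uword t = 0; t < T; ++t) {
      ridge_logistic(Xtr.slice(t), ytr, lambda, w, max_iter, tol);
      W.col(t) = w;
    }
    // score: decision values for every (train t, test t2)
    mat Wt = W.rows(1, c);       // c x T
    rowvec b = W.row(0);         // intercepts
    for (uword t2 = 0; t2 < T; ++t2) {
      mat S = Xte.slice(t2) * Wt;       // nte x T (train times)
      S.each_row() += b;
      for (uword t = 0; t < T; ++t) {
        double a = auc_rank(S.col(t), te_pos_all, te_neg_all);
        if (std::isfinite(a)) { overall(t, t2) += a; overall_n(t, t2) += 1.0; }
        for (int l = 0; l < n_levels; ++l) {
          double al = auc_rank(S.col(t), lv_pos[l], lv_neg[l]);
          if (std::isfinite(al)) { lev[l](t, t2) += al; lev_n[l](t, t2) += 1.0; }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  overall /= overall_n;
  Rcpp::List lvout(n_levels);
  for (int l = 0; l < n_levels; ++l) lvout[l] = mat(lev[l] / lev_n[l]);
  return Rcpp::List::create(Rcpp::Named("overall") = overall,
                            Rcpp::Named("levels") = lvout,
                            Rcpp::Named("n_folds") = overall_n);
}

// Cross-validated AUC for a plain feature matrix (used per sensor:
// features are that sensor's epoch timecourse).
// [[Rcpp::export]]
double cpp_cv_auc(const arma::mat& X, const arma::vec& y,
                  const arma::ivec& fold, double lambda, int max_iter,
                  double tol) {
  const int K = fold.max();
  double acc = 0.0; int m = 0;
  for (int k = 1; k <= K; ++k) {
    uvec tr = find(fold != k), te = find(fold == k);
    vec ytr = y(tr);
    if (ytr.max() == ytr.min())
      Rcpp::stop("training fold %d contains a single class; stratify folds", k);
    vec w(X.n_cols + 1, fill::zeros);
    ridge_logistic(X.rows(tr), ytr, lambda, w, max_iter, tol);
    vec s = w[0] + X.rows(te) * w.subvec(1, X.n_cols);
    vec yte = y(te);
    uvec pos = find(yte == 1), neg = find(yte == 0);
    double a = auc_rank(s, pos, neg);
    if (std::isfinite(a)) { acc += a; ++m; }
  }
  if (m == 0) return NA_REAL;
  return acc / m;
}

// Single ridge-logistic fit (exposed for testing against an
// independent optimizer). Returns (intercept, weights).
// [[Rcpp::export]]
arma::vec cpp_ridge_logistic(const arma::mat& X, const arma::vec& y,
                             double lambda, int max_iter, double tol) {
  vec w(X.n_cols + 1, fill::zeros);
  ridge_logistic(X, y, lambda, w, max_iter, tol);
  return w;
}

// AUC exposed for testing.
// [[Rcpp::export]]
double cpp_auc(const arma::vec& s, const arma::vec& y) {
  uvec pos = find(y == 1), neg = find(y == 0);
  return auc_rank(s, pos, neg);
}
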