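// Cluster-based permutation engines.  Domains are flattened point sets
// with adjacency supplied in CSR form (0-based); clusters are connected
// components of supra-threshold points with a consistent t sign.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Label connected components among points where keep[i] != 0 and sign
// matches; returns number of clusters, fills labels (0 = background)
// and masses (sum of t within cluster).
static int clusterize(const vec& t, double thr, const ivec& adj,
                      const ivec& ptr, ivec& labels, std::vector<double>& masses) {
  const uword p = t.n_elem;
  labels.zeros(p);
  masses.clear();
  int ncl = 0;
  std::vector<uword> stack;
  for (uword i = 0; i < p; ++i) {
    if (labels[i] != 0 || std::abs(t[i]) <= thr) continue;
    ++ncl;
    double sgn = t[i] > 0 ? 1.0 : -1.0;
    double mass = 0.0;
    stack.push_back(i);
    labels[i] = ncl;
    while (!stack.empty()) {
      uword u = stack.back(); stack.pop_back();
      mass += t[u];
      for (int e = ptr[u]; e < ptr[u + 1]; ++e) {
        uword v = (uword)adj[e];
        if (labels[v] == 0 && std::abs(t[v]) > thr &&
            (t[v] > 0 ? 1.0 : -1.0) == sgn) {
          labels[v] = ncl;
          stack.push_back(v);
        }
      }
    }
    masses.push_back(mass);
  }
  return ncl;
}

static double max_abs_mass(const vec& t, double thr, const ivec& adj,
                           const ivec& ptr) {
  const uword p = t.n_elem;
  ivec labels(p, fill::zeros);
  double best = 0.0;
  std::vector<uword> stack;
  for (uword i = 0; i < p; ++i) {
    if (labels[i] != 0 || std::abs(t[i]) <= thr) continue;
    double sgn = t[i] > 0 ? 1.0 : -1.0;
    double mass = 0.0;
    stack.push_back(i);
    labels[i] = 1;
    while (!stack.empty()) {
      uword u = stack.back(); stack.pop_back();
      mass += t[u];
      for (int e = ptr[u]; e < ptr[u + 1]; ++e) {
        uword v = (uword)adj[e];
        if (labels[v] == 0 && std::abs(t[v]) > thr &&
            (t[v] > 0 ? 1.0 : -1.0) == sgn) {
          labels[v] = 1;
          stack.push_back(v);
        }
      }
    }
    if (std::abs(mass) > best) best = std::abs(mass);
  }
  return best;
}

// One-sample t statistic per column of D (n x p), already centered on mu0.
static void onesample_t(const mat& D, vec& t) {
  const double n = (double)D.n_rows;
  rowvec m = mean(D, 0);
  rowvec v = (sum(square(D), 0) - n * square(m)) / (n - 1.0);
  t = (m / sqrt(v / n)).t();
  t.replace(datum::nan, 0.0);
}

// One-sample sign-flip cluster permutation test.
// D: subjects x points (centered), signs: nperm x n of +-1,
// adjacency CSR (adj, ptr).
// [[Rcpp::export]]
Rcpp::List cpp_cluster_onesample(const arma::mat& D, const arma::mat& signs,
                                 double thr, const arma::ivec& adj,
                                 const arma::ivec& ptr) {
  const uword n = D.n_rows, p = D.n_cols, nperm = signs.n_rows;
  vec t_obs;
  onesample_t(D, t_obs);
  ivec labels;
  std::vector<double> masses;
  clusterize(t_obs, thr, adj, ptr, labels, masses);

  // per-point sums of squares are sign-invariant
  rowvec ss = sum(square(D), 0);
  vec null(nperm);
  vec t(p);
  for (uword b = 0; b < nperm; ++b) {
    rowvec m = (signs.row(b) * D) / (double)n;
    rowvec v = (ss - n * square(m)) / (n - 1.0);
    t = (m / sqrt(v / (double)n)).t();
    t.replace(datum::nan, 0.0);
    null[b] = max_abs_mass(t, thr, adj, ptr);
  }
  vec pv(masses.size());
  for (uword c = 0; c < masses.size(); ++c) {
    double obs = std::abs(masses[c]);
    pv[c] = ((double)accu(null >= obs) + 1.0) / ((double)nperm + 1.0);
  }
  return Rcpp::List::create(Rcpp::Named("t") = t_obs,
                            Rcpp::Named("labels") = labels,
                            Rcpp::Named("masses") = masses,
                            Rcpp::Named("p") = pv,
                            Rcpp::Named("null_max") = null);
}

// Pooled-variance independent-samples t per column; g1 marks group A rows.
static void twosample_t(const mat& D, const uvec& ga, const uvec& gb, vec& t) {
  const double n1 = (double)ga.n_elem, n2 = (double)gb.n_elem;
  mat A = D.rows(ga), B = D.rows(gb);
  rowvec m1 = mean(A, 0), m2 = mean(B, 0);
  rowvec s1 = sum(square(A), 0) - n1 * square(m1);
  rowvec s2 = sum(square(B), 0) - n2 * square(m2);
  rowvec sp = (s1 + s2) / (n1 + n2 - 2.0);
  t = ((m1 - m2) / sqrt(sp * (1.0 / n1 + 1.0 / n2))).t();
  t.replace(datum::nan, 0.0);
}

// Two-sample (group-exchange) cluster permutation test.
// D: (n1+n2) x points stacked; perms: nperm x n1 matrix of 0-based row
// indices assigned to group A in each permutation.
// [[Rcpp::export]]
Rcpp::List cpp_cluster_twosample(const arma::mat& D, int n1,
                                 const arma::umat& perms, double thr,
                                 const arma::ivec& adj, const arma::ivec& ptr) {
  const uword n = D.n_rows, p = D.n_cols, nperm = perms.n_rows;
  uvec all = regspace<uvec>(0, n - 1);
  uvec ga = regspace<uvec>(0, n1 - 1);
  uvec gb = regspace<uvec>(n1, n - 1);
  vec t_obs;
  twosample_t(D, ga, gb, t_obs);
  ivec labels;
  std::vector<double> masses;
  clusterize(t_obs, thr, adj, ptr, labels, masses);

  vec null(nperm), t(p);
  for (uword b = 0; b < nperm; ++b) {
    uvec pa = perms.row(b).t();
    // complement
    uvec mark(n, fill::zeros);
    for (uword i = 0; i < pa.n_elem; ++i) mark[pa[i]] = 1;
    uvec pb = find(mark == 0);
    twosample_t(D, pa, pb, t);
    null[b] = max_abs_mass(t, thr, adj, ptr);
  }
  vec pv(masses.size());
  for (uword c = 0; c < masses.size(); ++c) {
    double obs = std::abs(masses[c]);
    pv[c] = ((double)accu(null >= obs) + 1.0) / ((double)nperm + 1.0);
  }
  return Rcpp::List::create(Rcpp::Named("t") = t_obs,
                            Rcpp::Named("labels") = labels,
                            Rcpp::Named("masses") = masses,
                            Rcpp::Named("p") = pv,
                            Rcpp::Named("null_max") = null);
}
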