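#include <Rcpp.h>
#include <functional>
#include <vector>
using namespace Rcpp;

// Sample entropy of a numeric series: -log(A/B) with B the number of
// ordered template pairs (i != j, i,j in 1..n-m) of length m within
// Chebyshev distance r, and A the same for length m+1.  Both counts use
// templates starting at 1..n-m so they range over the same indices.
// Returns NA when no pair matches at either length.
// [[Rcpp::export]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;  // templates of length m and m+1 both start at 0..nt-1
  if (nt < 2) return NA_REAL;
  const double* v = REAL(x);
  // a matching pair must agree at offset 0, so sort template starts by
  // their first value and only compare neighbours within r of each other
  std::vector<int> idx(nt);
  for (int i = 0; i < nt; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return v[a] < v[b]; });
  double A = 0.0, B = 0.0;
  for (int a = 0; a < nt - 1; ++a) {
    int i = idx[a];
    double lim = v[i] + r;
    for (int b = a + 1; b < nt && v[idx[b]] <= lim; ++b) {
      int j = idx[b];
      bool ok = true;
      for (int k = 1; k < m; ++k)
        if (std::fabs(v[i + k] - v[j + k]) > r) { ok = false; break; }
      if (!ok) continue;
      B += 1.0;
      if (std::fabs(v[i + m] - v[j + m]) <= r) A += 1.0;
    }
  }
  if (A == 0.0 || B == 0.0) return NA_REAL;
  return -std::log(A / B);
}

// Exact interventional Shapley values for a binary decision tree,
// averaged over a background sample.
//
// The tree is passed flattened: for node t, var[t] is the 1-based index
// of the split feature (0 for a leaf), split[t] the threshold (go left
// when x < split), left[t]/right[t] the 1-based child ids, and value[t]
// the leaf's positive-class score.
//
// For a single (explicand x, background b) pair the game
// v(S) = f(x_S, b_{S^c}) restricted to one leaf's path is a conjunction
// over the path features: the leaf is reached iff every path feature j
// either is in S and x follows the path at all of j's conditions, or is
// out of S and b follows them.  With p features followed only by x and
// q only by b, the Shapley value of such a conjunction game is
//   +leaf * (p-1)! q! / (p+q)!  for each of the p x-only features,
//   -leaf * p! (q-1)! / (p+q)!  for each of the q b-only features,
// and 0 for everyone else.  Summing over leaves gives the exact values;
// summing the values recovers f(x) - f(b) (local accuracy).
//
// Returns an n_x  x  n_feature matrix of Shapley values, each row
// averaged over all background rows.
// [[Rcpp::export]]
NumericMatrix tree_shapley_cpp(IntegerVector var, NumericVector split,
                               IntegerVector left, IntegerVector right,
                               NumericVector value,
                               NumericMatrix X, NumericMatrix B) {
  int n_nodes = var.size();
  int nx = X.nrow(), nb = B.nrow(), nf = X.ncol();
  NumericMatrix phi(nx, nf);

  // enumerate root-to-leaf paths once
  std::vector< std::vector<int> > path_feat;   // per leaf: feature ids (0-based)
  std::vector< std::vector<double> > path_thr; // thresholds
  std::vector< std::vector<int> > path_dir;    // +1 go-left (x < thr), -1 go-right
  std::vector<double> leaf_val;
  {
    std::vector<int> stack_node, stack_depth;
    std::vector<int> cur_feat, cur_dir; std::vector<double> cur_thr;
    // iterative DFS with explicit path
    std::function<void(int)> dfs = [&](int t) {
      if (var[t] == 0) {
        path_feat.push_back(cur_feat);
        path_thr.push_back(cur_thr);
        path_dir.push_back(cur_dir);
        leaf_val.push_back(value[t]);
        return;
      }
      int f = var[t] - 1;
      cur_feat.push_back(f); cur_thr.push_back(split[t]); cur_dir.push_back(1);
      dfs(left[t] - 1);
      cur_dir.back() = -1;
      dfs(right[t] - 1);
      cur_feat.pop_back(); cur_thr.pop_back(); cur_dir.pop_back();
    };
    dfs(0);
  }
  int n_leaves = leaf_val.size();

  // factorial table (path feature counts are tiny)
  std::vector<double> fact(171, 1.0);
  for (int i = 1; i < 171; ++i) fact[i] = fact[i - 1] * i;

  std::vector<int> xonly(nf), bonly(nf);
  std::vector<char> xfol(nf), bfol(nf), seen(nf);
  std::vector<int> feats; feats.reserve(nf);

  for (int ix = 0; ix < nx; ++ix) {
    for (int ib = 0; ib < nb; ++ib) {
      for (int l = 0; l < n_leaves; ++l) {
        const std::vector<int>& pf = path_feat[l];
        int np = pf.size();
        feats.clear();
        bool dead = false;
        // per-feature: does x (resp. b) satisfy every condition on this path?
        for (int c = 0; c < np; ++c) {
          int f = pf[c];
          if (!seen[f]) { seen[f] = 1; xfol[f] = 1; bfol[f] = 1; feats.push_back(f); }
          bool xs = (path_dir[l][c] == 1) ? (X(ix, f) < path_thr[l][c])
                                          : (X(ix, f) >= path_thr[l][c]);
          bool bs = (path_dir[l][c] == 1) ? (B(ib, f) < path_thr[l][c])
                                          : (B(ib, f) >= path_thr[l][c]);
          if (!xs) xfol[f] = 0;
          if (!bs) bfol[f] = 0;
        }
        int p = 0, q = 0;
        for (size_t k = 0; k < feats.size(); ++k) {
          int f = feats[k];
          if (xfol[f] && !bfol[f]) ++p;
          else if (!xfol[f] && bfol[f]) ++q;
          else if (!xfol[f] && !bfol[f]) dead = true;
        }
        if (!dead && (p + q) > 0) {
          double v = leaf_val[l];
          double wp = v * fact[p > 0 ? p - 1 : 0] * fact[q] / fact[p + q];
          double wq = v * fact[p] * fact[q > 0 ? q - 1 : 0] / fact[p + q];
          for (size_t k = 0; k < feats.size(); ++k) {
            int f = feats[k];
            if (xfol[f] && !bfol[f]) phi(ix, f) += wp;
            else if (!xfol[f] && bfol[f]) phi(ix, f) -= wq;
          }
        }
        for (size_t k = 0; k < feats.size(); ++k) seen[feats[k]] = 0;
      }
    }
  }
  for (int ix = 0; ix < nx; ++ix)
    for (int f = 0; f < nf; ++f) phi(ix, f) /= nb;
  return phi;
}
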