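#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Optimal univariate k-means on weighted sorted distinct values by dynamic
// programming.  D[q][i] = minimal within-cluster sum of squares for grouping
// values 0..i into q+1 contiguous clusters; the q-th row is filled by divide
// and conquer, which is valid because the optimal split index is monotone in
// i (the interval cost is a concave Monge matrix).  Overall O(k * u * log u)
// for u distinct values.

namespace {

struct Prefix {
  std::vector<long double> W, S, Q; // cumulative weight, weighted sum, weighted sum of squares
  // cost of clustering values j..i (0-based, inclusive) into one cluster
  long double cost(int j, int i) const {
    long double w = W[i + 1] - W[j];
    if (w <= 0) return 0.0L;
    long double s = S[i + 1] - S[j];
    long double q = Q[i + 1] - Q[j];
    long double c = q - s * s / w;
    return c > 0 ? c : 0.0L;
  }
};

void fill_row(const Prefix &ps,
              const std::vector<long double> &prev,
              std::vector<long double> &cur,
              std::vector<int> &back,
              int ilo, int ihi, int jlo, int jhi) {
  if (ilo > ihi) return;
  int mid = (ilo + ihi) / 2;
  int hi = jhi < mid ? jhi : mid;
  long double best = -1.0L;
  int bestj = jlo;
  for (int j = jlo; j <= hi; ++j) {
    long double c = prev[j - 1] + ps.cost(j, mid);
    if (best < 0 || c < best) { best = c; bestj = j; }
  }
  cur[mid] = best;
  back[mid] = bestj;
  fill_row(ps, prev, cur, back, ilo, mid - 1, jlo, bestj);
  fill_row(ps, prev, cur, back, mid + 1, ihi, bestj, jhi);
}

} // namespace

// [[Rcpp::export(name = ".ckmeans_dp")]]
List ckmeans_dp(NumericVector values, NumericVector weights, int kmax) {
  const int u = values.size();
  if (u < 1) stop("empty input");
  if (kmax < 1 || kmax > u) stop("kmax out of range");

  // shift by the weighted mean: wcss is shift-invariant and the prefix sums
  // of squares lose far less precision near zero
  long double wtot = 0.0L, wsum = 0.0L;
  for (int i = 0; i < u; ++i) { wtot += weights[i]; wsum += (long double)weights[i] * values[i]; }
  const long double shift = wsum / wtot;

  Prefix ps;
  ps.W.assign(u + 1, 0.0L); ps.S.assign(u + 1, 0.0L); ps.Q.assign(u + 1, 0.0L);
  for (int i = 0; i < u; ++i) {
    long double x = (long double)values[i] - shift;
    ps.W[i + 1] = ps.W[i] + weights[i];
    ps.S[i + 1] = ps.S[i] + weights[i] * x;
    ps.Q[i + 1] = ps.Q[i] + weights[i] * x * x;
  }

  std::vector<std::vector<int> > back(kmax, std::vector<int>(u, 0));
  std::vector<long double> prev(u), cur(u);
  NumericVector wcss(kmax);
  for (int i = 0; i < u; ++i) prev[i] = ps.cost(0, i); // one cluster
  wcss[0] = (double)prev[u - 1];
  for (int q = 1; q < kmax; ++q) {
    fill_row(ps, prev, cur, back[q], q, u - 1, q, u - 1);
    for (int i = 0; i < q; ++i) cur[i] = 0.0L; // fewer points than clusters: unused
    wcss[q] = (double)cur[u - 1];
    std::swap(prev, cur);
  }

  // backtrack cluster start indices (1-based in distinct-value space) per k
  List starts(kmax);
  for (int k = 1; k <= kmax; ++k) {
    IntegerVector st(k);
    int i = u - 1;
    for (int q = k - 1; q >= 1; --q) {
      int j = back[q][i];
      st[q] = j + 1;
      i = j - 1;
    }
    st[0] = 1;
    starts[k - 1] = st;
  }
  return List::create(_["wcss"] = wcss, _["starts"] = starts);
}
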