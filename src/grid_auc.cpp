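#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {
// one unique composite-score value with its case/control mass
struct Cell {
  double s;
  float d;
  float h;
};
}

// Rank-statistic ROC AUC for every weight vector of a simplex grid.
//
// Inputs are collapsed to unique component-risk rows: risks is u x k,
// n_case / n_ctrl hold the case and control counts of each unique row.
// For each row w of wts the composite score of unique row i is
// sum_j wts(w, j) * risks(i, j); the AUC is the probability that a random
// case outscores a random control, ties counted 1/2 (Mann-Whitney).
// This is the grid-search hot loop of weight fitting, so it lives in C++;
// counts are carried as floats inside the sort records (exact below 2^24)
// and accumulated in doubles.
// [[Rcpp::export]]
NumericVector cpp_grid_auc(NumericMatrix risks, NumericVector n_case,
                           NumericVector n_ctrl, NumericMatrix wts) {
  const int u = risks.nrow(), k = risks.ncol(), m = wts.nrow();
  if (n_case.size() != u || n_ctrl.size() != u)
    stop("count vectors must match the number of unique risk rows");
  if (wts.ncol() != k)
    stop("weight matrix column count must match the risk matrix");
  double tot1 = 0.0, tot0 = 0.0;
  for (int i = 0; i < u; ++i) {
    tot1 += n_case[i];
    tot0 += n_ctrl[i];
  }
  if (tot1 <= 0 || tot0 <= 0)
    stop("both classes must be present");

  // column-major copies for a cache-friendly inner product
  std::vector<double> R(static_cast<size_t>(u) * k);
  for (int j = 0; j < k; ++j)
    for (int i = 0; i < u; ++i)
      R[static_cast<size_t>(j) * u + i] = risks(i, j);

  std::vector<Cell> cells(u);
  NumericVector out(m);
  for (int w = 0; w < m; ++w) {
    for (int i = 0; i < u; ++i) {
      double v = 0.0;
      for (int j = 0; j < k; ++j)
        v += wts(w, j) * R[static_cast<size_t>(j) * u + i];
      cells[i].s = v;
      cells[i].d = static_cast<float>(n_case[i]);
      cells[i].h = static_cast<float>(n_ctrl[i]);
    }
    std::sort(cells.begin(), cells.end(),
              [](const Cell& a, const Cell& b) { return a.s < b.s; });
    double num = 0.0, cum_ctrl = 0.0;
    int i = 0;
    while (i < u) {
      int j = i;
      double d = 0.0, h = 0.0;
      const double v = cells[i].s;
      while (j < u && cells[j].s == v) {
        d += cells[j].d;
        h += cells[j].h;
        ++j;
      }
      num += d * (cum_ctrl + h / 2.0);
      cum_ctrl += h;
      i = j;
    }
    out[w] = num / (tot1 * tot0);
  }
  return out;
}
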