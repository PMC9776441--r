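// Dense linear assignment by shortest augmenting paths with dual potentials
// (Jonker-Volgenant family). Solves min sum_i C[i, a(i)] over permutations a
// for a square cost matrix; O(n^3).

#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector solve_lap(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<double> u(n, 0.0), v(n, 0.0), shortest(n);
  std::vector<int> col4row(n, -1), row4col(n, -1), path(n, -1);
  std::vector<bool> SR(n), SC(n);
  std::vector<int> remaining(n);

  for (int curRow = 0; curRow < n; ++curRow) {
    double minVal = 0.0;
    int i = curRow;
    int numRemaining = n;
    for (int it = 0; it < n; ++it) {
      remaining[it] = n - 1 - it;  // iterate high-to-low; removal by swap
      SR[it] = false;
      SC[it] = false;
      shortest[it] = INF;
    }
    int sink = -1;
    while (sink == -1) {
      SR[i] = true;
      int indexLowest = -1;
      double lowest = INF;
      for (int it = 0; it < numRemaining; ++it) {
        int j = remaining[it];
        double r = minVal + cost(i, j) - u[i] - v[j];
        if (r < shortest[j]) {
          path[j] = i;
          shortest[j] = r;
        }
        if (shortest[j] < lowest || (shortest[j] == lowest && row4col[j] == -1)) {
          lowest = shortest[j];
          indexLowest = it;
        }
      }
      minVal = lowest;
      if (minVal == INF) stop("infeasible cost matrix");
      int j = remaining[indexLowest];
      if (row4col[j] == -1) sink = j;
      else i = row4col[j];
      SC[j] = true;
      remaining[indexLowest] = remaining[--numRemaining];
    }

    u[curRow] += minVal;
    for (int k = 0; k < n; ++k) {
      if (SR[k] && k != curRow) u[k] += minVal - shortest[col4row[k]];
      if (SC[k]) v[k] -= minVal - shortest[k];
    }

    // augment along the alternating path ending at sink
    int j = sink;
    while (true) {
      int ii = path[j];
      row4col[j] = ii;
      int tmp = col4row[ii];
      col4row[ii] = j;
      if (ii == curRow) break;
      j = tmp;
    }
  }

  IntegerVector out(n);
  for (int k = 0; k < n; ++k) out[k] = col4row[k] + 1;  // 1-based
  return out;
}

// Log-domain Sinkhorn with annealed entropic temperature for uniform
// marginals; mirrors the reference R implementation. Returns a plan whose
// rows sum exactly to 1/n.
// [[Rcpp::export]]
NumericMatrix sinkhorn_plan_cpp(NumericMatrix d, int iters) {
  const int n = d.nrow();
  if (d.ncol() != n) stop("cost matrix must be square");
  double mc = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) mc += d(i, j);
  mc /= (double)n * n;
  NumericMatrix plan(n, n);
  if (mc == 0.0) {
    for (int i = 0; i < n; ++i) plan(i, i) = 1.0 / n;
    return plan;
  }
  const double loga = -std::log((double)n);
  std::vector<double> f(n, 0.0), g(n, 0.0);
  double eps = 0.0;
  for (int it = 0; it < iters; ++it) {
    double frac = (iters == 1) ? 0.0 : (double)it / (iters - 1);
    eps = mc * std::exp(std::log(0.5) + frac * (std::log(0.02) - std::log(0.5)));
    for (int i = 0; i < n; ++i) {
      double mx = -INFINITY;
      for (int j = 0; j < n; ++j) {
        double v = (g[j] - d(i, j)) / eps;
        if (v > mx) mx = v;
      }
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += std::exp((g[j] - d(i, j)) / eps - mx);
      f[i] = eps * (loga - (mx + std::log(s)));
    }
    for (int j = 0; j < n; ++j) {
      double mx = -INFINITY;
      for (int i = 0; i < n; ++i) {
        double v = (f[i] - d(i, j)) / eps;
        if (v > mx) mx = v;
      }
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += std::exp((f[i] - d(i, j)) / eps - mx);
      g[j] = eps * (loga - (mx + std::log(s)));
    }
  }
  for (int i = 0; i < n; ++i) {
    double rs = 0.0;
    for (int j = 0; j < n; ++j) {
      plan(i, j) = std::exp((f[i] + g[j] - d(i, j)) / eps);
      rs += plan(i, j);
    }
    double sc = 1.0 / (n * rs);
    for (int j = 0; j < n; ++j) plan(i, j) *= sc;
  }
  return plan;
}

// Greedy minimum density sampling: starting from first_index (1-based),
// repeatedly select the candidate with the lowest Gaussian-kernel density
// w.r.t. the points already selected. Ties go to the smaller index.
// Returns 1-based indices.
// [[Rcpp::export]]
IntegerVector mds_select_cpp(NumericMatrix pts, int n_out, double sigma,
                             int first_index) {
  const int n = pts.nrow();
  if (n_out > n) stop("n_out exceeds the cloud size");
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  std::vector<double> density(n, 0.0);
  std::vector<bool> taken(n, false);
  IntegerVector out(n_out);
  int last = first_index - 1;
  taken[last] = true;
  out[0] = first_index;
  for (int step = 1; step < n_out; ++step) {
    const double lx = pts(last, 0), ly = pts(last, 1), lz = pts(last, 2);
    int best = -1;
    double bestd = INFINITY;
    for (int i = 0; i < n; ++i) {
      double dx = pts(i, 0) - lx, dy = pts(i, 1) - ly, dz = pts(i, 2) - lz;
      density[i] += std::exp(-(dx * dx + dy * dy + dz * dz) * inv2s2);
      if (!taken[i] && density[i] < bestd) {
        bestd = density[i];
        best = i;
      }
    }
    taken[best] = true;
    out[step] = best + 1;
    last = best;
  }
  return out;
}
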