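#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Local 3x3 median of a height grid. NA entries are ignored; the window is
// clipped at the grid edges. A cell whose whole window is NA stays NA.
// [[Rcpp::export]]
NumericMatrix median3x3_cpp(NumericMatrix z) {
  int nr = z.nrow(), nc = z.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve(9);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= nc) continue;
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di;
          if (ii < 0 || ii >= nr) continue;
          double v = z(ii, jj);
          if (!ISNAN(v)) buf.push_back(v);
        }
      }
      if (buf.empty()) {
        out(i, j) = NA_REAL;
      } else {
        size_t n = buf.size();
        std::sort(buf.begin(), buf.end());
        out(i, j) = (n % 2 == 1) ? buf[n / 2]
                                 : 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
      }
    }
  }
  return out;
}

static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Topographic prominence of every strict 8-neighbour interior local maximum,
// by a descending union-find flood: when the component of a lower peak first
// touches the component of a higher peak, the lower peak's prominence is its
// height minus the current water level (the key saddle). The global maximum
// gets the full relief max(z) - min(z). Ties in peak height are broken by
// smaller linear index (deterministic). The grid must be void-free.
// [[Rcpp::export]]
List prominence_cpp(NumericMatrix z) {
  int nr = z.nrow(), nc = z.ncol(), n = nr * nc;

  // strict interior local maxima
  std::vector<bool> is_summit(n, false);
  for (int j = 1; j < nc - 1; ++j) {
    for (int i = 1; i < nr - 1; ++i) {
      double v = z(i, j);
      bool mx = true;
      for (int dj = -1; dj <= 1 && mx; ++dj)
        for (int di = -1; di <= 1 && mx; ++di)
          if (di != 0 || dj != 0)
            if (z(i + di, j + dj) >= v) mx = false;
      if (mx) is_summit[i + j * nr] = true;
    }
  }

  // order pixels by descending height, stable by index
  std::vector<int> ord(n);
  for (int k = 0; k < n; ++k) ord[k] = k;
  const double* zp = z.begin();
  std::stable_sort(ord.begin(), ord.end(), [zp](int a, int b) {
    return zp[a] > zp[b];
  });

  std::vector<int> parent(n, -1);      // -1 = not yet activated
  std::vector<int> comp_peak(n, -1);   // root -> peak pixel of component
  std::vector<double> prom(n, NA_REAL);

  double zmin = *std::min_element(zp, zp + n);

  for (int k = 0; k < n; ++k) {
    int p = ord[k];
    double level = zp[p];
    parent[p] = p;
    comp_peak[p] = p;
    int i = p % nr, j = p / nr;
    for (int dj = -1; dj <= 1; ++dj) {
      int jj = j + dj;
      if (jj < 0 || jj >= nc) continue;
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0) continue;
        int ii = i + di;
        if (ii < 0 || ii >= nr) continue;
        int q = ii + jj * nr;
        if (parent[q] < 0) continue;  // not yet flooded
        int rp = uf_find(parent, p), rq = uf_find(parent, q);
        if (rp == rq) continue;
        int pk_p = comp_peak[rp], pk_q = comp_peak[rq];
        // survivor: higher peak; ties -> smaller index
        bool p_wins = (zp[pk_p] > zp[pk_q]) ||
                      (zp[pk_p] == zp[pk_q] && pk_p < pk_q);
        int winner = p_wins ? rp : rq;
        int loser_peak = p_wins ? pk_q : pk_p;
        int loser = p_wins ? rq : rp;
        prom[loser_peak] = zp[loser_peak] - level;  // key saddle = level
        parent[loser] = winner;
        comp_peak[winner] = p_wins ? pk_p : pk_q;
      }
    }
  }
  // surviving root holds the global maximum
  for (int k = 0; k < n; ++k) {
    if (parent[k] == k && uf_find(parent, k) == k) {
      int pk = comp_peak[k];
      if (ISNAN(prom[pk])) prom[pk] = zp[pk] - zmin;
    }
  }

  std::vector<int> rows, cols;
  std::vector<double> height, prominence;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int k = i + j * nr;
      if (is_summit[k]) {
        rows.push_back(i + 1);
        cols.push_back(j + 1);
        height.push_back(zp[k]);
        prominence.push_back(prom[k]);
      }
    }
  return List::create(_["row"] = rows, _["col"] = cols,
                      _["height"] = height, _["prominence"] = prominence);
}
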