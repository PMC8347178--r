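#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Cell-list (uniform grid) neighbour search. Cell edge = the search radius,
// so all pairs closer than the radius lie in the 3x3 cell neighbourhood.
// Results are exact and identical to all-pairs enumeration.

typedef std::unordered_map<long long, std::vector<int> > Grid;

static inline long long cell_key(double x, double y, double cs) {
  long long cx = (long long)std::floor(x / cs);
  long long cy = (long long)std::floor(y / cs);
  return cx * 2000003LL + cy;
}

static Grid build_grid(const NumericVector& x, const NumericVector& y, double cs) {
  Grid g;
  for (int i = 0; i < x.size(); ++i)
    g[cell_key(x[i], y[i], cs)].push_back(i);
  return g;
}

// [[Rcpp::export(name = ".pair_hist_counts")]]
NumericVector pair_hist_counts(NumericVector x, NumericVector y,
                               double r_max, double bin_width) {
  int nbins = (int)std::ceil(r_max / bin_width - 1e-12);
  NumericVector counts(nbins);
  double cs = r_max;
  Grid g = build_grid(x, y, cs);
  double r2 = r_max * r_max;
  for (int i = 0; i < x.size(); ++i) {
    long long cx = (long long)std::floor(x[i] / cs);
    long long cy = (long long)std::floor(y[i] / cs);
    for (long long dx = -1; dx <= 1; ++dx) {
      for (long long dy = -1; dy <= 1; ++dy) {
        Grid::const_iterator it = g.find((cx + dx) * 2000003LL + (cy + dy));
        if (it == g.end()) continue;
        const std::vector<int>& v = it->second;
        for (size_t k = 0; k < v.size(); ++k) {
          int j = v[k];
          if (j <= i) continue;                    // unordered pairs, i < j
          double ddx = x[i] - x[j], ddy = y[i] - y[j];
          double d2 = ddx * ddx + ddy * ddy;
          if (d2 < r2) {
            int b = (int)(std::sqrt(d2) / bin_width);
            if (b >= nbins) b = nbins - 1;
            counts[b] += 1.0;
          }
        }
      }
    }
  }
  return counts;
}

// [[Rcpp::export(name = ".cross_hist_counts")]]
NumericVector cross_hist_counts(NumericVector xa, NumericVector ya,
                                NumericVector xb, NumericVector yb,
                                double r_max, double bin_width) {
  int nbins = (int)std::ceil(r_max / bin_width - 1e-12);
  NumericVector counts(nbins);
  double cs = r_max;
  Grid g = build_grid(xb, yb, cs);
  double r2 = r_max * r_max;
  for (int i = 0; i < xa.size(); ++i) {
    long long cx = (long long)std::floor(xa[i] / cs);
    long long cy = (long long)std::floor(ya[i] / cs);
    for (long long dx = -1; dx <= 1; ++dx) {
      for (long long dy = -1; dy <= 1; ++dy) {
        Grid::const_iterator it = g.find((cx + dx) * 2000003LL + (cy + dy));
        if (it == g.end()) continue;
        const std::vector<int>& v = it->second;
        for (size_t k = 0; k < v.size(); ++k) {
          int j = v[k];
          double ddx = xa[i] - xb[j], ddy = ya[i] - yb[j];
          double d2 = ddx * ddx + ddy * ddy;
          if (d2 < r2) {
            int b = (int)(std::sqrt(d2) / bin_width);
            if (b >= nbins) b = nbins - 1;
            counts[b] += 1.0;
          }
        }
      }
    }
  }
  return counts;
}

// For each point of A, does any point of B lie within radius (<=)?
// [[Rcpp::export(name = ".has_neighbor_within")]]
LogicalVector has_neighbor_within(NumericVector xa, NumericVector ya,
                                  NumericVector xb, NumericVector yb,
                                  double radius) {
  LogicalVector out(xa.size());
  double cs = radius > 0 ? radius : 1.0;
  Grid g = build_grid(xb, yb, cs);
  double r2 = radius * radius;
  for (int i = 0; i < xa.size(); ++i) {
    bool found = false;
    long long cx = (long long)std::floor(xa[i] / cs);
    long long cy = (long long)std::floor(ya[i] / cs);
    for (long long dx = -1; dx <= 1 && !found; ++dx) {
      for (long long dy = -1; dy <= 1 && !found; ++dy) {
        Grid::const_iterator it = g.find((cx + dx) * 2000003LL + (cy + dy));
        if (it == g.end()) continue;
        const std::vector<int>& v = it->second;
        for (size_t k = 0; k < v.size(); ++k) {
          int j = v[k];
          double ddx = xa[i] - xb[j], ddy = ya[i] - yb[j];
          if (ddx * ddx + ddy * ddy <= r2) { found = true; break; }
        }
      }
    }
    out[i] = found;
  }
  return out;
}
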