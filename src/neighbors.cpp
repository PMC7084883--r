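#include <Rcpp.h>
#include <array>
#include <map>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Uniform-grid cell list for fixed-radius neighbour queries in 3-D.
// Cell edge == search radius, so all neighbours of a point within r lie in
// the 27-cell block around its cell.  Boundaries are closed (d <= r), applied
// as d^2 <= r^2 on doubles so results are bit-identical to the brute-force
// scan used as the test oracle.

typedef std::array<int, 3> CellKey;
typedef std::map<CellKey, std::vector<int> > CellMap;

static inline CellKey cell_of(double x, double y, double z, double r) {
  CellKey k;
  k[0] = (int)std::floor(x / r);
  k[1] = (int)std::floor(y / r);
  k[2] = (int)std::floor(z / r);
  return k;
}

static CellMap build_grid(const NumericMatrix& pts, double r) {
  CellMap grid;
  for (int i = 0; i < pts.nrow(); ++i)
    grid[cell_of(pts(i, 0), pts(i, 1), pts(i, 2), r)].push_back(i);
  return grid;
}

// All unordered pairs (i < j, 1-based) with separation <= r.
// [[Rcpp::export(name = ".cpp_pairs_within")]]
IntegerMatrix cpp_pairs_within(NumericMatrix pts, double r) {
  const int n = pts.nrow();
  const double r2 = r * r;
  std::vector<int> ai, aj;
  if (n >= 2 && r > 0) {
    CellMap grid = build_grid(pts, r);
    for (int i = 0; i < n; ++i) {
      CellKey c = cell_of(pts(i, 0), pts(i, 1), pts(i, 2), r);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            CellKey nb = {{c[0] + dx, c[1] + dy, c[2] + dz}};
            CellMap::const_iterator it = grid.find(nb);
            if (it == grid.end()) continue;
            for (size_t m = 0; m < it->second.size(); ++m) {
              int j = it->second[m];
              if (j <= i) continue;
              double ddx = pts(i, 0) - pts(j, 0);
              double ddy = pts(i, 1) - pts(j, 1);
              double ddz = pts(i, 2) - pts(j, 2);
              if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) {
                ai.push_back(i + 1);
                aj.push_back(j + 1);
              }
            }
          }
    }
  }
  IntegerMatrix out(ai.size(), 2);
  for (size_t k = 0; k < ai.size(); ++k) {
    out(k, 0) = ai[k];
    out(k, 1) = aj[k];
  }
  colnames(out) = CharacterVector::create("i", "j");
  return out;
}

// For each centre, the number of points within <= r.
// [[Rcpp::export(name = ".cpp_radius_counts")]]
IntegerVector cpp_radius_counts(NumericMatrix pts, NumericMatrix centers,
                                double r) {
  const int nc = centers.nrow();
  const double r2 = r * r;
  IntegerVector out(nc);
  if (pts.nrow() == 0 || nc == 0 || r <= 0) return out;
  CellMap grid = build_grid(pts, r);
  for (int i = 0; i < nc; ++i) {
    CellKey c = cell_of(centers(i, 0), centers(i, 1), centers(i, 2), r);
    int cnt = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          CellKey nb = {{c[0] + dx, c[1] + dy, c[2] + dz}};
          CellMap::const_iterator it = grid.find(nb);
          if (it == grid.end()) continue;
          for (size_t m = 0; m < it->second.size(); ++m) {
            int j = it->second[m];
            double ddx = centers(i, 0) - pts(j, 0);
            double ddy = centers(i, 1) - pts(j, 1);
            double ddz = centers(i, 2) - pts(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) ++cnt;
          }
        }
    out[i] = cnt;
  }
  return out;
}
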