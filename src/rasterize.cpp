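#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Rasterize a triangulated height field onto a regular x/y grid by
// barycentric interpolation of vertex z. Grid nodes not covered by any
// triangle stay NA. Later faces overwrite earlier ones where triangles
// overlap in projection (meshes are expected to be height fields).
// [[Rcpp::export]]
NumericMatrix rasterize_mesh_cpp(NumericMatrix verts, IntegerMatrix faces,
                                 double x0, double y0, double pitch,
                                 int nx, int ny) {
  NumericMatrix z(nx, ny);
  std::fill(z.begin(), z.end(), NA_REAL);
  const int nf = faces.nrow();
  for (int f = 0; f < nf; ++f) {
    const int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    const double ax = verts(a, 0), ay = verts(a, 1), az = verts(a, 2);
    const double bx = verts(b, 0), by = verts(b, 1), bz = verts(b, 2);
    const double cx = verts(c, 0), cy = verts(c, 1), cz = verts(c, 2);
    const double det = (by - cy) * (ax - cx) + (cx - bx) * (ay - cy);
    if (det == 0.0) continue;  // degenerate in projection
    double xmin = std::min(ax, std::min(bx, cx));
    double xmax = std::max(ax, std::max(bx, cx));
    double ymin = std::min(ay, std::min(by, cy));
    double ymax = std::max(ay, std::max(by, cy));
    int i0 = std::max(0, (int)std::ceil((xmin - x0) / pitch - 1e-9));
    int i1 = std::min(nx - 1, (int)std::floor((xmax - x0) / pitch + 1e-9));
    int j0 = std::max(0, (int)std::ceil((ymin - y0) / pitch - 1e-9));
    int j1 = std::min(ny - 1, (int)std::floor((ymax - y0) / pitch + 1e-9));
    for (int i = i0; i <= i1; ++i) {
      const double px = x0 + i * pitch;
      for (int j = j0; j <= j1; ++j) {
        const double py = y0 + j * pitch;
        double l1 = ((by - cy) * (px - cx) + (cx - bx) * (py - cy)) / det;
        double l2 = ((cy - ay) * (px - cx) + (ax - cx) * (py - cy)) / det;
        double l3 = 1.0 - l1 - l2;
        const double eps = -1e-9;
        if (l1 >= eps && l2 >= eps && l3 >= eps)
          z(i, j) = l1 * az + l2 * bz + l3 * cz;
      }
    }
  }
  return z;
}

// Median nearest-neighbor spacing of a planar point set, via a uniform
// grid hash. Evaluated on at most max_sample points (deterministic
// stride subsample) against the full set.
// [[Rcpp::export]]
double median_nn_spacing_cpp(NumericMatrix xy, int max_sample = 5000) {
  const int n = xy.nrow();
  if (n < 2) return NA_REAL;
  double xmin = xy(0, 0), xmax = xy(0, 0), ymin = xy(0, 1), ymax = xy(0, 1);
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, xy(i, 0)); xmax = std::max(xmax, xy(i, 0));
    ymin = std::min(ymin, xy(i, 1)); ymax = std::max(ymax, xy(i, 1));
  }
  double w = std::max(xmax - xmin, 1e-300), h = std::max(ymax - ymin, 1e-300);
  double cell = std::sqrt(w * h / n) * 2.0;
  if (!(cell > 0)) cell = 1.0;
  int gx = std::max(1, (int)std::floor(w / cell) + 1);
  int gy = std::max(1, (int)std::floor(h / cell) + 1);
  std::vector<std::vector<int> > buckets((size_t)gx * gy);
  std::vector<int> bi(n), bj(n);
  for (int i = 0; i < n; ++i) {
    int ci = std::min(gx - 1, (int)((xy(i, 0) - xmin) / cell));
    int cj = std::min(gy - 1, (int)((xy(i, 1) - ymin) / cell));
    bi[i] = ci; bj[i] = cj;
    buckets[(size_t)ci * gy + cj].push_back(i);
  }
  int stride = std::max(1, n / max_sample);
  std::vector<double> nnd;
  for (int i = 0; i < n; i += stride) {
    double best = R_PosInf;
    for (int ring = 1; ring <= std::max(gx, gy); ++ring) {
      int r = ring - 1;
      for (int ci = bi[i] - r; ci <= bi[i] + r; ++ci) {
        if (ci < 0 || ci >= gx) continue;
        for (int cj = bj[i] - r; cj <= bj[i] + r; ++cj) {
          if (cj < 0 || cj >= gy) continue;
          if (ring > 1 && std::abs(ci - bi[i]) < r && std::abs(cj - bj[i]) < r)
            continue;  // interior rings already scanned
          const std::vector<int> &bk = buckets[(size_t)ci * gy + cj];
          for (size_t k = 0; k < bk.size(); ++k) {
            int j = bk[k];
            if (j == i) continue;
            double dx = xy(i, 0) - xy(j, 0), dy = xy(i, 1) - xy(j, 1);
            double d = std::sqrt(dx * dx + dy * dy);
            if (d < best) best = d;
          }
        }
      }
      // once a neighbor is found, one extra ring guarantees correctness
      if (R_FINITE(best) && r >= 1) break;
    }
    if (R_FINITE(best)) nnd.push_back(best);
  }
  if (nnd.empty()) return NA_REAL;
  std::sort(nnd.begin(), nnd.end());
  size_t m = nnd.size();
  return (m % 2 == 1) ? nnd[m / 2] : 0.5 * (nnd[m / 2 - 1] + nnd[m / 2]);
}
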