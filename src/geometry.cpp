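#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sutherland-Hodgman clip of a convex polygon by the half-plane
// { x : (x - m) . n <= 0 }.
static void clip_halfplane(std::vector<double>& xs, std::vector<double>& ys,
                           double mx, double my, double nx, double ny) {
  const int n = static_cast<int>(xs.size());
  std::vector<double> ox, oy;
  ox.reserve(n + 4);
  oy.reserve(n + 4);
  for (int i = 0; i < n; ++i) {
    const int j = (i + 1) % n;
    const double di = (xs[i] - mx) * nx + (ys[i] - my) * ny;
    const double dj = (xs[j] - mx) * nx + (ys[j] - my) * ny;
    const bool ini = di <= 0.0, inj = dj <= 0.0;
    if (ini) {
      ox.push_back(xs[i]);
      oy.push_back(ys[i]);
    }
    if (ini != inj) {
      const double t = di / (di - dj);
      ox.push_back(xs[i] + t * (xs[j] - xs[i]));
      oy.push_back(ys[i] + t * (ys[j] - ys[i]));
    }
  }
  xs.swap(ox);
  ys.swap(oy);
}

// Per-site Voronoi cell areas by iterative half-plane clipping.
// pts holds the n_orig original sites first, then their periodic ghost
// copies; every site's cell is clipped against the bisector of each other
// point. Neighbours are visited nearest-first so clipping can stop as soon
// as the remaining bisectors cannot intersect the current cell.
// [[Rcpp::export]]
NumericVector voronoi_areas_cpp(NumericMatrix pts, int n_orig, double bound) {
  const int n = pts.nrow();
  NumericVector areas(n_orig);
  std::vector<int> ord(n);
  std::vector<double> d2(n);
  for (int i = 0; i < n_orig; ++i) {
    const double sx = pts(i, 0), sy = pts(i, 1);
    for (int j = 0; j < n; ++j) {
      const double dx = pts(j, 0) - sx, dy = pts(j, 1) - sy;
      d2[j] = dx * dx + dy * dy;
      ord[j] = j;
    }
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return d2[a] < d2[b]; });
    std::vector<double> xs = {sx - bound, sx + bound, sx + bound, sx - bound};
    std::vector<double> ys = {sy - bound, sy - bound, sy + bound, sy + bound};
    for (int k = 0; k < n; ++k) {
      const int j = ord[k];
      if (j == i || d2[j] == 0.0) continue;
      double maxr2 = 0.0;
      for (size_t v = 0; v < xs.size(); ++v) {
        const double dx = xs[v] - sx, dy = ys[v] - sy;
        const double r2 = dx * dx + dy * dy;
        if (r2 > maxr2) maxr2 = r2;
      }
      // a bisector at distance sqrt(d2)/2 beyond every vertex cannot cut
      if (d2[j] > 4.0 * maxr2) break;
      clip_halfplane(xs, ys, 0.5 * (sx + pts(j, 0)), 0.5 * (sy + pts(j, 1)),
                     pts(j, 0) - sx, pts(j, 1) - sy);
      if (xs.size() < 3) break;
    }
    double a = 0.0;
    const int m = static_cast<int>(xs.size());
    for (int v = 0; v < m; ++v) {
      const int w = (v + 1) % m;
      a += xs[v] * ys[w] - xs[w] * ys[v];
    }
    areas[i] = 0.5 * std::fabs(a);
  }
  return areas;
}

// Nearest-site fill of an nx x ny fractional grid over the in-plane cell.
// hmat rows are the in-plane lattice vectors (v1, v2); sites are Cartesian
// xy coordinates. Distances use the in-plane minimum-image convention.
// Returns the 1-based index of the nearest site and the distance, per pixel
// (matrices indexed [iy, ix]).
// [[Rcpp::export]]
List raster_nearest_cpp(int nx, int ny, NumericMatrix hmat,
                        NumericMatrix sites) {
  const double a11 = hmat(0, 0), a12 = hmat(0, 1);
  const double a21 = hmat(1, 0), a22 = hmat(1, 1);
  const double det = a11 * a22 - a12 * a21;
  const int ns = sites.nrow();
  std::vector<double> fs1(ns), fs2(ns);
  for (int s = 0; s < ns; ++s) {
    const double x = sites(s, 0), y = sites(s, 1);
    const double f1 = (x * a22 - y * a21) / det;
    const double f2 = (y * a11 - x * a12) / det;
    fs1[s] = f1 - std::floor(f1);
    fs2[s] = f2 - std::floor(f2);
  }
  IntegerMatrix idx(ny, nx);
  NumericMatrix dist(ny, nx);
  for (int ix = 0; ix < nx; ++ix) {
    const double p1 = (ix + 0.5) / nx;
    for (int iy = 0; iy < ny; ++iy) {
      const double p2 = (iy + 0.5) / ny;
      double best = 1e300;
      int bi = -1;
      for (int s = 0; s < ns; ++s) {
        double df1 = fs1[s] - p1, df2 = fs2[s] - p2;
        df1 -= std::round(df1);
        df2 -= std::round(df2);
        for (int s1 = -1; s1 <= 1; ++s1) {
          for (int s2 = -1; s2 <= 1; ++s2) {
            const double g1 = df1 + s1, g2 = df2 + s2;
            const double dx = g1 * a11 + g2 * a21;
            const double dy = g1 * a12 + g2 * a22;
            const double r2 = dx * dx + dy * dy;
            if (r2 < best) {
              best = r2;
              bi = s;
            }
          }
        }
      }
      idx(iy, ix) = bi + 1;
      dist(iy, ix) = std::sqrt(best);
    }
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

// Brute-force pixel-count areas: every pixel centre of an ngrid x ngrid
// fractional grid is assigned to the closest site over all 9 explicit
// in-plane periodic images, by plain Euclidean distance. Kept deliberately
// naive and separate from the clipping code: it serves as an independent
// oracle for the Voronoi areas.
// [[Rcpp::export]]
NumericVector pixel_count_areas_cpp(int ngrid, NumericMatrix hmat,
                                    NumericMatrix sites) {
  const double a11 = hmat(0, 0), a12 = hmat(0, 1);
  const double a21 = hmat(1, 0), a22 = hmat(1, 1);
  const int ns = sites.nrow();
  std::vector<double> imx, imy;
  std::vector<int> parent;
  imx.reserve(ns * 9);
  imy.reserve(ns * 9);
  parent.reserve(ns * 9);
  for (int s = 0; s < ns; ++s) {
    for (int s1 = -1; s1 <= 1; ++s1) {
      for (int s2 = -1; s2 <= 1; ++s2) {
        imx.push_back(sites(s, 0) + s1 * a11 + s2 * a21);
        imy.push_back(sites(s, 1) + s1 * a12 + s2 * a22);
        parent.push_back(s);
      }
    }
  }
  const int nim = static_cast<int>(imx.size());
  std::vector<long long> counts(ns, 0);
  for (int i = 0; i < ngrid; ++i) {
    const double f1 = (i + 0.5) / ngrid;
    for (int j = 0; j < ngrid; ++j) {
      const double f2 = (j + 0.5) / ngrid;
      const double px = f1 * a11 + f2 * a21;
      const double py = f1 * a12 + f2 * a22;
      double best = 1e300;
      int bi = 0;
      for (int m = 0; m < nim; ++m) {
        const double dx = imx[m] - px, dy = imy[m] - py;
        const double r2 = dx * dx + dy * dy;
        if (r2 < best) {
          best = r2;
          bi = parent[m];
        }
      }
      counts[bi] += 1;
    }
  }
  const double cross = std::fabs(a11 * a22 - a12 * a21);
  const double pix = cross / (static_cast<double>(ngrid) * ngrid);
  NumericVector areas(ns);
  for (int s = 0; s < ns; ++s) areas[s] = counts[s] * pix;
  return areas;
}
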