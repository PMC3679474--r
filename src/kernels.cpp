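#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Pixel-level kernels for the morphometry and phantom-rendering paths.
// Everything here is deterministic: no RNG, no thread-order dependence.

// Voronoi parenchyma mask: a pixel is tissue (0) when it lies within
// half_septum of the boundary between its own Voronoi cell and any
// neighbouring cell; airspace (1) otherwise. Distance to the boundary with
// site b, seen from a pixel whose nearest site is a, is the exact
// point-to-bisector distance (d_b^2 - d_a^2) / (2 |a - b|).
// centers: n x 2 matrix of (x, y) in pixel units, 0-based continuous coords.
// [[Rcpp::export]]
IntegerMatrix voronoi_airspace_mask(NumericMatrix centers, int width, int height,
                                    double half_septum) {
  const int n = centers.nrow();
  if (n < 1) stop("need at least one Voronoi site");
  if (width < 1 || height < 1) stop("non-positive image dimensions");

  // bucket sites on a grid of roughly one mean inter-site spacing
  double spacing = std::sqrt((double)width * (double)height / (double)n);
  double bs = std::max(spacing, 4.0);
  int bw = std::max(1, (int)std::ceil(width / bs));
  int bh = std::max(1, (int)std::ceil(height / bs));
  std::vector< std::vector<int> > buckets((size_t)bw * bh);
  for (int i = 0; i < n; ++i) {
    int bx = std::min(bw - 1, std::max(0, (int)(centers(i, 0) / bs)));
    int by = std::min(bh - 1, std::max(0, (int)(centers(i, 1) / bs)));
    buckets[(size_t)by * bw + bx].push_back(i);
  }

  std::vector<double> cx(n), cy(n);
  for (int i = 0; i < n; ++i) { cx[i] = centers(i, 0); cy[i] = centers(i, 1); }

  IntegerMatrix mask(height, width);
  std::vector<int> cand;
  cand.reserve(128);
  // candidate sites are gathered once per bucket cell, then reused for
  // every pixel inside that bucket
  for (int by = 0; by < bh; ++by) {
    int y0 = (int)(by * bs), y1 = std::min(height, (int)((by + 1) * bs));
    for (int bx = 0; bx < bw; ++bx) {
      int x0 = (int)(bx * bs), x1 = std::min(width, (int)((bx + 1) * bs));
      int ring = 2;
      for (;;) {
        cand.clear();
        for (int dy = -ring; dy <= ring; ++dy) {
          int yy = by + dy;
          if (yy < 0 || yy >= bh) continue;
          for (int dx = -ring; dx <= ring; ++dx) {
            int xx = bx + dx;
            if (xx < 0 || xx >= bw) continue;
            const std::vector<int> &b = buckets[(size_t)yy * bw + xx];
            cand.insert(cand.end(), b.begin(), b.end());
          }
        }
        if ((int)cand.size() >= 2 || (ring >= bw && ring >= bh)) break;
        ++ring;
      }
      if ((int)cand.size() < 2) {
        cand.resize(n);
        for (int i = 0; i < n; ++i) cand[i] = i;
      }
      const int nc = (int)cand.size();
      for (int y = y0; y < y1; ++y) {
        for (int x = x0; x < x1; ++x) {
          int a = -1;
          double d2a = R_PosInf;
          for (int k = 0; k < nc; ++k) {
            int idx = cand[k];
            double ddx = x - cx[idx], ddy = y - cy[idx];
            double d2 = ddx * ddx + ddy * ddy;
            if (d2 < d2a) { d2a = d2; a = idx; }
          }
          double dmin = R_PosInf;
          for (int k = 0; k < nc; ++k) {
            int idx = cand[k];
            if (idx == a) continue;
            double ddx = x - cx[idx], ddy = y - cy[idx];
            double d2b = ddx * ddx + ddy * ddy;
            double abx = cx[idx] - cx[a], aby = cy[idx] - cy[a];
            double ab = std::sqrt(abx * abx + aby * aby);
            if (ab <= 0) continue;
            double d = (d2b - d2a) / (2.0 * ab);
            if (d < dmin) dmin = d;
          }
          mask(y, x) = (dmin < half_septum) ? 0 : 1;
        }
      }
    }
  }
  return mask;
}

// Two-cluster Lloyd iteration with caller-supplied (deterministic) initial
// centroids. x: n x p feature matrix, init: 2 x p. Stops when assignments
// stabilise. Returns 0/1 assignments, final centroids and iteration count.
// [[Rcpp::export]]
List kmeans2_lloyd(NumericMatrix x, NumericMatrix init, int max_iter = 100) {
  const int n = x.nrow(), p = x.ncol();
  if (init.nrow() != 2 || init.ncol() != p) stop("init must be 2 x ncol(x)");
  NumericMatrix cen = clone(init);
  IntegerVector assign(n, -1);
  bool changed = true;
  int iter = 0;
  while (changed && iter < max_iter) {
    changed = false;
    ++iter;
    std::vector<double> sum0(p, 0.0), sum1(p, 0.0);
    long n0 = 0, n1 = 0;
    for (int i = 0; i < n; ++i) {
      double d0 = 0, d1 = 0;
      for (int j = 0; j < p; ++j) {
        double a = x(i, j) - cen(0, j);
        d0 += a * a;
        double b = x(i, j) - cen(1, j);
        d1 += b * b;
      }
      int cl = (d1 < d0) ? 1 : 0;  // ties go to cluster 0
      if (cl != assign[i]) { assign[i] = cl; changed = true; }
      if (cl == 0) { ++n0; for (int j = 0; j < p; ++j) sum0[j] += x(i, j); }
      else         { ++n1; for (int j = 0; j < p; ++j) sum1[j] += x(i, j); }
    }
    if (n0 > 0) for (int j = 0; j < p; ++j) cen(0, j) = sum0[j] / n0;
    if (n1 > 0) for (int j = 0; j < p; ++j) cen(1, j) = sum1[j] / n1;
  }
  return List::create(_["cluster"] = assign, _["centers"] = cen,
                      _["iterations"] = iter);
}

static int uf_find(std::vector<int> &p, int i) {
  while (p[i] != i) { p[i] = p[p[i]]; i = p[i]; }
  return i;
}

// 8-connected component labelling of the foreground (non-zero) pixels of a
// binary raster, two-pass union-find. Returns labels (0 = background,
// 1..K = components) and the pixel area of each component.
// [[Rcpp::export]]
List label_components8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);  // index 0 unused
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      if (mask(y, x) == 0) { lab(y, x) = 0; continue; }
      int neigh[4];
      int nn = 0;
      if (x > 0 && lab(y, x - 1)) neigh[nn++] = lab(y, x - 1);
      if (y > 0) {
        if (lab(y - 1, x)) neigh[nn++] = lab(y - 1, x);
        if (x > 0 && lab(y - 1, x - 1)) neigh[nn++] = lab(y - 1, x - 1);
        if (x < W - 1 && lab(y - 1, x + 1)) neigh[nn++] = lab(y - 1, x + 1);
      }
      if (nn == 0) {
        int nl = (int)parent.size();
        parent.push_back(nl);
        lab(y, x) = nl;
      } else {
        int m = neigh[0];
        for (int k = 1; k < nn; ++k) m = std::min(m, neigh[k]);
        lab(y, x) = m;
        for (int k = 0; k < nn; ++k) {
          int a = uf_find(parent, m), b = uf_find(parent, neigh[k]);
          if (a != b) parent[std::max(a, b)] = std::min(a, b);
        }
      }
    }
  }
  std::vector<int> root(parent.size(), 0), newid(parent.size(), 0);
  int cnt = 0;
  for (size_t i = 1; i < parent.size(); ++i) root[i] = uf_find(parent, i);
  for (size_t i = 1; i < parent.size(); ++i)
    if (root[i] == (int)i) newid[i] = ++cnt;
  IntegerVector area(cnt);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x)
      if (lab(y, x)) {
        int id = newid[root[lab(y, x)]];
        lab(y, x) = id;
        area[id - 1] += 1;
      }
  return List::create(_["labels"] = lab, _["areas"] = area);
}

// Render a class-index raster (values 1..K indexing palette rows) to an
// H x W x 3 array, adding clipped Gaussian pixel noise drawn from R's RNG
// stream (deterministic under set.seed).
// [[Rcpp::export]]
NumericVector render_classes(IntegerMatrix classes, NumericMatrix palette,
                             double noise_sd) {
  const int H = classes.nrow(), W = classes.ncol();
  const int K = palette.nrow();
  NumericVector img((R_xlen_t)H * W * 3);
  const R_xlen_t plane = (R_xlen_t)H * W;
  for (int ch = 0; ch < 3; ++ch) {
    R_xlen_t off = plane * ch;
    for (int x = 0; x < W; ++x) {
      for (int y = 0; y < H; ++y) {
        int k = classes(y, x);
        if (k < 1 || k > K) stop("class index out of palette range");
        double v = palette(k - 1, ch);
        if (noise_sd > 0) {
          v += norm_rand() * noise_sd;
          if (v < 0) v = 0; else if (v > 1) v = 1;
        }
        img[off + (R_xlen_t)x * H + y] = v;
      }
    }
  }
  img.attr("dim") = IntegerVector::create(H, W, 3);
  return img;
}
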