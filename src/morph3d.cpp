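// 3D image primitives operating on R arrays laid out (z, y, x) column-major.
// All distances are physical: each axis pass of the EDT is weighted by its
// voxel spacing, so downstream erosion/dilation bands are specified in um.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform (lower envelope of parabolas), spacing s.
// Parabolas with infinite height are excluded from the envelope.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double s) {
  std::vector<int> idx;
  idx.reserve(n);
  for (int i = 0; i < n; i++) if (f[i] != INF) idx.push_back(i);
  if (idx.empty()) { for (int i = 0; i < n; i++) d[i] = INF; return; }

  std::vector<int> v(idx.size());
  std::vector<double> z(idx.size() + 1);
  const double s2 = s * s;
  int k = 0;
  v[0] = idx[0]; z[0] = -INF; z[1] = INF;
  for (size_t m = 1; m < idx.size(); m++) {
    int q = idx[m];
    double sp;
    while (true) {
      int p = v[k];
      sp = ((f[q] + s2 * (double)q * q) - (f[p] + s2 * (double)p * p)) /
           (2.0 * s2 * (q - p));
      if (sp <= z[k] && k > 0) { k--; } else break;
    }
    if (sp <= z[k]) { v[k] = q; }  // replaces the lone remaining parabola
    else { k++; v[k] = q; z[k] = sp; }
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double diff = (double)(q - v[k]);
    d[q] = s2 * diff * diff + f[v[k]];
  }
}

// Squared Euclidean distance from every voxel to the nearest zero voxel of
// `mask` (i.e. distance-to-background of the foreground), with anisotropic
// spacing (sz, sy, sx). dims = (nz, ny, nx).
// [[Rcpp::export]]
NumericVector cpp_sq_edt(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? INF : 0.0;

  std::vector<double> f, d;
  // pass along z (fastest-varying)
  f.resize(nz); d.resize(nz);
  for (int x = 0; x < nx; x++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int z = 0; z < nz; z++) f[z] = out[base + z];
      dt1d(f, d, nz, spacing[0]);
      for (int z = 0; z < nz; z++) out[base + z] = d[z];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int x = 0; x < nx; x++)
    for (int z = 0; z < nz; z++) {
      R_xlen_t base = z + (R_xlen_t)nz * ny * x;
      for (int y = 0; y < ny; y++) f[y] = out[base + (R_xlen_t)nz * y];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; y++) out[base + (R_xlen_t)nz * y] = d[y];
    }
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int y = 0; y < ny; y++)
    for (int z = 0; z < nz; z++) {
      R_xlen_t base = z + (R_xlen_t)nz * y;
      R_xlen_t stride = (R_xlen_t)nz * ny;
      for (int x = 0; x < nx; x++) f[x] = out[base + stride * x];
      dt1d(f, d, nx, spacing[2]);
      for (int x = 0; x < nx; x++) out[base + stride * x] = d[x];
    }
  return out;
}

struct WsEntry {
  double value;
  R_xlen_t order;   // insertion order: deterministic tie-break
  R_xlen_t idx;
  int label;
};
struct WsCompare {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.value != b.value) return a.value > b.value;  // min-heap on value
    return a.order > b.order;
  }
};

// Marker-based priority-flood watershed on `relief` restricted to `mask`.
// Seeds carry positive labels; the flood grows from low relief upward.
// [[Rcpp::export]]
IntegerVector cpp_seeded_watershed(NumericVector relief, IntegerVector seeds,
                                   LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector labels(n, 0);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCompare> pq;
  R_xlen_t order = 0;
  for (R_xlen_t i = 0; i < n; i++) {
    if (seeds[i] > 0 && mask[i]) {
      labels[i] = seeds[i];
      pq.push(WsEntry{relief[i], order++, i, seeds[i]});
    }
  }
  const R_xlen_t dz = 1, dy = nz, dx = (R_xlen_t)nz * ny;
  while (!pq.empty()) {
    WsEntry e = pq.top(); pq.pop();
    R_xlen_t i = e.idx;
    int z = (int)(i % nz), y = (int)((i / nz) % ny), x = (int)(i / dx);
    const int offs[6][2] = {{0,-1},{0,1},{1,-1},{1,1},{2,-1},{2,1}};
    for (int k = 0; k < 6; k++) {
      int ax = offs[k][0], dir = offs[k][1];
      int zz = z + (ax == 0 ? dir : 0);
      int yy = y + (ax == 1 ? dir : 0);
      int xx = x + (ax == 2 ? dir : 0);
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t j = zz * dz + (R_xlen_t)yy * dy + (R_xlen_t)xx * dx;
      if (!mask[j] || labels[j] != 0) continue;
      labels[j] = e.label;
      double v = relief[j] > e.value ? relief[j] : e.value;
      pq.push(WsEntry{v, order++, j, e.label});
    }
  }
  return labels;
}

// Connected-component labeling (face connectivity) of a logical mask.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  const R_xlen_t dx = (R_xlen_t)nz * ny;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || labels[s] != 0) continue;
    next++;
    labels[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t i = stack.back(); stack.pop_back();
      int z = (int)(i % nz), y = (int)((i / nz) % ny), x = (int)(i / dx);
      const int offs[6][2] = {{0,-1},{0,1},{1,-1},{1,1},{2,-1},{2,1}};
      for (int k = 0; k < 6; k++) {
        int ax = offs[k][0], dir = offs[k][1];
        int zz = z + (ax == 0 ? dir : 0);
        int yy = y + (ax == 1 ? dir : 0);
        int xx = x + (ax == 2 ? dir : 0);
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t j = zz + (R_xlen_t)nz * yy + dx * xx;
        if (mask[j] && labels[j] == 0) { labels[j] = next; stack.push_back(j); }
      }
    }
  }
  return labels;
}

// ---- Bowyer-Watson 2D Delaunay --------------------------------------------

struct Tri { int a, b, c; double cx, cy, r2; bool alive; };

static Tri make_tri(int a, int b, int c,
                    const std::vector<double>& px,
                    const std::vector<double>& py) {
  Tri t; t.a = a; t.b = b; t.c = c; t.alive = true;
  double ax = px[a], ay = py[a], bx = px[b], by = py[b], cx = px[c], cy = py[c];
  double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  if (std::fabs(d) < 1e-300) { t.cx = t.cy = 0; t.r2 = INF; return t; }
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by, c2 = cx * cx + cy * cy;
  t.cx = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
  t.cy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
  double dx = ax - t.cx, dy = ay - t.cy;
  t.r2 = dx * dx + dy * dy;
  return t;
}

// Returns an (ntri x 3) matrix of 1-based point indices.
// [[Rcpp::export]]
IntegerMatrix cpp_delaunay2d(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 3) stop("need at least 3 points");
  std::vector<double> px(x.begin(), x.end()), py(y.begin(), y.end());
  double xmin = px[0], xmax = px[0], ymin = py[0], ymax = py[0];
  for (int i = 1; i < n; i++) {
    xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
    ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
  }
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0) stop("degenerate point set (all points coincide)");
  double midx = 0.5 * (xmin + xmax), midy = 0.5 * (ymin + ymax);
  // super-triangle well outside the data
  px.push_back(midx - 20 * span); py.push_back(midy - span);
  px.push_back(midx + 20 * span); py.push_back(midy - span);
  px.push_back(midx);             py.push_back(midy + 20 * span);
  int s0 = n, s1 = n + 1, s2 = n + 2;

  std::vector<Tri> tris;
  tris.push_back(make_tri(s0, s1, s2, px, py));
  const double eps = 1e-12 * span * span;

  std::vector<std::array<int, 2>> edges;
  for (int p = 0; p < n; p++) {
    edges.clear();
    for (size_t t = 0; t < tris.size(); t++) {
      if (!tris[t].alive) continue;
      double dx = px[p] - tris[t].cx, dy = py[p] - tris[t].cy;
      if (dx * dx + dy * dy <= tris[t].r2 + eps) {
        tris[t].alive = false;
        int vs[3] = {tris[t].a, tris[t].b, tris[t].c};
        for (int e = 0; e < 3; e++) {
          int u = vs[e], v = vs[(e + 1) % 3];
          // keep boundary edges only: shared edges appear twice
          bool dup = false;
          for (size_t q = 0; q < edges.size(); q++) {
            if ((edges[q][0] == v && edges[q][1] == u) ||
                (edges[q][0] == u && edges[q][1] == v)) {
              edges.erase(edges.begin() + q); dup = true; break;
            }
          }
          if (!dup) edges.push_back({u, v});
        }
      }
    }
    for (auto& e : edges) tris.push_back(make_tri(e[0], e[1], p, px, py));
    // compact occasionally to bound the scan cost
    if (tris.size() > 8u * (size_t)(p + 4)) {
      std::vector<Tri> keep;
      keep.reserve(tris.size());
      for (auto& t : tris) if (t.alive) keep.push_back(t);
      tris.swap(keep);
    }
  }
  std::vector<std::array<int, 3>> out;
  for (auto& t : tris) {
    if (!t.alive) continue;
    if (t.a >= n || t.b >= n || t.c >= n) continue;
    out.push_back({t.a + 1, t.b + 1, t.c + 1});
  }
  IntegerMatrix m(out.size(), 3);
  for (size_t i = 0; i < out.size(); i++) {
    m(i, 0) = out[i][0]; m(i, 1) = out[i][1]; m(i, 2) = out[i][2];
  }
  return m;
}
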