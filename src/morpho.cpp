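// Low-level raster primitives shared by segmentation, morphology and FISH
// detection: connected-component labelling (8/26-connectivity), exact
// anisotropic Euclidean distance transform (Felzenszwalb & Huttenlocher
// lower-envelope algorithm per axis), separable Gaussian smoothing,
// seeded priority-flood watershed, and plateau-stable local maxima.
//
// All arrays arrive in R's column-major layout; `dim` is the R dim()
// vector (length 2 or 3) and linear indices are 0-based.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double BIG = 1e30;

struct Geom {
  int nd;
  int d[3];
  R_xlen_t n;
  Geom(IntegerVector dim) {
    nd = dim.size();
    if (nd != 2 && nd != 3) stop("arrays must be 2D or 3D");
    n = 1;
    for (int a = 0; a < nd; ++a) { d[a] = dim[a]; n *= dim[a]; }
    for (int a = nd; a < 3; ++a) d[a] = 1;
  }
  inline void coords(R_xlen_t i, int c[3]) const {
    c[0] = (int)(i % d[0]);
    c[1] = (int)((i / d[0]) % d[1]);
    c[2] = (int)(i / ((R_xlen_t)d[0] * d[1]));
  }
  inline R_xlen_t index(const int c[3]) const {
    return (R_xlen_t)c[0] + (R_xlen_t)d[0] * ((R_xlen_t)c[1] + (R_xlen_t)d[1] * c[2]);
  }
};

// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dim) {
  Geom g(dim);
  if ((R_xlen_t)mask.size() != g.n) stop("mask length does not match dim");
  IntegerVector lab(g.n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  int c[3], nb[3];
  for (R_xlen_t start = 0; start < g.n; ++start) {
    if (!mask[start] || lab[start] != 0) continue;
    ++next;
    lab[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t i = stack.back(); stack.pop_back();
      g.coords(i, c);
      for (int dz = (g.nd == 3 ? -1 : 0); dz <= (g.nd == 3 ? 1 : 0); ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            nb[0] = c[0] + dx; nb[1] = c[1] + dy; nb[2] = c[2] + dz;
            if (nb[0] < 0 || nb[0] >= g.d[0] || nb[1] < 0 || nb[1] >= g.d[1] ||
                nb[2] < 0 || nb[2] >= g.d[2]) continue;
            R_xlen_t j = g.index(nb);
            if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// 1D squared-distance transform along positions x = i*h (lower envelope).
static void dt1d(std::vector<double>& f, std::vector<double>& dst,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double h) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG; z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double xq = q * h;
    double s;
    for (;;) {
      double xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * h;
    dst[q] = dx * dx + f[v[k]];
  }
}

// Squared Euclidean distance from every TRUE voxel to the nearest FALSE
// voxel centre, with per-axis physical spacing. FALSE voxels get 0.
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  Geom g(dim);
  if ((R_xlen_t)mask.size() != g.n) stop("mask length does not match dim");
  if (spacing.size() != g.nd) stop("spacing length must match dim length");
  NumericVector out(g.n);
  for (R_xlen_t i = 0; i < g.n; ++i) out[i] = mask[i] ? BIG : 0.0;

  int maxd = std::max(g.d[0], std::max(g.d[1], g.d[2]));
  std::vector<double> f(maxd), dst(maxd), z(maxd + 1);
  std::vector<int> v(maxd);

  for (int axis = 0; axis < g.nd; ++axis) {
    int n = g.d[axis];
    double h = spacing[axis];
    // stride of this axis and iteration over all perpendicular lines
    R_xlen_t stride = 1;
    for (int a = 0; a < axis; ++a) stride *= g.d[a];
    R_xlen_t nlines = g.n / n;
    for (R_xlen_t line = 0; line < nlines; ++line) {
      // decompose line id into the fixed coordinates
      R_xlen_t rem = line, base = 0, mult = 1;
      for (int a = 0; a < g.nd; ++a) {
        if (a == axis) { mult *= g.d[a]; continue; }
        R_xlen_t ca = rem % g.d[a];
        rem /= g.d[a];
        base += ca * mult;
        mult *= g.d[a];
      }
      for (int q = 0; q < n; ++q) f[q] = out[base + (R_xlen_t)q * stride];
      dt1d(f, dst, v, z, n, h);
      for (int q = 0; q < n; ++q) out[base + (R_xlen_t)q * stride] = dst[q];
    }
  }
  for (R_xlen_t i = 0; i < g.n; ++i) if (out[i] >= BIG) out[i] = R_PosInf;
  out.attr("dim") = dim;
  return out;
}

// Separable Gaussian smoothing with reflected boundaries; sigma per axis
// in voxel units (sigma <= 0 skips that axis).
// [[Rcpp::export(name = ".gauss_sep")]]
NumericVector gauss_sep(NumericVector img, IntegerVector dim, NumericVector sigma) {
  Geom g(dim);
  if ((R_xlen_t)img.size() != g.n) stop("image length does not match dim");
  if (sigma.size() != g.nd) stop("sigma length must match dim length");
  NumericVector cur = clone(img);
  for (int axis = 0; axis < g.nd; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double sum = 0.0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * (double)i * i / (s * s));
      sum += k[i + r];
    }
    for (int i = 0; i <= 2 * r; ++i) k[i] /= sum;

    NumericVector nxt(g.n);
    int n = g.d[axis];
    R_xlen_t stride = 1;
    for (int a = 0; a < axis; ++a) stride *= g.d[a];
    R_xlen_t nlines = g.n / n;
    std::vector<double> line(n);
    for (R_xlen_t li = 0; li < nlines; ++li) {
      R_xlen_t rem = li, base = 0, mult = 1;
      for (int a = 0; a < g.nd; ++a) {
        if (a == axis) { mult *= g.d[a]; continue; }
        R_xlen_t ca = rem % g.d[a];
        rem /= g.d[a];
        base += ca * mult;
        mult *= g.d[a];
      }
      for (int q = 0; q < n; ++q) line[q] = cur[base + (R_xlen_t)q * stride];
      for (int q = 0; q < n; ++q) {
        double acc = 0.0;
        for (int i = -r; i <= r; ++i) {
          int p = q + i;
          if (p < 0) p = -p - 1;            // reflect
          if (p >= n) p = 2 * n - p - 1;
          if (p < 0) p = 0;                 // degenerate short lines
          if (p >= n) p = n - 1;
          acc += k[i + r] * line[p];
        }
        nxt[base + (R_xlen_t)q * stride] = acc;
      }
    }
    cur = nxt;
  }
  cur.attr("dim") = dim;
  return cur;
}

// Plateau-stable local maxima: voxel i is a maximum iff every neighbour j
// satisfies img[j] < img[i], or img[j] == img[i] with j > i (so exactly
// one voxel per tied adjacent pair survives, deterministically).
// [[Rcpp::export(name = ".local_maxima")]]
LogicalVector local_maxima(NumericVector img, IntegerVector dim) {
  Geom g(dim);
  if ((R_xlen_t)img.size() != g.n) stop("image length does not match dim");
  LogicalVector out(g.n, (int)true);
  int c[3], nb[3];
  for (R_xlen_t i = 0; i < g.n; ++i) {
    g.coords(i, c);
    bool ok = true;
    for (int dz = (g.nd == 3 ? -1 : 0); ok && dz <= (g.nd == 3 ? 1 : 0); ++dz)
      for (int dy = -1; ok && dy <= 1; ++dy)
        for (int dx = -1; ok && dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          nb[0] = c[0] + dx; nb[1] = c[1] + dy; nb[2] = c[2] + dz;
          if (nb[0] < 0 || nb[0] >= g.d[0] || nb[1] < 0 || nb[1] >= g.d[1] ||
              nb[2] < 0 || nb[2] >= g.d[2]) continue;
          R_xlen_t j = g.index(nb);
          if (img[j] > img[i] || (img[j] == img[i] && j < i)) ok = false;
        }
    out[i] = ok;
  }
  out.attr("dim") = dim;
  return out;
}

struct QItem {
  double pri;
  unsigned long long order;
  R_xlen_t idx;
  int lab;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.pri != b.pri) return a.pri < b.pri;   // max-heap on priority
    return a.order > b.order;                   // FIFO among ties
  }
};

// Seeded watershed by priority flooding (descending priority, typically a
// distance transform). Every TRUE voxel of `mask` reachable from a seed is
// assigned the label of the first region to reach it.
// [[Rcpp::export(name = ".flood_watershed")]]
IntegerVector flood_watershed(NumericVector priority, IntegerVector seeds,
                              LogicalVector mask, IntegerVector dim) {
  Geom g(dim);
  if ((R_xlen_t)priority.size() != g.n || (R_xlen_t)seeds.size() != g.n ||
      (R_xlen_t)mask.size() != g.n) stop("array lengths do not match dim");
  IntegerVector lab(g.n, 0);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> q;
  unsigned long long order = 0;
  for (R_xlen_t i = 0; i < g.n; ++i) {
    if (seeds[i] > 0 && mask[i]) {
      lab[i] = seeds[i];
      q.push(QItem{priority[i], order++, i, seeds[i]});
    }
  }
  int c[3], nb[3];
  while (!q.empty()) {
    QItem it = q.top(); q.pop();
    g.coords(it.idx, c);
    for (int dz = (g.nd == 3 ? -1 : 0); dz <= (g.nd == 3 ? 1 : 0); ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          nb[0] = c[0] + dx; nb[1] = c[1] + dy; nb[2] = c[2] + dz;
          if (nb[0] < 0 || nb[0] >= g.d[0] || nb[1] < 0 || nb[1] >= g.d[1] ||
              nb[2] < 0 || nb[2] >= g.d[2]) continue;
          R_xlen_t j = g.index(nb);
          if (mask[j] && lab[j] == 0) {
            lab[j] = it.lab;
            q.push(QItem{priority[j], order++, j, it.lab});
          }
        }
  }
  lab.attr("dim") = dim;
  return lab;
}
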