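// Low-level raster operations for nuclear segmentation and spot calling.
// All matrices are column-major (R layout); pixel (r, c) -> index r + c*nrow.
// Connectivity is 8-neighbour throughout unless noted.

#include <Rcpp.h>
#include <algorithm>
#include <functional>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DR4[4] = {-1, 1, 0, 0};
static const int DC4[4] = {0, 0, -1, 1};

// Median filter with a disc structuring element (dx^2 + dy^2 <= radius^2),
// reflecting the image at the border.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter_disc(const NumericMatrix& img, double radius) {
  int nr = img.nrow(), nc = img.ncol();
  int ir = (int)std::floor(radius);
  std::vector<int> offr, offc;
  for (int dr = -ir; dr <= ir; ++dr)
    for (int dc = -ir; dc <= ir; ++dc)
      if ((double)(dr * dr + dc * dc) <= radius * radius + 1e-9) {
        offr.push_back(dr);
        offc.push_back(dc);
      }
  size_t k = offr.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf(k);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      for (size_t i = 0; i < k; ++i) {
        int rr = r + offr[i], cc = c + offc[i];
        // reflect (edge pixel not repeated)
        if (rr < 0) rr = -rr;
        if (rr >= nr) rr = 2 * nr - 2 - rr;
        if (cc < 0) cc = -cc;
        if (cc >= nc) cc = 2 * nc - 2 - cc;
        buf[i] = img(rr, cc);
      }
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.end());
      double med = buf[k / 2];
      if (k % 2 == 0) {
        // even count: average of the two central order statistics
        double lo = *std::max_element(buf.begin(), buf.begin() + k / 2);
        med = (med + lo) / 2.0;
      }
      out(r, c) = med;
    }
  }
  return out;
}

// Label connected foreground components (8- or 4-connectivity).
// Labels are assigned in raster scan order of each component's first pixel,
// so they are deterministic and consecutive from 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  const int* dr = connectivity == 4 ? DR4 : DR8;
  const int* dc = connectivity == 4 ? DC4 : DC8;
  int nn = connectivity == 4 ? 4 : 8;
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int pr = idx % nr, pc = idx / nr;
        for (int i = 0; i < nn; ++i) {
          int rr = pr + dr[i], cc = pc + dc[i];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Fill holes: background regions (4-connected) not reachable from the image
// border become foreground.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix reach(nr, nc);
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if ((r == 0 || r == nr - 1 || c == 0 || c == nc - 1) && !mask(r, c) &&
          !reach(r, c)) {
        reach(r, c) = true;
        stack.push_back(r + c * nr);
        while (!stack.empty()) {
          int idx = stack.back();
          stack.pop_back();
          int pr = idx % nr, pc = idx / nr;
          for (int i = 0; i < 4; ++i) {
            int rr = pr + DR4[i], cc = pc + DC4[i];
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (!mask(rr, cc) && !reach(rr, cc)) {
              reach(rr, cc) = true;
              stack.push_back(rr + cc * nr);
            }
          }
        }
      }
  LogicalMatrix out(nr, nc);
  for (int i = 0; i < nr * nc; ++i) out[i] = mask[i] || !reach[i];
  return out;
}

// One-dimensional squared distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        --k;
      } else
        break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance transform: distance from each foreground pixel to
// the nearest background pixel (background itself gets 0).
// [[Rcpp::export]]
NumericMatrix cpp_distance_transform(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e20;
  NumericMatrix g(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  std::vector<int> v(std::max(nr, nc));
  std::vector<double> z(std::max(nr, nc) + 1);
  // columns first
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? INF : 0.0;
    dt1d(f, d, nr, v, z);
    for (int r = 0; r < nr; ++r) g(r, c) = d[r];
  }
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = g(r, c);
    dt1d(f, d, nc, v, z);
    for (int c = 0; c < nc; ++c) out(r, c) = std::sqrt(d[c]);
  }
  return out;
}

struct WsNode {
  double elev;
  long order;
  int idx;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.elev != b.elev) return a.elev < b.elev;  // pop highest elevation
    return a.order > b.order;                      // then FIFO
  }
};

// Marker-controlled watershed on an elevation map (here: the distance
// transform, flooded from its peaks downwards). Every masked pixel is
// assigned to the basin of exactly one marker; no watershed-line pixels.
// markers: 0 = none, k > 0 = seed label.
// [[Rcpp::export]]
IntegerMatrix cpp_marker_watershed(const NumericMatrix& elev,
                                   const IntegerMatrix& markers,
                                   const LogicalMatrix& mask) {
  int nr = elev.nrow(), nc = elev.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (markers(r, c) > 0 && mask(r, c)) {
        lab(r, c) = markers(r, c);
        pq.push({elev(r, c), order++, r + c * nr});
      }
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    int pr = nd.idx % nr, pc = nd.idx / nr;
    int l = lab(pr, pc);
    for (int i = 0; i < 8; ++i) {
      int rr = pr + DR8[i], cc = pc + DC8[i];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (mask(rr, cc) && lab(rr, cc) == 0) {
        lab(rr, cc) = l;  // claim at push time: deterministic
        pq.push({elev(rr, cc), order++, rr + cc * nr});
      }
    }
  }
  return lab;
}

// Prominence-based maxima detection (ImageJ "Find Maxima" noise-tolerance
// semantics). A local maximum is accepted iff its prominence -- height above
// the highest saddle connecting it to any higher (or equal-but-earlier)
// region -- strictly exceeds `tolerance`. The highest maximum of each masked
// region has prominence peak - region minimum. Plateaus yield one
// representative pixel: topmost, then leftmost. Only masked pixels are
// considered; saddle paths may not leave the mask.
// Returns a matrix with columns (row, col, peak_value, prominence), 0-based
// coordinates, sorted by (row, col).
// [[Rcpp::export]]
NumericMatrix cpp_find_maxima(const NumericMatrix& img,
                              const LogicalMatrix& mask, double tolerance) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<int> px;
  px.reserve((size_t)nr * nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (mask(r, c)) px.push_back(r + c * nr);
  // order: value desc, then row asc, then col asc
  std::sort(px.begin(), px.end(), [&](int a, int b) {
    double va = img[a], vb = img[b];
    if (va != vb) return va > vb;
    int ra = a % nr, rb = b % nr;
    if (ra != rb) return ra < rb;
    return a / nr < b / nr;
  });
  size_t n = px.size();
  std::vector<int> rank(nr * nc, -1);  // processing order, -1 = not yet
  std::vector<int> parent(n), peak_px(n), peak_rank(n);
  std::vector<double> peak_val(n);
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  };
  std::vector<double> call_r, call_c, call_v, call_p;
  std::vector<int> roots_here;
  for (size_t t = 0; t < n; ++t) {
    int idx = px[t];
    double v = img[idx];
    int pr = idx % nr, pc = idx / nr;
    roots_here.clear();
    for (int i = 0; i < 8; ++i) {
      int rr = pr + DR8[i], cc = pc + DC8[i];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int nidx = rr + cc * nr;
      if (rank[nidx] < 0) continue;  // unprocessed or unmasked
      int root = find(rank[nidx]);
      bool seen = false;
      for (int rh : roots_here)
        if (rh == root) {
          seen = true;
          break;
        }
      if (!seen) roots_here.push_back(root);
    }
    rank[idx] = (int)t;
    if (roots_here.empty()) {
      // new summit
      parent[t] = (int)t;
      peak_px[t] = idx;
      peak_val[t] = v;
      peak_rank[t] = (int)t;
    } else {
      // winner: highest peak, ties to the earliest-processed peak
      int win = roots_here[0];
      for (size_t i = 1; i < roots_here.size(); ++i) {
        int r2 = roots_here[i];
        if (peak_val[r2] > peak_val[win] ||
            (peak_val[r2] == peak_val[win] && peak_rank[r2] < peak_rank[win]))
          win = r2;
      }
      for (int r2 : roots_here) {
        if (r2 == win) continue;
        double prom = peak_val[r2] - v;  // saddle at current level
        if (prom > tolerance) {
          call_r.push_back(peak_px[r2] % nr);
          call_c.push_back(peak_px[r2] / nr);
          call_v.push_back(peak_val[r2]);
          call_p.push_back(prom);
        }
        parent[r2] = win;
      }
      parent[t] = win;
    }
  }
  // surviving summits: prominence relative to the minimum of their region,
  // i.e. the value of the last pixel merged beneath them
  std::vector<double> region_min(n, 0.0);
  std::vector<bool> alive(n, false);
  for (size_t t = 0; t < n; ++t) {
    int root = find((int)t);
    double v = img[px[t]];
    if (!alive[root]) {
      alive[root] = true;
      region_min[root] = v;
    } else if (v < region_min[root]) {
      region_min[root] = v;
    }
  }
  for (size_t t = 0; t < n; ++t) {
    if (parent[t] != (int)t || !alive[t]) continue;
    double prom = peak_val[t] - region_min[t];
    if (prom > tolerance) {
      call_r.push_back(peak_px[t] % nr);
      call_c.push_back(peak_px[t] / nr);
      call_v.push_back(peak_val[t]);
      call_p.push_back(prom);
    }
  }
  size_t m = call_r.size();
  std::vector<size_t> ord(m);
  for (size_t i = 0; i < m; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (call_r[a] != call_r[b]) return call_r[a] < call_r[b];
    return call_c[a] < call_c[b];
  });
  NumericMatrix out(m, 4);
  for (size_t i = 0; i < m; ++i) {
    out(i, 0) = call_r[ord[i]];
    out(i, 1) = call_c[ord[i]];
    out(i, 2) = call_v[ord[i]];
    out(i, 3) = call_p[ord[i]];
  }
  colnames(out) = CharacterVector::create("row", "col", "value", "prominence");
  return out;
}
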