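// Low-level image primitives shared by the segmentation, detection and
// rendering layers. All matrices are column-major (R convention); pixel
// (r, c) is 1-based on the R side, 0-based here.
#include <Rcpp.h>
#include <queue>
#include <deque>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double INF = 1e20;

// ---------------------------------------------------------------------------
// Connected-component labeling (4- or 8-connectivity), flood fill by stack.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * h);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int pr = idx % h, pc = idx / h;
        for (int k = 0; k < nn; ++k) {
          int nr = pr + dr8[k], nc = pc + dc8[k];
          if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
          if (mask(nr, nc) && !lab(nr, nc)) {
            lab(nr, nc) = next;
            stack.push_back(nr + nc * h);
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher).
// Returns, for every pixel, the distance to the nearest FALSE pixel.
// Pixels outside the image are ignored (not treated as background).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt(const LogicalMatrix& mask) {
  const int h = mask.nrow(), w = mask.ncol();
  NumericMatrix sq(h, w);
  std::vector<double> f(std::max(h, w)), d(std::max(h, w));
  // columns first
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) f[r] = mask(r, c) ? INF : 0.0;
    dt1d(f, d, h);
    for (int r = 0; r < h; ++r) sq(r, c) = d[r];
  }
  for (int r = 0; r < h; ++r) {
    for (int c = 0; c < w; ++c) f[c] = sq(r, c);
    dt1d(f, d, w);
    for (int c = 0; c < w; ++c) sq(r, c) = d[c];
  }
  for (int i = 0; i < h * w; ++i) sq[i] = std::sqrt(std::min(sq[i], INF));
  return sq;
}

// ---------------------------------------------------------------------------
// Separable running min/max over a (2*radius+1) square window (van Herk).
static void run1d(std::vector<double>& x, int n, int radius, bool do_max) {
  if (radius <= 0 || n == 0) return;
  std::deque<int> dq;
  std::vector<double> out(n);
  for (int i = 0; i < n + radius; ++i) {
    if (i < n) {
      while (!dq.empty() &&
             (do_max ? x[dq.back()] <= x[i] : x[dq.back()] >= x[i]))
        dq.pop_back();
      dq.push_back(i);
    }
    int center = i - radius;
    if (center >= 0) {
      while (dq.front() < center - radius) dq.pop_front();
      out[center] = x[dq.front()];
    }
  }
  x = out;
}

static NumericMatrix minmax_filter(const NumericMatrix& img, int radius, bool do_max) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix out(h, w);
  std::vector<double> buf(std::max(h, w));
  for (int c = 0; c < w; ++c) {
    buf.assign(img.begin() + (size_t)c * h, img.begin() + (size_t)(c + 1) * h);
    buf.resize(h);
    run1d(buf, h, radius, do_max);
    for (int r = 0; r < h; ++r) out(r, c) = buf[r];
  }
  for (int r = 0; r < h; ++r) {
    for (int c = 0; c < w; ++c) buf[c] = out(r, c);
    buf.resize(w);
    run1d(buf, w, radius, do_max);
    for (int c = 0; c < w; ++c) out(r, c) = buf[c];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_max_filter(const NumericMatrix& img, int radius) {
  return minmax_filter(img, radius, true);
}

// [[Rcpp::export]]
NumericMatrix cpp_min_filter(const NumericMatrix& img, int radius) {
  return minmax_filter(img, radius, false);
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, reflected borders.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(const NumericMatrix& img, double sigma) {
  const int h = img.nrow(), w = img.ncol();
  if (sigma <= 0) return clone(img);
  int radius = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * radius + 1);
  double s = 0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + radius];
  }
  for (double& v : k) v /= s;
  NumericMatrix tmp(h, w), out(h, w);
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r) {
      double acc = 0;
      for (int i = -radius; i <= radius; ++i) {
        int rr = r + i;
        if (rr < 0) rr = -rr - 1;
        if (rr >= h) rr = 2 * h - rr - 1;
        acc += k[i + radius] * img(rr, c);
      }
      tmp(r, c) = acc;
    }
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r) {
      double acc = 0;
      for (int i = -radius; i <= radius; ++i) {
        int cc = c + i;
        if (cc < 0) cc = -cc - 1;
        if (cc >= w) cc = 2 * w - cc - 1;
        acc += k[i + radius] * tmp(r, cc);
      }
      out(r, c) = acc;
    }
  return out;
}

// ---------------------------------------------------------------------------
// Marker-based watershed: priority flood ascending the relief, restricted to
// mask. FIFO tie-break (insertion counter) keeps the result deterministic.
struct WsNode {
  double value;
  uint64_t order;
  int idx;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.value != b.value) return a.value > b.value;
    return a.order > b.order;
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& relief,
                            const IntegerMatrix& markers,
                            const LogicalMatrix& mask) {
  const int h = relief.nrow(), w = relief.ncol();
  IntegerMatrix lab(h, w);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  uint64_t counter = 0;
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r)
      if (markers(r, c) > 0 && mask(r, c)) {
        lab(r, c) = markers(r, c);
        pq.push({relief(r, c), counter++, r + c * h});
      }
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    int pr = nd.idx % h, pc = nd.idx / h;
    int l = lab(pr, pc);
    for (int k = 0; k < 4; ++k) {
      int nr = pr + dr[k], nc = pc + dc[k];
      if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
      if (!mask(nr, nc) || lab(nr, nc)) continue;
      lab(nr, nc) = l;
      pq.push({relief(nr, nc), counter++, nr + nc * h});
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Nearest-seed (Voronoi) labeling on the pixel grid; seeds in pixel coords.
// [[Rcpp::export]]
IntegerMatrix cpp_nearest_label(int h, int w,
                                const NumericVector& sr,
                                const NumericVector& sc) {
  const int n = sr.size();
  IntegerMatrix lab(h, w);
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r) {
      double best = INF;
      int bi = 0;
      for (int i = 0; i < n; ++i) {
        double dr = r - sr[i], dc = c - sc[i];
        double d = dr * dr + dc * dc;
        if (d < best) { best = d; bi = i + 1; }
      }
      lab(r, c) = bi;
    }
  return lab;
}

// ---------------------------------------------------------------------------
// Contrast-limited adaptive histogram equalization over an n_tiles x n_tiles
// grid with bilinear interpolation between tile mappings. Output in [0, 1].
// [[Rcpp::export]]
NumericMatrix cpp_clahe(const NumericMatrix& img, int n_tiles, int nbins,
                        double clip_limit) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix out(h, w);
  double mx = -INF, mn = INF;
  for (int i = 0; i < h * w; ++i) {
    if (img[i] > mx) mx = img[i];
    if (img[i] < mn) mn = img[i];
  }
  if (mx <= mn) return out;  // constant image -> all zeros
  const double range = mx - mn;
  int tr = std::min(n_tiles, h), tc = std::min(n_tiles, w);
  // per-tile clipped histogram -> CDF mapping
  std::vector<std::vector<double>> map((size_t)tr * tc,
                                       std::vector<double>(nbins, 0.0));
  std::vector<int> npix((size_t)tr * tc, 0);
  std::vector<std::vector<int>> hist((size_t)tr * tc,
                                     std::vector<int>(nbins, 0));
  for (int c = 0; c < w; ++c) {
    int tj = std::min(tc - 1, c * tc / w);
    for (int r = 0; r < h; ++r) {
      int ti = std::min(tr - 1, r * tr / h);
      int b = (int)((img(r, c) - mn) / range * nbins);
      if (b >= nbins) b = nbins - 1;
      hist[(size_t)ti * tc + tj][b]++;
      npix[(size_t)ti * tc + tj]++;
    }
  }
  for (int t = 0; t < tr * tc; ++t) {
    std::vector<int>& hst = hist[t];
    int n = npix[t];
    if (n == 0) continue;
    double limit = std::max(1.0, clip_limit * (double)n / nbins);
    double excess = 0;
    for (int b = 0; b < nbins; ++b)
      if (hst[b] > limit) { excess += hst[b] - limit; hst[b] = (int)limit; }
    double add = excess / nbins;
    double cum = 0;
    for (int b = 0; b < nbins; ++b) {
      cum += hst[b] + add;
      map[t][b] = cum / n;
    }
  }
  // bilinear interpolation between tile-center mappings
  for (int c = 0; c < w; ++c) {
    double fx = ((double)c + 0.5) * tc / w - 0.5;
    int j0 = (int)std::floor(fx);
    double wx = fx - j0;
    int j1 = j0 + 1;
    if (j0 < 0) { j0 = 0; j1 = 0; wx = 0; }
    if (j1 >= tc) { j1 = tc - 1; j0 = tc - 1; wx = 0; }
    for (int r = 0; r < h; ++r) {
      double fy = ((double)r + 0.5) * tr / h - 0.5;
      int i0 = (int)std::floor(fy);
      double wy = fy - i0;
      int i1 = i0 + 1;
      if (i0 < 0) { i0 = 0; i1 = 0; wy = 0; }
      if (i1 >= tr) { i1 = tr - 1; i0 = tr - 1; wy = 0; }
      int b = (int)((img(r, c) - mn) / range * nbins);
      if (b >= nbins) b = nbins - 1;
      double v00 = map[(size_t)i0 * tc + j0][b];
      double v01 = map[(size_t)i0 * tc + j1][b];
      double v10 = map[(size_t)i1 * tc + j0][b];
      double v11 = map[(size_t)i1 * tc + j1][b];
      out(r, c) = (1 - wy) * ((1 - wx) * v00 + wx * v01) +
                  wy * ((1 - wx) * v10 + wx * v11);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Moore boundary tracing of the first (scan-order) connected component.
// Returns an n x 2 matrix of 1-based (row, col) boundary pixels in order.
// [[Rcpp::export]]
IntegerMatrix cpp_trace_boundary(const LogicalMatrix& mask) {
  const int h = mask.nrow(), w = mask.ncol();
  int sr = -1, sc = -1;
  for (int c = 0; c < w && sr < 0; ++c)
    for (int r = 0; r < h; ++r)
      if (mask(r, c)) { sr = r; sc = c; break; }
  if (sr < 0) return IntegerMatrix(0, 2);
  // Moore neighborhood in clockwise screen order starting East; after a
  // move in direction d the search resumes two steps counter-clockwise
  const int dr[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  const int dc[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  std::vector<int> rows, cols;
  int cr = sr, cc = sc, dir = 0;
  rows.push_back(cr + 1); cols.push_back(cc + 1);
  int first_dir = -1;
  for (int step = 0; step < 4 * h * w; ++step) {
    bool found = false;
    int d = (dir + 6) % 8;
    int dd = 0;
    for (int k = 0; k < 8; ++k) {
      dd = (d + k) % 8;
      int nr = cr + dr[dd], nc = cc + dc[dd];
      if (nr >= 0 && nr < h && nc >= 0 && nc < w && mask(nr, nc)) {
        found = true;
        break;
      }
    }
    if (!found) break;  // isolated pixel
    // Jacob's criterion: back at start, leaving in the same direction again
    if (cr == sr && cc == sc) {
      if (first_dir < 0) first_dir = dd;
      else if (dd == first_dir) break;
    }
    cr += dr[dd]; cc += dc[dd]; dir = dd;
    if (cr == sr && cc == sc) continue;  // don't duplicate the start pixel
    rows.push_back(cr + 1); cols.push_back(cc + 1);
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i];
    out(i, 1) = cols[i];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Stamp filled discs (max-composited) onto an image; 1-based centers.
// [[Rcpp::export]]
NumericMatrix cpp_draw_discs(const NumericMatrix& img,
                             const NumericVector& r0,
                             const NumericVector& c0,
                             const NumericVector& radius,
                             const NumericVector& value) {
  NumericMatrix out = clone(img);
  const int h = out.nrow(), w = out.ncol();
  for (int i = 0; i < r0.size(); ++i) {
    double rr = r0[i] - 1.0, cc = c0[i] - 1.0, rad = radius[i];
    int rlo = std::max(0, (int)std::floor(rr - rad));
    int rhi = std::min(h - 1, (int)std::ceil(rr + rad));
    int clo = std::max(0, (int)std::floor(cc - rad));
    int chi = std::min(w - 1, (int)std::ceil(cc + rad));
    for (int c = clo; c <= chi; ++c)
      for (int r = rlo; r <= rhi; ++r) {
        double dr = r - rr, dc = c - cc;
        if (dr * dr + dc * dc <= rad * rad && out(r, c) < value[i])
          out(r, c) = value[i];
      }
  }
  return out;
}

// ---------------------------------------------------------------------------
// CRC-32 (PNG/zip polynomial) and Adler-32 over a raw vector.
// [[Rcpp::export]]
double cpp_crc32(const RawVector& data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t n = 0; n < 256; ++n) {
      uint32_t c = n;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[n] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}

// [[Rcpp::export]]
double cpp_adler32(const RawVector& data) {
  uint32_t a = 1, b = 0;
  const uint32_t MOD = 65521;
  for (R_xlen_t i = 0; i < data.size(); ++i) {
    a = (a + data[i]) % MOD;
    b = (b + a) % MOD;
  }
  return (double)((b << 16) | a);
}
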