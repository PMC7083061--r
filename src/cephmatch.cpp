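// Compiled kernels for the cephalogram superimposition pipeline.
//
// Image convention throughout: an R numeric matrix with nrow = height and
// ncol = width; pixel (x, y) in 0-based image coordinates (x rightward,
// y downward, origin top-left) lives at M(y, x). Intensities are in [0, 1].

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Bilinear sample with border clamping (replicate padding).
static inline double sample_clamp(const NumericMatrix &img, double x, double y) {
  int w = img.ncol(), h = img.nrow();
  if (x < 0) x = 0; if (x > w - 1) x = w - 1;
  if (y < 0) y = 0; if (y > h - 1) y = h - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = clampi(x0 + 1, 0, w - 1), y1 = clampi(y0 + 1, 0, h - 1);
  double fx = x - x0, fy = y - y0;
  return (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
         fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
}

// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(const NumericMatrix &img, double sigma) {
  int h = img.nrow(), w = img.ncol();
  if (sigma <= 0) return clone(img);
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;

  NumericMatrix tmp(h, w), out(h, w);
  for (int y = 0; y < h; ++y)          // horizontal pass, replicate borders
    for (int x = 0; x < w; ++x) {
      double acc = 0;
      for (int i = -r; i <= r; ++i) acc += k[i + r] * img(y, clampi(x + i, 0, w - 1));
      tmp(y, x) = acc;
    }
  for (int y = 0; y < h; ++y)          // vertical pass
    for (int x = 0; x < w; ++x) {
      double acc = 0;
      for (int i = -r; i <= r; ++i) acc += k[i + r] * tmp(clampi(y + i, 0, h - 1), x);
      out(y, x) = acc;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(const NumericMatrix &img, int out_h, int out_w) {
  int h = img.nrow(), w = img.ncol();
  NumericMatrix out(out_h, out_w);
  double sy = (double)h / out_h, sx = (double)w / out_w;
  for (int y = 0; y < out_h; ++y)
    for (int x = 0; x < out_w; ++x)
      out(y, x) = sample_clamp(img, (x + 0.5) * sx - 0.5, (y + 0.5) * sy - 0.5);
  return out;
}

// Inverse-mapped bilinear warp: output(q) = img(Rinv * (q - t)), where the
// transform maps source coordinates into the output frame by R(theta) p + t.
// Pixels that map outside the source are filled with `fill`.
// [[Rcpp::export]]
NumericMatrix cpp_warp_rigid(const NumericMatrix &img, double theta,
                             double tx, double ty, int out_h, int out_w,
                             double fill) {
  int h = img.nrow(), w = img.ncol();
  double c = std::cos(theta), s = std::sin(theta);
  NumericMatrix out(out_h, out_w);
  for (int y = 0; y < out_h; ++y) {
    for (int x = 0; x < out_w; ++x) {
      double dx = x - tx, dy = y - ty;
      double sxp = c * dx + s * dy;    // R(-theta) applied to (dx, dy)
      double syp = -s * dx + c * dy;
      const double eps = 1e-6;   // tolerate rounding at exact borders
      if (sxp < -eps || sxp > w - 1 + eps || syp < -eps || syp > h - 1 + eps) {
        out(y, x) = fill;
      } else {
        out(y, x) = sample_clamp(img, sxp, syp);
      }
    }
  }
  return out;
}

// 16-point Bresenham circle of radius 3 (clockwise from 12 o'clock, y down).
static const int CIRC_DX[16] = { 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1 };
static const int CIRC_DY[16] = { -3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3 };

// Longest circular run of `true` in flags[16]; also the sum of vals over that
// run (ties on length broken by the larger sum, then earliest start).
static void best_run(const bool *flags, const double *vals, int &len, double &sum) {
  len = 0; sum = 0;
  // all set: full circle
  bool all = true;
  for (int i = 0; i < 16; ++i) if (!flags[i]) { all = false; break; }
  if (all) {
    len = 16;
    for (int i = 0; i < 16; ++i) sum += vals[i];
    return;
  }
  for (int start = 0; start < 16; ++start) {
    if (!flags[start] || flags[(start + 15) % 16]) continue; // run starts here
    int l = 0; double sm = 0;
    for (int i = 0; i < 16 && flags[(start + i) % 16]; ++i) { ++l; sm += vals[(start + i) % 16]; }
    if (l > len || (l == len && sm > sum)) { len = l; sum = sm; }
  }
}

// FAST segment-test detector: a pixel is a corner when >= min_arc contiguous
// circle pixels are all brighter than center + t or all darker than
// center - t. Score = sum of (|delta| - t) over the best qualifying arc.
// Non-maximum suppression within a 3x3 neighbourhood on that score; score
// ties resolved by (y, x) lexicographic order. Returns columns x, y, score
// (0-based coordinates).
// [[Rcpp::export]]
NumericMatrix cpp_fast_detect(const NumericMatrix &img, double threshold, int min_arc) {
  int h = img.nrow(), w = img.ncol();
  NumericMatrix score(h, w); // 0 = not a corner
  for (int y = 3; y < h - 3; ++y) {
    for (int x = 3; x < w - 3; ++x) {
      double ic = img(y, x);
      double d[16]; bool bright[16], dark[16];
      int nb = 0, nd = 0;
      for (int i = 0; i < 16; ++i) {
        d[i] = img(y + CIRC_DY[i], x + CIRC_DX[i]) - ic;
        bright[i] = d[i] > threshold;
        dark[i] = d[i] < -threshold;
        nb += bright[i]; nd += dark[i];
      }
      double best = 0;
      if (nb >= min_arc) {
        int len; double sum;
        double v[16]; for (int i = 0; i < 16; ++i) v[i] = d[i] - threshold;
        best_run(bright, v, len, sum);
        if (len >= min_arc && sum > best) best = sum;
      }
      if (nd >= min_arc) {
        int len; double sum;
        double v[16]; for (int i = 0; i < 16; ++i) v[i] = -d[i] - threshold;
        best_run(dark, v, len, sum);
        if (len >= min_arc && sum > best) best = sum;
      }
      score(y, x) = best;
    }
  }
  std::vector<double> xs, ys, ss;
  for (int y = 3; y < h - 3; ++y) {
    for (int x = 3; x < w - 3; ++x) {
      double sc = score(y, x);
      if (sc <= 0) continue;
      bool keep = true;
      for (int dy = -1; dy <= 1 && keep; ++dy)
        for (int dx = -1; dx <= 1 && keep; ++dx) {
          if (dx == 0 && dy == 0) continue;
          double sn = score(y + dy, x + dx);
          if (sn > sc) keep = false;
          else if (sn == sc && (dy < 0 || (dy == 0 && dx < 0))) keep = false;
        }
      if (keep) { xs.push_back(x); ys.push_back(y); ss.push_back(sc); }
    }
  }
  NumericMatrix out(xs.size(), 3);
  for (size_t i = 0; i < xs.size(); ++i) { out(i, 0) = xs[i]; out(i, 1) = ys[i]; out(i, 2) = ss[i]; }
  colnames(out) = CharacterVector::create("x", "y", "score");
  return out;
}

// Harris corner measure det(M) - k tr(M)^2 summed over a square window,
// gradients by central differences with replicate borders.
// [[Rcpp::export]]
NumericVector cpp_harris(const NumericMatrix &img, const NumericMatrix &pts,
                         int half_win, double k) {
  int h = img.nrow(), w = img.ncol(), n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int cx = (int)pts(i, 0), cy = (int)pts(i, 1);
    double sxx = 0, syy = 0, sxy = 0;
    for (int dy = -half_win; dy <= half_win; ++dy) {
      for (int dx = -half_win; dx <= half_win; ++dx) {
        int x = clampi(cx + dx, 0, w - 1), y = clampi(cy + dy, 0, h - 1);
        double gx = 0.5 * (img(y, clampi(x + 1, 0, w - 1)) - img(y, clampi(x - 1, 0, w - 1)));
        double gy = 0.5 * (img(clampi(y + 1, 0, h - 1), x) - img(clampi(y - 1, 0, h - 1), x));
        sxx += gx * gx; syy += gy * gy; sxy += gx * gy;
      }
    }
    out[i] = (sxx * syy - sxy * sxy) - k * (sxx + syy) * (sxx + syy);
  }
  return out;
}

// Intensity-centroid orientation: atan2(m01, m10) with moments over a
// circular patch (replicate padding at borders).
// [[Rcpp::export]]
NumericVector cpp_orientation(const NumericMatrix &img, const NumericMatrix &pts,
                              int radius) {
  int w = img.ncol(), h = img.nrow(), n = pts.nrow();
  NumericVector out(n);
  int r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    int cx = (int)std::lround(pts(i, 0)), cy = (int)std::lround(pts(i, 1));
    double m10 = 0, m01 = 0;
    for (int dy = -radius; dy <= radius; ++dy) {
      for (int dx = -radius; dx <= radius; ++dx) {
        if (dx * dx + dy * dy > r2) continue;
        double v = img(clampi(cy + dy, 0, h - 1), clampi(cx + dx, 0, w - 1));
        m10 += dx * v; m01 += dy * v;
      }
    }
    // symmetric patches cancel only up to floating-point summation order
    if (std::fabs(m10) < 1e-9 && std::fabs(m01) < 1e-9) out[i] = 0;
    else out[i] = std::atan2(m01, m10);
  }
  return out;
}

// Rotation-steered binary descriptor. `pattern` is 256 x 4 (px, py, qx, qy)
// offsets in a 31x31 patch frame; the pair table is rotated by each
// keypoint's orientation, sample positions rounded to integers and clamped
// to the image. Bit i = 1 iff I(p_i) < I(q_i) (strict; ties give 0).
// Returns n x 32 bytes, bit i stored in byte i/8 at position i%8.
// [[Rcpp::export]]
IntegerMatrix cpp_describe(const NumericMatrix &img, const NumericMatrix &kps,
                           const IntegerMatrix &pattern) {
  int n = kps.nrow(), nb = pattern.nrow();
  int w = img.ncol(), h = img.nrow();
  IntegerMatrix out(n, nb / 8);
  for (int i = 0; i < n; ++i) {
    double cx = kps(i, 0), cy = kps(i, 1), th = kps(i, 2);
    double c = std::cos(th), s = std::sin(th);
    int icx = (int)std::lround(cx), icy = (int)std::lround(cy);
    for (int b = 0; b < nb; ++b) {
      int px = pattern(b, 0), py = pattern(b, 1);
      int qx = pattern(b, 2), qy = pattern(b, 3);
      int rpx = (int)std::lround(c * px - s * py), rpy = (int)std::lround(s * px + c * py);
      int rqx = (int)std::lround(c * qx - s * qy), rqy = (int)std::lround(s * qx + c * qy);
      double vp = img(clampi(icy + rpy, 0, h - 1), clampi(icx + rpx, 0, w - 1));
      double vq = img(clampi(icy + rqy, 0, h - 1), clampi(icx + rqx, 0, w - 1));
      if (vp < vq) out(i, b / 8) |= (1 << (b % 8));
    }
  }
  return out;
}

static inline int popcount64(uint64_t v) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(v);
#else
  int c = 0; while (v) { v &= v - 1; ++c; } return c;
#endif
}

static void pack_rows(const IntegerMatrix &d, std::vector<uint64_t> &packed, int words) {
  int n = d.nrow(), nb = d.ncol();
  packed.assign((size_t)n * words, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < nb; ++j)
      packed[(size_t)i * words + j / 8] |= ((uint64_t)(d(i, j) & 0xFF)) << (8 * (j % 8));
}

// Brute-force nearest neighbour by Hamming distance: for every descriptor in
// A, its closest descriptor in B (ties -> lowest B index). Returns columns
// ia, ib (1-based) and distance, sorted by ia.
// [[Rcpp::export]]
IntegerMatrix cpp_match_hamming(const IntegerMatrix &da, const IntegerMatrix &db) {
  int na = da.nrow(), nbn = db.nrow();
  int words = (da.ncol() + 7) / 8;
  std::vector<uint64_t> pa, pb;
  pack_rows(da, pa, words);
  pack_rows(db, pb, words);
  IntegerMatrix out(na, 3);
  for (int i = 0; i < na; ++i) {
    int best = INT_MAX, besti = -1;
    const uint64_t *ra = &pa[(size_t)i * words];
    for (int j = 0; j < nbn; ++j) {
      const uint64_t *rb = &pb[(size_t)j * words];
      int dist = 0;
      for (int k = 0; k < words; ++k) dist += popcount64(ra[k] ^ rb[k]);
      if (dist < best) { best = dist; besti = j; }
    }
    out(i, 0) = i + 1; out(i, 1) = besti + 1; out(i, 2) = best;
  }
  colnames(out) = CharacterVector::create("ia", "ib", "distance");
  return out;
}

// Hamming distance between two byte-vector descriptors.
// [[Rcpp::export]]
int cpp_hamming(const IntegerVector &d1, const IntegerVector &d2) {
  int n = d1.size(), dist = 0;
  for (int i = 0; i < n; ++i) {
    int v = (d1[i] ^ d2[i]) & 0xFF;
    while (v) { v &= v - 1; ++dist; }
  }
  return dist;
}
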