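#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bresenham circle of radius 3: 16 offsets, clockwise from 12 o'clock.
static const int CIRC_X[16] = {0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1};
static const int CIRC_Y[16] = {-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3};

// FAST segment test: a pixel is a corner when >= 9 contiguous circle pixels
// are all brighter than center + t or all darker than center - t.
// Coordinates returned 1-based (x = column, y = row).
// [[Rcpp::export(name = ".fast_detect_cpp")]]
DataFrame fast_detect_cpp(NumericMatrix img, double threshold) {
  const int H = img.nrow(), W = img.ncol();
  std::vector<double> xs, ys, scores;
  if (H >= 7 && W >= 7) {
    for (int y = 3; y < H - 3; ++y) {
      for (int x = 3; x < W - 3; ++x) {
        double c = img(y, x);
        int flags[16];
        for (int k = 0; k < 16; ++k) {
          double p = img(y + CIRC_Y[k], x + CIRC_X[k]);
          flags[k] = (p > c + threshold) ? 1 : ((p < c - threshold) ? -1 : 0);
        }
        // longest circular run of identical nonzero flag
        bool corner = false;
        for (int s = 0; s < 16 && !corner; ++s) {
          int f = flags[s];
          if (f == 0) continue;
          int run = 1;
          while (run < 9 && flags[(s + run) % 16] == f) ++run;
          if (run >= 9) corner = true;
        }
        if (corner) {
          double sc = 0.0;
          for (int k = 0; k < 16; ++k) {
            double d = std::fabs(img(y + CIRC_Y[k], x + CIRC_X[k]) - c) - threshold;
            if (d > 0) sc += d;
          }
          xs.push_back(x + 1.0);
          ys.push_back(y + 1.0);
          scores.push_back(sc);
        }
      }
    }
  }
  return DataFrame::create(_["x"] = xs, _["y"] = ys, _["score"] = scores);
}

static inline double bilinear(const NumericMatrix& img, double y, double x) {
  // 0-based coordinates, clamped at the border
  const int H = img.nrow(), W = img.ncol();
  if (x < 0) x = 0;
  if (x > W - 1) x = W - 1;
  if (y < 0) y = 0;
  if (y > H - 1) y = H - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = x0 + 1 < W ? x0 + 1 : W - 1;
  int y1 = y0 + 1 < H ? y0 + 1 : H - 1;
  double ax = x - x0, ay = y - y0;
  return (1 - ay) * ((1 - ax) * img(y0, x0) + ax * img(y0, x1)) +
         ay * ((1 - ax) * img(y1, x0) + ax * img(y1, x1));
}

// 2x downsample with 2x2 box averaging
static NumericMatrix halve(const NumericMatrix& img) {
  int H = img.nrow() / 2, W = img.ncol() / 2;
  if (H < 1) H = 1;
  if (W < 1) W = 1;
  NumericMatrix out(H, W);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      int y2 = 2 * y, x2 = 2 * x;
      int y3 = y2 + 1 < img.nrow() ? y2 + 1 : y2;
      int x3 = x2 + 1 < img.ncol() ? x2 + 1 : x2;
      out(y, x) = 0.25 * (img(y2, x2) + img(y2, x3) + img(y3, x2) + img(y3, x3));
    }
  return out;
}

static std::vector<NumericMatrix> build_pyramid(const NumericMatrix& img, int levels) {
  std::vector<NumericMatrix> pyr;
  pyr.push_back(img);
  for (int l = 1; l < levels; ++l) {
    const NumericMatrix& prev = pyr.back();
    if (prev.nrow() < 8 || prev.ncol() < 8) break;
    pyr.push_back(halve(prev));
  }
  return pyr;
}

// Extract an n x n patch of `img` whose top-left corner sits at the
// fractional 0-based position (y0, x0). All samples share one set of
// bilinear weights; a pointer-based fast path covers windows fully inside
// the image, with clamped sampling at the border.
static void sample_patch(const NumericMatrix& img, double y0, double x0,
                         int n, double* out) {
  const int H = img.nrow(), W = img.ncol();
  const int xi = (int)std::floor(x0), yi = (int)std::floor(y0);
  const double ax = x0 - xi, ay = y0 - yi;
  const double w00 = (1 - ay) * (1 - ax), w01 = (1 - ay) * ax;
  const double w10 = ay * (1 - ax), w11 = ay * ax;
  if (xi >= 0 && yi >= 0 && xi + n < W && yi + n < H) {
    const double* base = img.begin() + (std::size_t)xi * H + yi;
    for (int c = 0; c < n; ++c) {
      const double* p0 = base + (std::size_t)c * H;
      const double* p1 = p0 + H;
      double* o = out + (std::size_t)c * n;
      for (int r = 0; r < n; ++r) {
        o[r] = w00 * p0[r] + w01 * p1[r] + w10 * p0[r + 1] + w11 * p1[r + 1];
      }
    }
  } else {
    for (int c = 0; c < n; ++c)
      for (int r = 0; r < n; ++r)
        out[(std::size_t)c * n + r] = bilinear(img, y0 + r, x0 + c);
  }
}

// One pyramidal LK solve for a single point between two pyramids.
// pt is 0-based (x, y) in the full-resolution image. Returns false when the
// point leaves the image or the normal matrix is singular at the base level.
static bool lk_point(const std::vector<NumericMatrix>& pyr0,
                     const std::vector<NumericMatrix>& pyr1,
                     double& px, double& py,
                     int half_win, int max_iter, double eps,
                     std::vector<double>& buf) {
  const int L = (int)pyr0.size();
  double gx = 0.0, gy = 0.0;  // flow guess propagated across levels
  bool ok = true;
  for (int l = L - 1; l >= 0; --l) {
    const NumericMatrix& I0 = pyr0[l];
    const NumericMatrix& I1 = pyr1[l];
    const double scale = std::pow(2.0, l);
    const double cx = px / scale, cy = py / scale;
    int hw = half_win;
    int mindim = std::min(I0.nrow(), I0.ncol());
    if (2 * hw + 3 > mindim) hw = (mindim - 3) / 2;
    if (hw < 1) hw = 1;
    const int side = 2 * hw + 1, ext = side + 2;
    const int n = side * side;
    buf.resize((std::size_t)ext * ext + 3 * (std::size_t)n);
    double* patch = buf.data();            // (side+2)^2 source patch
    double* i0 = patch + (std::size_t)ext * ext;
    double* ixg = i0 + n;
    double* iyg = ixg + n;
    sample_patch(I0, cy - hw - 1, cx - hw - 1, ext, patch);
    double g11 = 0, g12 = 0, g22 = 0;
    for (int c = 0; c < side; ++c)
      for (int r = 0; r < side; ++r) {
        const int k = c * side + r;
        const int pc = c + 1, pr = r + 1;
        i0[k] = patch[(std::size_t)pc * ext + pr];
        double gxv = 0.5 * (patch[(std::size_t)(pc + 1) * ext + pr] -
                            patch[(std::size_t)(pc - 1) * ext + pr]);
        double gyv = 0.5 * (patch[(std::size_t)pc * ext + pr + 1] -
                            patch[(std::size_t)pc * ext + pr - 1]);
        ixg[k] = gxv;
        iyg[k] = gyv;
        g11 += gxv * gxv;
        g12 += gxv * gyv;
        g22 += gyv * gyv;
      }
    double det = g11 * g22 - g12 * g12;
    if (det < 1e-12) {
      if (l == 0) ok = false;
      gx *= 2.0; gy *= 2.0;  // keep guess, try finer level
      continue;
    }
    double vx = gx, vy = gy;
    std::vector<double> cur((std::size_t)n);
    for (int it = 0; it < max_iter; ++it) {
      sample_patch(I1, cy - hw + vy, cx - hw + vx, side, cur.data());
      double b1 = 0, b2 = 0;
      for (int k = 0; k < n; ++k) {
        double diff = i0[k] - cur[k];
        b1 += diff * ixg[k];
        b2 += diff * iyg[k];
      }
      double dx = (g22 * b1 - g12 * b2) / det;
      double dy = (g11 * b2 - g12 * b1) / det;
      vx += dx;
      vy += dy;
      if (std::sqrt(dx * dx + dy * dy) < eps) break;
    }
    if (l > 0) {
      gx = 2.0 * vx;
      gy = 2.0 * vy;
    } else {
      px += vx;
      py += vy;
    }
  }
  if (!ok) return false;
  const NumericMatrix& base = pyr1[0];
  if (px < 0 || px > base.ncol() - 1 || py < 0 || py > base.nrow() - 1) return false;
  return true;
}

// Track seed points through a frame sequence, chaining frame-to-frame flow.
// frames: list of H x W numeric matrices; seeds: N x 2 matrix of 1-based (x, y).
// Returns positions (N x T x 2, 1-based, NA where invalid) and valid (N x T).
// [[Rcpp::export(name = ".lk_track_cpp")]]
List lk_track_cpp(List frames, NumericMatrix seeds,
                  int half_win, int levels, int max_iter, double eps) {
  const int T = frames.size();
  const int N = seeds.nrow();
  NumericVector positions(Dimension(N, T, 2));
  LogicalMatrix valid(N, T);
  std::fill(positions.begin(), positions.end(), NA_REAL);
  std::vector<double> px(N), py(N);
  std::vector<bool> alive(N, true);
  for (int i = 0; i < N; ++i) {
    px[i] = seeds(i, 0) - 1.0;  // to 0-based
    py[i] = seeds(i, 1) - 1.0;
    positions[i + (std::size_t)0 * N] = seeds(i, 0);
    positions[i + (std::size_t)0 * N + (std::size_t)N * T] = seeds(i, 1);
    valid(i, 0) = true;
  }
  NumericMatrix cur = frames[0];
  std::vector<NumericMatrix> pyr0 = build_pyramid(cur, levels);
  std::vector<double> buf;
  for (int t = 1; t < T; ++t) {
    NumericMatrix nxt = frames[t];
    std::vector<NumericMatrix> pyr1 = build_pyramid(nxt, levels);
    for (int i = 0; i < N; ++i) {
      if (!alive[i]) continue;
      double x = px[i], y = py[i];
      bool ok = lk_point(pyr0, pyr1, x, y, half_win, max_iter, eps, buf);
      if (ok) {
        px[i] = x;
        py[i] = y;
        positions[i + (std::size_t)t * N] = x + 1.0;
        positions[i + (std::size_t)t * N + (std::size_t)N * T] = y + 1.0;
        valid(i, t) = true;
      } else {
        alive[i] = false;
      }
    }
    pyr0.swap(pyr1);
  }
  return List::create(_["positions"] = positions, _["valid"] = valid);
}
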