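// Inner loops of the DPIV engine: circular FFT cross-correlation of
// interrogation windows, integer peak search with sub-pixel refinement,
// and synthetic frame rendering. Kept in C++ because a 60 s recording at
// 57 FPS means ~3.4k frame pairs x ~400 windows each.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <complex>
#include <map>
#include <vector>
using namespace Rcpp;

// Three-point sub-pixel fit along one axis. Gaussian on log-values when
// all three samples are positive (exact for a sampled Gaussian peak),
// parabolic otherwise. Returns offset in (-1, 1); flags which fit ran.
static double subpixel_fit_1d(double cm, double c0, double cp, bool &gaussian) {
  if (cm > 0.0 && c0 > 0.0 && cp > 0.0) {
    const double lm = std::log(cm), l0 = std::log(c0), lp = std::log(cp);
    const double den = 2.0 * lm - 4.0 * l0 + 2.0 * lp;
    if (std::fabs(den) > 1e-300) {
      gaussian = true;
      double d = (lm - lp) / den;
      if (std::fabs(d) < 1.0) return d;
    }
  }
  gaussian = false;
  const double den = 2.0 * (cm - 2.0 * c0 + cp);
  if (std::fabs(den) < 1e-300) return 0.0;
  double d = (cm - cp) / den;
  if (std::fabs(d) >= 1.0) return 0.0;
  return d;
}

// ---- radix-2 FFT with cached plans -------------------------------------
// Interrogation windows are square powers of two (16/32/64 by default),
// so a plain iterative Cooley-Tukey transform with precomputed twiddles
// and bit-reversal tables is both simple and fast enough for the
// ~10^6 window correlations of a full recording.

struct FFTPlan {
  int n = 0;
  std::vector<int> rev;                   // bit-reversal permutation
  std::vector<std::complex<double>> w;    // w[k] = exp(-2*pi*i*k/n), k < n/2
};

static const FFTPlan &plan_for(int n) {
  static std::map<int, FFTPlan> cache;
  auto it = cache.find(n);
  if (it != cache.end()) return it->second;
  FFTPlan p;
  p.n = n;
  p.rev.resize(n);
  int lg = 0;
  while ((1 << lg) < n) ++lg;
  for (int i = 0; i < n; ++i) {
    int r = 0;
    for (int b = 0; b < lg; ++b) if (i & (1 << b)) r |= 1 << (lg - 1 - b);
    p.rev[i] = r;
  }
  p.w.resize(n / 2);
  for (int k = 0; k < n / 2; ++k) {
    const double ang = -2.0 * M_PI * k / n;
    p.w[k] = std::complex<double>(std::cos(ang), std::sin(ang));
  }
  return cache.emplace(n, std::move(p)).first->second;
}

// Unscaled in-place transform; inverse = conjugated twiddles, no 1/n.
static void fft1d(std::complex<double> *x, const FFTPlan &p, bool inverse) {
  const int n = p.n;
  for (int i = 0; i < n; ++i) {
    if (i < p.rev[i]) std::swap(x[i], x[p.rev[i]]);
  }
  for (int len = 2; len <= n; len <<= 1) {
    const int half = len >> 1, step = n / len;
    for (int i = 0; i < n; i += len) {
      for (int k = 0; k < half; ++k) {
        std::complex<double> w = p.w[k * step];
        if (inverse) w = std::conj(w);
        const std::complex<double> u = x[i + k];
        const std::complex<double> v = x[i + k + half] * w;
        x[i + k] = u + v;
        x[i + k + half] = u - v;
      }
    }
  }
}

// In-place 2-D transform of an n x n column-major buffer: columns, then
// rows via transpose / columns / transpose.
static void fft2d(std::complex<double> *z, int n, bool inverse,
                  std::complex<double> *scratch) {
  const FFTPlan &p = plan_for(n);
  for (int j = 0; j < n; ++j) fft1d(z + static_cast<size_t>(j) * n, p, inverse);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      scratch[j + static_cast<size_t>(i) * n] = z[i + static_cast<size_t>(j) * n];
  for (int j = 0; j < n; ++j) fft1d(scratch + static_cast<size_t>(j) * n, p, inverse);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      z[i + static_cast<size_t>(j) * n] = scratch[j + static_cast<size_t>(i) * n];
}

// Circular cross-correlation of mean-subtracted windows via the DFT.
// Raw (unshifted) plane: element (r, c) is the correlation at row lag r,
// column lag c (mod n), i.e. the peak index equals the displacement of b
// relative to a. Both real inputs are packed into one complex transform
// (a + i*b); their spectra are separated by Hermitian symmetry.
static arma::mat xcorr_raw(const arma::mat &a, const arma::mat &b) {
  const int n = a.n_rows;
  const size_t n2 = static_cast<size_t>(n) * n;
  std::vector<std::complex<double>> z(n2), cross(n2), scratch(n2);
  for (size_t q = 0; q < n2; ++q) z[q] = std::complex<double>(a[q], b[q]);
  fft2d(z.data(), n, false, scratch.data());
  // F_a(k) = (Z(k) + conj(Z(-k))) / 2 ; F_b(k) = (Z(k) - conj(Z(-k))) / (2i)
  for (int j = 0; j < n; ++j) {
    const int jm = (n - j) % n;
    for (int i = 0; i < n; ++i) {
      const int im = (n - i) % n;
      const std::complex<double> zk = z[i + static_cast<size_t>(j) * n];
      const std::complex<double> zm =
          std::conj(z[im + static_cast<size_t>(jm) * n]);
      const std::complex<double> fa = 0.5 * (zk + zm);
      const std::complex<double> fb =
          std::complex<double>(0.0, -0.5) * (zk - zm);
      cross[i + static_cast<size_t>(j) * n] = std::conj(fa) * fb;
    }
  }
  fft2d(cross.data(), n, true, scratch.data());
  arma::mat out(n, n);
  const double scale = 1.0 / n2;
  for (size_t q = 0; q < n2; ++q) out[q] = cross[q].real() * scale;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_xcorr_plane(NumericMatrix a_, NumericMatrix b_) {
  arma::mat a(a_.begin(), a_.nrow(), a_.ncol(), false);
  arma::mat b(b_.begin(), b_.nrow(), b_.ncol(), false);
  arma::mat a0 = a - arma::accu(a) / a.n_elem;
  arma::mat b0 = b - arma::accu(b) / b.n_elem;
  arma::mat c = xcorr_raw(a0, b0);
  // fftshift so that zero lag sits at (n/2 + 1, n/2 + 1) in 1-based R
  // indexing; row/col index i corresponds to lag i - (n/2 + 1).
  const int nr = c.n_rows, nc = c.n_cols;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    int jr = (j + nc / 2) % nc;
    for (int i = 0; i < nr; ++i) {
      int ir = (i + nr / 2) % nr;
      out(i, j) = c(ir, jr);
    }
  }
  return out;
}

// Gaussian window weighting (sigma = n/4) applied to the
// mean-subtracted interrogation windows. Suppresses particle images
// truncated by the window border, which otherwise bias the sub-pixel
// displacement towards integer values.
static const arma::mat &weight_for(int n) {
  static std::map<int, arma::mat> cache;
  auto it = cache.find(n);
  if (it != cache.end()) return it->second;
  arma::vec g(n);
  const double c = (n - 1) / 2.0, s = n / 4.0;
  for (int i = 0; i < n; ++i) g[i] = std::exp(-(i - c) * (i - c) / (2 * s * s));
  return cache.emplace(n, g * g.t()).first->second;
}

// One interrogation pass over a list of windows. x0/y0 are 0-based
// top-left corners (column, row) of each window in frame a; offx/offy
// are integer pre-shifts applied to the matching window of frame b
// (clamped to stay inside the frame; the clamped value is what enters
// the reported displacement).
//
// Returns an n x 8 matrix with columns:
//   1 dx  2 dy  3 peak height  4 peak ratio (first/second peak)
//   5 degenerate flag  6 border-maximum flag  7 used offx  8 used offy
// [[Rcpp::export]]
NumericMatrix cpp_piv_pass(NumericMatrix frame_a, NumericMatrix frame_b,
                           IntegerVector x0, IntegerVector y0, int win,
                           IntegerVector offx, IntegerVector offy,
                           bool weight = true) {
  const int h = frame_a.nrow(), w = frame_a.ncol();
  const int n = x0.size();
  arma::mat A(frame_a.begin(), h, w, false);
  arma::mat B(frame_b.begin(), h, w, false);
  NumericMatrix out(n, 8);

  for (int k = 0; k < n; ++k) {
    const int ax = x0[k], ay = y0[k];
    int bx = ax + offx[k], by = ay + offy[k];
    if (bx < 0) bx = 0;
    if (by < 0) by = 0;
    if (bx > w - win) bx = w - win;
    if (by > h - win) by = h - win;
    const int ux = bx - ax, uy = by - ay;  // offsets actually applied

    arma::mat wa = A.submat(ay, ax, ay + win - 1, ax + win - 1);
    arma::mat wb = B.submat(by, bx, by + win - 1, bx + win - 1);
    wa -= arma::accu(wa) / wa.n_elem;
    wb -= arma::accu(wb) / wb.n_elem;
    if (weight) {
      const arma::mat &wgt = weight_for(win);
      wa %= wgt;
      wb %= wgt;
    }
    const double va = arma::accu(wa % wa), vb = arma::accu(wb % wb);
    if (va < 1e-10 || vb < 1e-10) {  // featureless window: correlation undefined
      out(k, 0) = NA_REAL; out(k, 1) = NA_REAL;
      out(k, 2) = 0.0; out(k, 3) = 0.0;
      out(k, 4) = 1.0; out(k, 5) = 0.0;
      out(k, 6) = ux; out(k, 7) = uy;
      continue;
    }

    arma::mat c = xcorr_raw(wa, wb);
    int pr = 0, pc = 0;
    double peak = c(0, 0);
    for (int j = 0; j < win; ++j)
      for (int i = 0; i < win; ++i)
        if (c(i, j) > peak) { peak = c(i, j); pr = i; pc = j; }

    // signed circular lags in [-win/2, win/2 - 1]
    const int lag_y = (pr < win / 2) ? pr : pr - win;
    const int lag_x = (pc < win / 2) ? pc : pc - win;
    const bool border = (lag_x == -win / 2 || lag_x == win / 2 - 1 ||
                         lag_y == -win / 2 || lag_y == win / 2 - 1);

    // second peak outside the 3x3 neighborhood (circular) of the first
    double peak2 = -std::numeric_limits<double>::infinity();
    for (int j = 0; j < win; ++j) {
      int dj = std::abs(j - pc); dj = std::min(dj, win - dj);
      for (int i = 0; i < win; ++i) {
        int di = std::abs(i - pr); di = std::min(di, win - di);
        if (di <= 1 && dj <= 1) continue;
        if (c(i, j) > peak2) peak2 = c(i, j);
      }
    }
    const double ratio = (peak2 > 0.0) ? peak / peak2 : INFINITY;

    bool gx = false, gy = false;
    const double cyp = c((pr + 1) % win, pc), cym = c((pr + win - 1) % win, pc);
    const double cxp = c(pr, (pc + 1) % win), cxm = c(pr, (pc + win - 1) % win);
    const double sy = subpixel_fit_1d(cym, peak, cyp, gy);
    const double sx = subpixel_fit_1d(cxm, peak, cxp, gx);

    out(k, 0) = ux + lag_x + sx;
    out(k, 1) = uy + lag_y + sy;
    out(k, 2) = peak / std::sqrt(va * vb);  // normalized peak height
    out(k, 3) = ratio;
    out(k, 4) = 0.0;
    out(k, 5) = border ? 1.0 : 0.0;
    out(k, 6) = ux; out(k, 7) = uy;
  }
  return out;
}

static double median_of(std::vector<double> v) {
  const size_t n = v.size();
  std::sort(v.begin(), v.end());
  if (n % 2 == 1) return v[n / 2];
  return 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

// Normalized median test on the 8-neighborhood of a regular vector
// grid (column-major, ny rows x nx cols). residual = |v - median| /
// (median absolute deviation + eps), per component; a vector is an
// outlier when either component exceeds the threshold. Cells with
// fewer than 3 valid neighbors are left alone. Also returns the local
// mean of valid neighbors for replacement.
//
// Output n x 3: outlier flag, neighbor-mean dx, neighbor-mean dy.
// [[Rcpp::export]]
NumericMatrix cpp_nmt(NumericVector dx, NumericVector dy,
                      LogicalVector valid, int ny, int nx,
                      double threshold, double eps) {
  const int n = ny * nx;
  NumericMatrix out(n, 3);
  std::vector<double> ndx, ndy;
  ndx.reserve(8); ndy.reserve(8);
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      const int k = i + j * ny;
      ndx.clear(); ndy.clear();
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          const int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= ny || jj < 0 || jj >= nx) continue;
          const int kk = ii + jj * ny;
          if (!valid[kk] || NumericVector::is_na(dx[kk])) continue;
          ndx.push_back(dx[kk]);
          ndy.push_back(dy[kk]);
        }
      }
      const int m = ndx.size();
      if (m >= 1) {
        double sx = 0.0, sy = 0.0;
        for (int q = 0; q < m; ++q) { sx += ndx[q]; sy += ndy[q]; }
        out(k, 1) = sx / m;
        out(k, 2) = sy / m;
      } else {
        out(k, 1) = NA_REAL;
        out(k, 2) = NA_REAL;
      }
      if (m < 3 || !valid[k] || NumericVector::is_na(dx[k])) {
        out(k, 0) = 0.0;
        continue;
      }
      const double medx = median_of(ndx), medy = median_of(ndy);
      std::vector<double> rx(m), ry(m);
      for (int q = 0; q < m; ++q) {
        rx[q] = std::fabs(ndx[q] - medx);
        ry[q] = std::fabs(ndy[q] - medy);
      }
      const double resx = std::fabs(dx[k] - medx) / (median_of(rx) + eps);
      const double resy = std::fabs(dy[k] - medy) / (median_of(ry) + eps);
      out(k, 0) = (resx > threshold || resy > threshold) ? 1.0 : 0.0;
    }
  }
  return out;
}

// Render particle images: isotropic Gaussian spots on a uniform
// background with additive read noise, quantized to 8 bit. Positions are
// 0-based pixel coordinates (x = column, y = row); one column per frame.
// Noise is drawn from R's RNG so a set.seed() in R fixes the output.
// [[Rcpp::export]]
IntegerVector cpp_render_frames(NumericMatrix x_px, NumericMatrix y_px,
                                int height, int width, double spot_sigma,
                                double spot_peak, double background,
                                double noise_sigma) {
  const int np = x_px.nrow(), nf = x_px.ncol();
  IntegerVector out(static_cast<R_xlen_t>(height) * width * nf);
  out.attr("dim") = IntegerVector::create(height, width, nf);
  const int rad = static_cast<int>(std::ceil(4.0 * spot_sigma));
  const double inv2s2 = 1.0 / (2.0 * spot_sigma * spot_sigma);
  std::vector<double> img(static_cast<size_t>(height) * width);

  for (int f = 0; f < nf; ++f) {
    std::fill(img.begin(), img.end(), background);
    for (int p = 0; p < np; ++p) {
      const double cx = x_px(p, f), cy = y_px(p, f);
      const int i0 = std::max(0, static_cast<int>(std::floor(cy)) - rad);
      const int i1 = std::min(height - 1, static_cast<int>(std::ceil(cy)) + rad);
      const int j0 = std::max(0, static_cast<int>(std::floor(cx)) - rad);
      const int j1 = std::min(width - 1, static_cast<int>(std::ceil(cx)) + rad);
      for (int j = j0; j <= j1; ++j) {
        const double dx2 = (j - cx) * (j - cx);
        for (int i = i0; i <= i1; ++i) {
          const double r2 = dx2 + (i - cy) * (i - cy);
          img[static_cast<size_t>(j) * height + i] +=
              spot_peak * std::exp(-r2 * inv2s2);
        }
      }
    }
    const R_xlen_t base = static_cast<R_xlen_t>(f) * height * width;
    for (R_xlen_t q = 0; q < static_cast<R_xlen_t>(height) * width; ++q) {
      double v = img[q];
      if (noise_sigma > 0.0) v += noise_sigma * norm_rand();
      int iv = static_cast<int>(std::lround(v));
      if (iv < 0) iv = 0;
      if (iv > 255) iv = 255;
      out[base + q] = iv;
    }
  }
  return out;
}
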