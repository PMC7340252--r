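// Image primitives shared by the picker, the 2D classifier and the CNN.
// Convention: matrices are indexed [y, x] (row = y); coordinates handed in
// from R are 0-based pixel centers, x = column, y = row.

#include "imageops.h"
#include <queue>

using namespace arma;

// reflect-101 index (a b c d -> c b | a b c d | c b a): no duplicated edge
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * (n - 1);
  i = std::abs(i) % period;
  return (i < n) ? i : period - i;
}

arma::mat bilinear_resize(const arma::mat& img, int out_h, int out_w) {
  const int h = img.n_rows, w = img.n_cols;
  mat out(out_h, out_w);
  const double sy = (double)h / out_h, sx = (double)w / out_w;
  for (int xo = 0; xo < out_w; ++xo) {
    double xs = (xo + 0.5) * sx - 0.5;
    int x0 = (int)std::floor(xs);
    double fx = xs - x0;
    int xa = std::min(std::max(x0, 0), w - 1);
    int xb = std::min(std::max(x0 + 1, 0), w - 1);
    for (int yo = 0; yo < out_h; ++yo) {
      double ys = (yo + 0.5) * sy - 0.5;
      int y0 = (int)std::floor(ys);
      double fy = ys - y0;
      int ya = std::min(std::max(y0, 0), h - 1);
      int yb = std::min(std::max(y0 + 1, 0), h - 1);
      out(yo, xo) = (1 - fy) * ((1 - fx) * img(ya, xa) + fx * img(ya, xb)) +
                    fy       * ((1 - fx) * img(yb, xa) + fx * img(yb, xb));
    }
  }
  return out;
}

arma::mat rotate_reflect(const arma::mat& img, double angle_deg) {
  const int h = img.n_rows, w = img.n_cols;
  const double cy = (h - 1) / 2.0, cx = (w - 1) / 2.0;
  const double th = angle_deg * M_PI / 180.0;
  const double c = std::cos(th), s = std::sin(th);
  mat out(h, w);
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      // inverse mapping: rotate output grid by -angle about the center
      double dx = x - cx, dy = y - cy;
      double xs = cx + c * dx + s * dy;
      double ys = cy - s * dx + c * dy;
      int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      double fx = xs - x0, fy = ys - y0;
      int xa = reflect_idx(x0, w), xb = reflect_idx(x0 + 1, w);
      int ya = reflect_idx(y0, h), yb = reflect_idx(y0 + 1, h);
      out(y, x) = (1 - fy) * ((1 - fx) * img(ya, xa) + fx * img(ya, xb)) +
                  fy       * ((1 - fx) * img(yb, xa) + fx * img(yb, xb));
    }
  }
  return out;
}

arma::vec standardize_flat(const arma::mat& img) {
  vec v = vectorise(img);
  double m = mean(v), sd = stddev(v, 0);
  if (sd < 1e-12) return zeros<vec>(v.n_elem);
  return (v - m) / sd;
}

// [[Rcpp::export(name = ".cpp_bilinear_resize")]]
arma::mat cpp_bilinear_resize(const arma::mat& img, int out_h, int out_w) {
  return bilinear_resize(img, out_h, out_w);
}

// [[Rcpp::export(name = ".cpp_rotate_reflect")]]
arma::mat cpp_rotate_reflect(const arma::mat& img, double angle_deg) {
  return rotate_reflect(img, angle_deg);
}

// circular shift: out(y, x) = img(y - dy, x - dx) (content moves by +dy, +dx)
// [[Rcpp::export(name = ".cpp_shift_circ")]]
arma::mat cpp_shift_circ(const arma::mat& img, int dy, int dx) {
  return shift(shift(img, dy, 0), dx, 1);
}

// local windowed mean with reflect-101 boundary, via integral image
// [[Rcpp::export(name = ".cpp_box_mean_reflect")]]
arma::mat cpp_box_mean_reflect(const arma::mat& img, int window) {
  const int h = img.n_rows, w = img.n_cols, r = window / 2;
  if (window % 2 == 0 || window < 3)
    Rcpp::stop("window must be odd and >= 3");
  if (window > h || window > w)
    Rcpp::stop("window (%d) larger than image (%dx%d)", window, h, w);
  mat pad(h + 2 * r, w + 2 * r);
  for (int x = 0; x < w + 2 * r; ++x)
    for (int y = 0; y < h + 2 * r; ++y)
      pad(y, x) = img(reflect_idx(y - r, h), reflect_idx(x - r, w));
  // integral image with zero top row / left col
  mat I(h + 2 * r + 1, w + 2 * r + 1, fill::zeros);
  for (int x = 1; x <= w + 2 * r; ++x) {
    double colsum = 0;
    for (int y = 1; y <= h + 2 * r; ++y) {
      colsum += pad(y - 1, x - 1);
      I(y, x) = I(y, x - 1) + colsum;
    }
  }
  mat out(h, w);
  const double area = (double)window * window;
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y)
      out(y, x) = (I(y + window, x + window) - I(y, x + window) -
                   I(y + window, x) + I(y, x)) / area;
  return out;
}

// 8-connected component labelling (BFS), labels 1..n, background 0
// [[Rcpp::export(name = ".cpp_label8")]]
Rcpp::IntegerMatrix cpp_label8(const Rcpp::LogicalMatrix& mask) {
  const int h = mask.nrow(), w = mask.ncol();
  Rcpp::IntegerMatrix lab(h, w);
  int next = 0;
  std::queue<std::pair<int, int>> q;
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      if (!mask(y, x) || lab(y, x)) continue;
      lab(y, x) = ++next;
      q.push({y, x});
      while (!q.empty()) {
        auto [cy, cx] = q.front(); q.pop();
        for (int dx = -1; dx <= 1; ++dx) {
          for (int dy = -1; dy <= 1; ++dy) {
            int ny = cy + dy, nx = cx + dx;
            if (ny < 0 || nx < 0 || ny >= h || nx >= w) continue;
            if (mask(ny, nx) && !lab(ny, nx)) {
              lab(ny, nx) = next;
              q.push({ny, nx});
            }
          }
        }
      }
    }
  }
  return lab;
}

// Extract square windows centered at 0-based (cx, cy), block-bin, resize to
// out_px and standardize. Returns (out_px^2) x n matrix, one crop per column.
// Callers must pass in-bounds centers; box must be divisible by bin_factor.
// [[Rcpp::export(name = ".cpp_extract_windows")]]
arma::mat cpp_extract_windows(const arma::mat& img,
                              const arma::vec& cx, const arma::vec& cy,
                              int box, int bin_factor, int out_px) {
  const int h = img.n_rows, w = img.n_cols, n = cx.n_elem;
  if (box % bin_factor != 0) Rcpp::stop("box not divisible by bin_factor");
  const int nb = box / bin_factor;
  mat out(out_px * out_px, n);
  for (int i = 0; i < n; ++i) {
    int x0 = (int)std::lround(cx(i)) - box / 2;
    int y0 = (int)std::lround(cy(i)) - box / 2;
    if (x0 < 0 || y0 < 0 || x0 + box > w || y0 + box > h)
      Rcpp::stop("window %d out of bounds", i + 1);
    mat crop = img.submat(y0, x0, y0 + box - 1, x0 + box - 1);
    mat binned(nb, nb);
    if (bin_factor == 1) {
      binned = crop;
    } else {
      for (int bx = 0; bx < nb; ++bx)
        for (int by = 0; by < nb; ++by)
          binned(by, bx) = accu(crop.submat(by * bin_factor, bx * bin_factor,
                                            (by + 1) * bin_factor - 1,
                                            (bx + 1) * bin_factor - 1)) /
                           (bin_factor * bin_factor);
    }
    mat rs = (nb == out_px) ? binned : bilinear_resize(binned, out_px, out_px);
    out.col(i) = standardize_flat(rs);
  }
  return out;
}

// block-mean binning; trailing rows/cols not filling a block are dropped
// [[Rcpp::export(name = ".cpp_bin_image")]]
arma::mat cpp_bin_image(const arma::mat& img, int factor) {
  const int h = img.n_rows / factor, w = img.n_cols / factor;
  if (h < 1 || w < 1) Rcpp::stop("bin factor larger than image");
  if (factor == 1) return img;
  mat out(h, w);
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y)
      out(y, x) = accu(img.submat(y * factor, x * factor,
                                  (y + 1) * factor - 1,
                                  (x + 1) * factor - 1)) / (factor * factor);
  return out;
}
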