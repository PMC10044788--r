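// Low-level numeric kernels for the small convolutional networks.
// Tensors are passed as R numeric vectors in (H, W, C) column-major layout:
// element (y, x, c) sits at index y + H*x + H*W*c (0-based).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int idx3(int y, int x, int c, int H, int W) {
  return y + H * x + H * W * c;
}

// im2col for a kxk kernel with stride s and symmetric zero padding p.
// Output: (k*k*C) x (Ho*Wo) matrix; column = output position (row-major over
// (yo, xo) with yo fastest), row = (ky, kx, c) with ky fastest.
// [[Rcpp::export]]
arma::mat cpp_im2col(const NumericVector& im, int H, int W, int C,
                     int k, int s, int p) {
  int Ho = (H + 2 * p - k) / s + 1;
  int Wo = (W + 2 * p - k) / s + 1;
  arma::mat out(k * k * C, Ho * Wo, arma::fill::zeros);
  const double* px = im.begin();
  for (int xo = 0; xo < Wo; ++xo) {
    for (int yo = 0; yo < Ho; ++yo) {
      int col = yo + Ho * xo;
      int y0 = yo * s - p, x0 = xo * s - p;
      for (int c = 0; c < C; ++c) {
        for (int kx = 0; kx < k; ++kx) {
          int xx = x0 + kx;
          if (xx < 0 || xx >= W) continue;
          for (int ky = 0; ky < k; ++ky) {
            int yy = y0 + ky;
            if (yy < 0 || yy >= H) continue;
            out(ky + k * kx + k * k * c, col) = px[idx3(yy, xx, c, H, W)];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add columns back into an image.
// [[Rcpp::export]]
NumericVector cpp_col2im(const arma::mat& cols, int H, int W, int C,
                         int k, int s, int p) {
  int Ho = (H + 2 * p - k) / s + 1;
  int Wo = (W + 2 * p - k) / s + 1;
  NumericVector im(H * W * C);
  double* px = im.begin();
  for (int xo = 0; xo < Wo; ++xo) {
    for (int yo = 0; yo < Ho; ++yo) {
      int col = yo + Ho * xo;
      int y0 = yo * s - p, x0 = xo * s - p;
      for (int c = 0; c < C; ++c) {
        for (int kx = 0; kx < k; ++kx) {
          int xx = x0 + kx;
          if (xx < 0 || xx >= W) continue;
          for (int ky = 0; ky < k; ++ky) {
            int yy = y0 + ky;
            if (yy < 0 || yy >= H) continue;
            px[idx3(yy, xx, c, H, W)] += cols(ky + k * kx + k * k * c, col);
          }
        }
      }
    }
  }
  return im;
}

// Max pooling, kernel k, stride s, zero "same-ish" padding p.
// Returns list(value, argmax) where argmax holds the 0-based flat input index
// that won each output cell (-1 where the window saw only padding).
// [[Rcpp::export]]
List cpp_maxpool(const NumericVector& im, int H, int W, int C,
                 int k, int s, int p) {
  int Ho = (H + 2 * p - k) / s + 1;
  int Wo = (W + 2 * p - k) / s + 1;
  NumericVector out(Ho * Wo * C);
  IntegerVector arg(Ho * Wo * C);
  const double* px = im.begin();
  for (int c = 0; c < C; ++c) {
    for (int xo = 0; xo < Wo; ++xo) {
      for (int yo = 0; yo < Ho; ++yo) {
        double best = -1e300; int bi = -1;
        int y0 = yo * s - p, x0 = xo * s - p;
        for (int kx = 0; kx < k; ++kx) {
          int xx = x0 + kx; if (xx < 0 || xx >= W) continue;
          for (int ky = 0; ky < k; ++ky) {
            int yy = y0 + ky; if (yy < 0 || yy >= H) continue;
            double v = px[idx3(yy, xx, c, H, W)];
            if (v > best) { best = v; bi = idx3(yy, xx, c, H, W); }
          }
        }
        int o = idx3(yo, xo, c, Ho, Wo);
        out[o] = (bi >= 0) ? best : 0.0;
        arg[o] = bi;
      }
    }
  }
  return List::create(_["value"] = out, _["argmax"] = arg,
                      _["Ho"] = Ho, _["Wo"] = Wo);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(const NumericVector& grad_out,
                                   const IntegerVector& argmax,
                                   int in_len) {
  NumericVector g(in_len);
  for (int i = 0; i < grad_out.size(); ++i) {
    int a = argmax[i];
    if (a >= 0) g[a] += grad_out[i];
  }
  return g;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
NumericVector cpp_upsample2(const NumericVector& im, int H, int W, int C) {
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector out(Ho * Wo * C);
  const double* px = im.begin(); double* po = out.begin();
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < Wo; ++x)
      for (int y = 0; y < Ho; ++y)
        po[idx3(y, x, c, Ho, Wo)] = px[idx3(y / 2, x / 2, c, H, W)];
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_backward(const NumericVector& grad_out,
                                     int H, int W, int C) {
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector g(H * W * C);
  const double* po = grad_out.begin(); double* pg = g.begin();
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < Wo; ++x)
      for (int y = 0; y < Ho; ++y)
        pg[idx3(y / 2, x / 2, c, H, W)] += po[idx3(y, x, c, Ho, Wo)];
  return g;
}

// 8-connected component labelling of a logical mask (H x W, column-major).
// Returns integer labels 1..n, 0 for background.
// [[Rcpp::export]]
IntegerVector cpp_label8(const LogicalVector& mask, int H, int W) {
  IntegerVector lab(H * W, 0);
  std::vector<int> stack;
  int next = 0;
  for (int start = 0; start < H * W; ++start) {
    if (!mask[start] || lab[start]) continue;
    ++next;
    stack.push_back(start);
    lab[start] = next;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int y = p % H, x = p / H;
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx; if (xx < 0 || xx >= W) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy; if (yy < 0 || yy >= H) continue;
          int q = yy + H * xx;
          if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
        }
      }
    }
  }
  return lab;
}
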