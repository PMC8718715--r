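// Dense compute kernels for the convolutional network engine.
// Tensor layout throughout: (H, W, C, B) in R column-major order.
// Convolution weights: matrix (k*k*Cin) x Cout, rows ordered as the
// column-major flattening of a (k, k, Cin) array (dr fastest).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericVector alloc4(int H, int W, int C, int B) {
  NumericVector v((R_xlen_t)H * W * C * B);
  v.attr("dim") = IntegerVector::create(H, W, C, B);
  return v;
}

static void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& B) {
  IntegerVector dm = x.attr("dim");
  H = dm[0];
  W = dm[1];
  C = (dm.size() > 2) ? dm[2] : 1;
  B = (dm.size() > 3) ? dm[3] : 1;
}

// im2col for one sample (zero padding, stride 1, "same" output).
// src points to (H, W, Cin) slab; cols is (k*k*Cin) x (H*W).
static void im2col(const double* src, arma::mat& cols, int H, int W, int Cin,
                   int k) {
  int pad = k / 2;
  for (int ci = 0; ci < Cin; ++ci) {
    const double* ch = src + (R_xlen_t)ci * H * W;
    for (int dc = 0; dc < k; ++dc) {
      for (int dr = 0; dr < k; ++dr) {
        int row = dr + k * (dc + k * ci);
        for (int c = 0; c < W; ++c) {
          int cc = c + dc - pad;
          if (cc < 0 || cc >= W) {
            for (int r = 0; r < H; ++r) cols(row, r + H * c) = 0.0;
            continue;
          }
          for (int r = 0; r < H; ++r) {
            int rr = r + dr - pad;
            cols(row, r + H * c) =
                (rr < 0 || rr >= H) ? 0.0 : ch[rr + H * cc];
          }
        }
      }
    }
  }
}

// col2im accumulate (transpose of im2col) into dst (H, W, Cin) slab.
static void col2im_acc(const arma::mat& cols, double* dst, int H, int W,
                       int Cin, int k) {
  int pad = k / 2;
  for (int ci = 0; ci < Cin; ++ci) {
    double* ch = dst + (R_xlen_t)ci * H * W;
    for (int dc = 0; dc < k; ++dc) {
      for (int dr = 0; dr < k; ++dr) {
        int row = dr + k * (dc + k * ci);
        for (int c = 0; c < W; ++c) {
          int cc = c + dc - pad;
          if (cc < 0 || cc >= W) continue;
          for (int r = 0; r < H; ++r) {
            int rr = r + dr - pad;
            if (rr < 0 || rr >= H) continue;
            ch[rr + H * cc] += cols(row, r + H * c);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward(NumericVector X, NumericMatrix Wm,
                             NumericVector bias, int k) {
  int H, W, Cin, B;
  get_dims4(X, H, W, Cin, B);
  int Cout = Wm.ncol();
  if (Wm.nrow() != k * k * Cin) stop("weight/input channel mismatch");
  arma::mat Wa(Wm.begin(), Wm.nrow(), Cout, false);
  NumericVector Y = alloc4(H, W, Cout, B);
  arma::mat cols(k * k * Cin, H * W);
  for (int b = 0; b < B; ++b) {
    im2col(&X[(R_xlen_t)b * H * W * Cin], cols, H, W, Cin, k);
    arma::mat out = cols.t() * Wa;  // (H*W) x Cout
    double* dst = &Y[(R_xlen_t)b * H * W * Cout];
    for (int oc = 0; oc < Cout; ++oc) {
      double bb = bias[oc];
      const double* col = out.colptr(oc);
      double* d = dst + (R_xlen_t)oc * H * W;
      for (int i = 0; i < H * W; ++i) d[i] = col[i] + bb;
    }
  }
  return Y;
}

// [[Rcpp::export]]
List conv2d_backward(NumericVector X, NumericMatrix Wm, NumericVector dY,
                     int k) {
  int H, W, Cin, B;
  get_dims4(X, H, W, Cin, B);
  int Cout = Wm.ncol();
  arma::mat Wa(Wm.begin(), Wm.nrow(), Cout, false);
  NumericVector dX = alloc4(H, W, Cin, B);
  NumericMatrix dW(Wm.nrow(), Cout);
  arma::mat dWa(dW.begin(), Wm.nrow(), Cout, false);
  NumericVector db(Cout);
  arma::mat cols(k * k * Cin, H * W);
  for (int b = 0; b < B; ++b) {
    im2col(&X[(R_xlen_t)b * H * W * Cin], cols, H, W, Cin, k);
    arma::mat dYs(const_cast<double*>(&dY[(R_xlen_t)b * H * W * Cout]), H * W,
                  Cout, false);
    dWa += cols * dYs;
    arma::mat dcols = Wa * dYs.t();  // (k*k*Cin) x (H*W)
    col2im_acc(dcols, &dX[(R_xlen_t)b * H * W * Cin], H, W, Cin, k);
    for (int oc = 0; oc < Cout; ++oc) db[oc] += arma::accu(dYs.col(oc));
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// 2x2 max pooling (H, W even). Returns list(y, which) where which stores the
// 0..3 index (dr + 2*dc) of the argmax within each 2x2 block.
// [[Rcpp::export]]
List maxpool2_forward(NumericVector X) {
  int H, W, C, B;
  get_dims4(X, H, W, C, B);
  if (H % 2 || W % 2) stop("maxpool2 requires even H and W");
  int h = H / 2, w = W / 2;
  NumericVector Y = alloc4(h, w, C, B);
  IntegerVector which(Y.size());
  which.attr("dim") = Y.attr("dim");
  for (R_xlen_t s = 0; s < (R_xlen_t)C * B; ++s) {
    const double* src = &X[s * H * W];
    double* dst = &Y[s * h * w];
    int* wh = &which[s * h * w];
    for (int c = 0; c < w; ++c) {
      for (int r = 0; r < h; ++r) {
        int base = 2 * r + H * 2 * c;
        double best = src[base];
        int arg = 0;
        double v = src[base + 1];
        if (v > best) { best = v; arg = 1; }
        v = src[base + H];
        if (v > best) { best = v; arg = 2; }
        v = src[base + H + 1];
        if (v > best) { best = v; arg = 3; }
        dst[r + h * c] = best;
        wh[r + h * c] = arg;
      }
    }
  }
  return List::create(_["y"] = Y, _["which"] = which);
}

// [[Rcpp::export]]
NumericVector maxpool2_backward(NumericVector dY, IntegerVector which, int H,
                                int W) {
  int h, w, C, B;
  get_dims4(dY, h, w, C, B);
  NumericVector dX = alloc4(H, W, C, B);
  for (R_xlen_t s = 0; s < (R_xlen_t)C * B; ++s) {
    const double* dy = &dY[s * h * w];
    const int* wh = &which[s * h * w];
    double* dx = &dX[s * H * W];
    for (int c = 0; c < w; ++c)
      for (int r = 0; r < h; ++r) {
        int arg = wh[r + h * c];
        int base = 2 * r + H * 2 * c;
        int off = (arg & 1) + H * (arg >> 1);
        dx[base + off] += dy[r + h * c];
      }
  }
  return dX;
}

// 2x nearest-neighbour upsampling.
// [[Rcpp::export]]
NumericVector upsample2_forward(NumericVector X) {
  int H, W, C, B;
  get_dims4(X, H, W, C, B);
  NumericVector Y = alloc4(2 * H, 2 * W, C, B);
  for (R_xlen_t s = 0; s < (R_xlen_t)C * B; ++s) {
    const double* src = &X[s * H * W];
    double* dst = &Y[s * 4 * H * W];
    int H2 = 2 * H;
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        double v = src[r + H * c];
        int base = 2 * r + H2 * 2 * c;
        dst[base] = v;
        dst[base + 1] = v;
        dst[base + H2] = v;
        dst[base + H2 + 1] = v;
      }
  }
  return Y;
}

// [[Rcpp::export]]
NumericVector upsample2_backward(NumericVector dY) {
  int H2, W2, C, B;
  get_dims4(dY, H2, W2, C, B);
  int H = H2 / 2, W = W2 / 2;
  NumericVector dX = alloc4(H, W, C, B);
  for (R_xlen_t s = 0; s < (R_xlen_t)C * B; ++s) {
    const double* dy = &dY[s * (R_xlen_t)H2 * W2];
    double* dx = &dX[s * (R_xlen_t)H * W];
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        int base = 2 * r + H2 * 2 * c;
        dx[r + H * c] =
            dy[base] + dy[base + 1] + dy[base + H2] + dy[base + H2 + 1];
      }
  }
  return dX;
}

// Pairwise squared distances between all pixel centres of an H x W grid
// (x = col, y = row, 0-based) and a set of points (n x 2, columns x, y).
// Returns (H*W) x n matrix in pixel column-major order.
// [[Rcpp::export]]
NumericMatrix grid_point_dist2(int H, int W, NumericMatrix pts) {
  int n = pts.nrow();
  NumericMatrix out(H * W, n);
  for (int j = 0; j < n; ++j) {
    double px = pts(j, 0), py = pts(j, 1);
    for (int c = 0; c < W; ++c) {
      double dx = c - px;
      for (int r = 0; r < H; ++r) {
        double dy = r - py;
        out(r + H * c, j) = dx * dx + dy * dy;
      }
    }
  }
  return out;
}
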