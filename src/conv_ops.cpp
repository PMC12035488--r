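// 2-D convolution kernels (stride 1, zero padding, optional channel groups)
// used by the super-resolution network. Arrays are column-major with
// dimensions (H, W, C, N); weights are (k, k, Cin/groups, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col(const double* x, int H, int W, int Cg,
                   int k, int pad, int Ho, int Wo, arma::mat& M) {
  // M: (Ho*Wo) x (k*k*Cg); column index = i + k*(j + k*ci)
  for (int ci = 0; ci < Cg; ++ci) {
    const double* xc = x + (size_t)H * W * ci;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        double* col = M.colptr(i + k * (j + k * ci));
        for (int ow = 0; ow < Wo; ++ow) {
          int iw = ow + j - pad;
          double* dst = col + (size_t)Ho * ow;
          if (iw < 0 || iw >= W) {
            std::fill(dst, dst + Ho, 0.0);
            continue;
          }
          const double* src = xc + (size_t)H * iw;
          for (int oh = 0; oh < Ho; ++oh) {
            int ih = oh + i - pad;
            dst[oh] = (ih < 0 || ih >= H) ? 0.0 : src[ih];
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& M, int H, int W, int Cg,
                       int k, int pad, int Ho, int Wo, double* dx) {
  for (int ci = 0; ci < Cg; ++ci) {
    double* xc = dx + (size_t)H * W * ci;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const double* col = M.colptr(i + k * (j + k * ci));
        for (int ow = 0; ow < Wo; ++ow) {
          int iw = ow + j - pad;
          if (iw < 0 || iw >= W) continue;
          double* dst = xc + (size_t)H * iw;
          const double* src = col + (size_t)Ho * ow;
          for (int oh = 0; oh < Ho; ++oh) {
            int ih = oh + i - pad;
            if (ih >= 0 && ih < H) dst[ih] += src[oh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b, int pad, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cg = wd[2], Cout = wd[3];
  if (C % groups != 0 || Cout % groups != 0 || Cg != C / groups)
    stop("channel/group mismatch in conv2d");
  int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  int Cog = Cout / groups;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  arma::mat M((size_t)Ho * Wo, (size_t)k * k * Cg);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const double* xblk = x.begin() + (size_t)H * W * (g * Cg) + (size_t)H * W * C * n;
      im2col(xblk, H, W, Cg, k, pad, Ho, Wo, M);
      arma::mat Wm(const_cast<double*>(w.begin()) + (size_t)k * k * Cg * (g * Cog),
                   (size_t)k * k * Cg, Cog, false, true);
      arma::mat Y(y.begin() + (size_t)Ho * Wo * (g * Cog) + (size_t)Ho * Wo * Cout * n,
                  (size_t)Ho * Wo, Cog, false, true);
      Y = M * Wm;
      for (int co = 0; co < Cog; ++co) Y.col(co) += b[g * Cog + co];
    }
  }
  return y;
}

// depth-to-space: (H, W, C*r^2, N) -> (rH, rW, C, N); input channel index
// decomposes as di + r*dj + r^2*c
// [[Rcpp::export]]
NumericVector cpp_pixel_shuffle(NumericVector x, int r, bool inverse) {
  IntegerVector xd = x.attr("dim");
  int H, W, C, N;
  if (!inverse) {
    H = xd[0]; W = xd[1]; C = xd[2] / (r * r); N = xd[3];
  } else {
    H = xd[0] / r; W = xd[1] / r; C = xd[2]; N = xd[3];
  }
  NumericVector y(x.size());
  const double* xs = x.begin();
  double* ys = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int dj = 0; dj < r; ++dj)
        for (int di = 0; di < r; ++di) {
          size_t in_off = (size_t)H * W * ((size_t)di + r * dj + (size_t)r * r * c +
                                           (size_t)r * r * C * n);
          for (int w = 0; w < W; ++w) {
            const size_t out_base =
                (size_t)di + (size_t)r * H * (dj + (size_t)r * (w + (size_t)W *
                    (c + (size_t)C * n)));
            const double* src = xs + in_off + (size_t)H * w;
            if (!inverse) {
              for (int h = 0; h < H; ++h)
                ys[out_base + (size_t)r * h] = src[h];
            } else {
              double* dst = y.begin() + in_off + (size_t)H * w;
              const double* src2 = xs + out_base;
              for (int h = 0; h < H; ++h)
                dst[h] = src2[(size_t)r * h];
            }
          }
        }
  if (!inverse)
    y.attr("dim") = IntegerVector::create(H * r, W * r, C, N);
  else
    y.attr("dim") = IntegerVector::create(H, W, C * r * r, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w,
                         NumericVector dy, int pad, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cg = wd[2], Cout = wd[3];
  int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  int Cog = Cout / groups;

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);

  arma::mat M((size_t)Ho * Wo, (size_t)k * k * Cg);
  arma::mat dXcol((size_t)Ho * Wo, (size_t)k * k * Cg);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const double* xblk = x.begin() + (size_t)H * W * (g * Cg) + (size_t)H * W * C * n;
      im2col(xblk, H, W, Cg, k, pad, Ho, Wo, M);
      arma::mat Wm(const_cast<double*>(w.begin()) + (size_t)k * k * Cg * (g * Cog),
                   (size_t)k * k * Cg, Cog, false, true);
      arma::mat dWm(dw.begin() + (size_t)k * k * Cg * (g * Cog),
                    (size_t)k * k * Cg, Cog, false, true);
      arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * (g * Cog) +
                       (size_t)Ho * Wo * Cout * n,
                   (size_t)Ho * Wo, Cog, false, true);
      dWm += M.t() * dY;
      for (int co = 0; co < Cog; ++co) db[g * Cog + co] += arma::accu(dY.col(co));
      dXcol = dY * Wm.t();
      col2im_add(dXcol, H, W, Cg, k, pad, Ho, Wo,
                 dx.begin() + (size_t)H * W * (g * Cg) + (size_t)H * W * C * n);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
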