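// Tensor kernels for the segmentation network.
//
// Array convention (matches the R side): dense double arrays in R's
// column-major layout with dim = c(H, W, C, N); H indexes rows (y, down),
// W columns (x, right). Convolutions are cross-correlations (no kernel flip),
// zero-padded. im2col matrices are built transposed, (L x R) with
// L = Ho*Wo output positions (l = ho + Ho*wo) and R = kh*kw*Cin_g taps
// (r = i + kh*(j + kw*c)), so that every product is a plain "N","N" GEMM and
// the R-level Eq.-style reference (im2col %*% weights) reproduces results
// bit-for-bit through the same BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline IntegerVector dims_of(const NumericVector& a) {
  return a.attr("dim");
}

// bilinear lookup on one H x W plane with zero value outside the support
static inline double bilin_plane(const double* xp, int H, int W,
                                 double py, double px) {
  double y0f = std::floor(py), x0f = std::floor(px);
  int y0 = (int)y0f, x0 = (int)x0f;
  double fy = py - y0f, fx = px - x0f;
  double v = 0.0;
  for (int a = 0; a <= 1; ++a) {
    int yy = y0 + a;
    if (yy < 0 || yy >= H) continue;
    double wy = a ? fy : 1.0 - fy;
    if (wy == 0.0) continue;
    for (int b = 0; b <= 1; ++b) {
      int xx = x0 + b;
      if (xx < 0 || xx >= W) continue;
      double wx = b ? fx : 1.0 - fx;
      if (wx == 0.0) continue;
      v += xp[yy + (R_xlen_t)H * xx] * wy * wx;
    }
  }
  return v;
}

// ---------------------------------------------------------------- conv2d ----

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w,
                            NumericVector bias, int stride, int pad,
                            int groups) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin_g = wd[2], Cout = wd[3];
  if (Cin_g * groups != Cin) stop("conv2d: input channels (%d) incompatible with weight groups", Cin);
  if (Cout % groups != 0) stop("conv2d: output channels not divisible by groups");
  int Cout_g = Cout / groups;
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  R_xlen_t L = (R_xlen_t)Ho * Wo, R = (R_xlen_t)kh * kw * Cin_g;

  NumericVector y(L * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wall(w.begin(), R, Cout, false, true);
  arma::mat colT(L * N, R); // batch folded into rows for one wide GEMM

  for (int g = 0; g < groups; ++g) {
    for (int n = 0; n < N; ++n) {
      for (int c = 0; c < Cin_g; ++c) {
        const double* xp = x.begin() + (R_xlen_t)H * W * ((g * Cin_g + c) + (R_xlen_t)Cin * n);
        for (int j = 0; j < kw; ++j) {
          for (int i = 0; i < kh; ++i) {
            double* colcol = colT.colptr(i + kh * (j + kw * c)) + L * n;
            for (int wo = 0; wo < Wo; ++wo) {
              int wi = wo * stride - pad + j;
              bool wok = (wi >= 0 && wi < W);
              for (int ho = 0; ho < Ho; ++ho) {
                int hi = ho * stride - pad + i;
                double v = 0.0;
                if (wok && hi >= 0 && hi < H) v = xp[hi + (R_xlen_t)H * wi];
                colcol[ho + (R_xlen_t)Ho * wo] = v;
              }
            }
          }
        }
      }
    }
    arma::mat Wg(Wall.colptr(g * Cout_g), R, Cout_g, false, true);
    arma::mat Y = colT * Wg; // (L*N, Cout_g)
    for (int n = 0; n < N; ++n) {
      for (int o = 0; o < Cout_g; ++o) {
        const double* src = Y.colptr(o) + L * n;
        double* yc = y.begin() + L * ((R_xlen_t)(g * Cout_g + o) + (R_xlen_t)Cout * n);
        if (bias.size() > 0) {
          double b = bias[g * Cout_g + o];
          for (R_xlen_t l = 0; l < L; ++l) yc[l] = src[l] + b;
        } else {
          std::copy(src, src + L, yc);
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
                   int stride, int pad, int groups, bool has_bias) {
  IntegerVector xd = dims_of(x), wd = dims_of(w), yd = dims_of(dy);
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin_g = wd[2], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  int Cout_g = Cout / groups;
  R_xlen_t L = (R_xlen_t)Ho * Wo, R = (R_xlen_t)kh * kw * Cin_g;

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(has_bias ? Cout : 0);

  arma::mat Wall(w.begin(), R, Cout, false, true);
  arma::mat dWall(dw.begin(), R, Cout, false, true);
  arma::mat colT(L * N, R);
  arma::mat dY(L * N, Cout_g);

  for (int g = 0; g < groups; ++g) {
    for (int n = 0; n < N; ++n) {
      for (int c = 0; c < Cin_g; ++c) {
        const double* xp = x.begin() + (R_xlen_t)H * W * ((g * Cin_g + c) + (R_xlen_t)Cin * n);
        for (int j = 0; j < kw; ++j) {
          for (int i = 0; i < kh; ++i) {
            double* colcol = colT.colptr(i + kh * (j + kw * c)) + L * n;
            for (int wo = 0; wo < Wo; ++wo) {
              int wi = wo * stride - pad + j;
              bool wok = (wi >= 0 && wi < W);
              for (int ho = 0; ho < Ho; ++ho) {
                int hi = ho * stride - pad + i;
                double v = 0.0;
                if (wok && hi >= 0 && hi < H) v = xp[hi + (R_xlen_t)H * wi];
                colcol[ho + (R_xlen_t)Ho * wo] = v;
              }
            }
          }
        }
      }
      for (int o = 0; o < Cout_g; ++o) {
        const double* dyc = dy.begin() + L * ((R_xlen_t)(g * Cout_g + o) + (R_xlen_t)Cout * n);
        std::copy(dyc, dyc + L, dY.colptr(o) + L * n);
        if (has_bias) {
          double s = 0.0;
          for (R_xlen_t l = 0; l < L; ++l) s += dyc[l];
          db[g * Cout_g + o] += s;
        }
      }
    }
    arma::mat Wg(Wall.colptr(g * Cout_g), R, Cout_g, false, true);
    arma::mat dWg(dWall.colptr(g * Cout_g), R, Cout_g, false, true);
    dWg += colT.t() * dY;
    arma::mat dColT = dY * Wg.t(); // (L*N, R)
    // col2im scatter-add
    for (int n = 0; n < N; ++n) {
      for (int c = 0; c < Cin_g; ++c) {
        double* dxp = dx.begin() + (R_xlen_t)H * W * ((g * Cin_g + c) + (R_xlen_t)Cin * n);
        for (int j = 0; j < kw; ++j) {
          for (int i = 0; i < kh; ++i) {
            const double* dc = dColT.colptr(i + kh * (j + kw * c)) + L * n;
            for (int wo = 0; wo < Wo; ++wo) {
              int wi = wo * stride - pad + j;
              if (wi < 0 || wi >= W) continue;
              for (int ho = 0; ho < Ho; ++ho) {
                int hi = ho * stride - pad + i;
                if (hi < 0 || hi >= H) continue;
                dxp[hi + (R_xlen_t)H * wi] += dc[ho + (R_xlen_t)Ho * wo];
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// --------------------------------------------------------------- maxpool ----

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = dims_of(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  R_xlen_t L = (R_xlen_t)Ho * Wo;
  NumericVector y(L * C * N);
  IntegerVector idx(L * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = y.attr("dim");
  R_xlen_t p = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          int bi = -1;
          for (int j = 0; j < k; ++j) {
            int wi = wo * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hi = ho * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              double v = xp[hi + (R_xlen_t)H * wi];
              if (v > best) { best = v; bi = hi + H * wi; }
            }
          }
          // column-major write order coincides with (ho fastest) only if we
          // index explicitly:
          R_xlen_t o = (R_xlen_t)ho + Ho * wo + L * (c + (R_xlen_t)C * n);
          y[o] = best;
          idx[o] = bi;
          ++p;
        }
      }
    }
  }
  (void)p;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(IntegerVector idx, NumericVector dy, int H, int W) {
  IntegerVector yd = dims_of(dy);
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  R_xlen_t L = (R_xlen_t)Ho * Wo;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* dxp = dx.begin() + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      const R_xlen_t off = L * (c + (R_xlen_t)C * n);
      for (R_xlen_t l = 0; l < L; ++l) {
        int bi = idx[off + l];
        if (bi >= 0) dxp[bi] += dy[off + l];
      }
    }
  }
  return dx;
}

// ------------------------------------------------- bilinear 2x upsampling ----

static void up2x_coeffs(int H, std::vector<int>& i0, std::vector<int>& i1,
                        std::vector<double>& f) {
  int Ho = 2 * H;
  i0.resize(Ho); i1.resize(Ho); f.resize(Ho);
  for (int o = 0; o < Ho; ++o) {
    double s = (o + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    int a = (int)std::floor(s);
    if (a > H - 1) a = H - 1;
    i0[o] = a;
    i1[o] = std::min(a + 1, H - 1);
    f[o] = s - a;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample2x_fw(NumericVector x) {
  IntegerVector xd = dims_of(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> h0, h1, w0, w1;
  std::vector<double> fh, fw;
  up2x_coeffs(H, h0, h1, fh);
  up2x_coeffs(W, w0, w1, fw);
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      double* yp = y.begin() + (R_xlen_t)Ho * Wo * (c + (R_xlen_t)C * n);
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          double a = xp[h0[oh] + (R_xlen_t)H * w0[ow]];
          double b = xp[h0[oh] + (R_xlen_t)H * w1[ow]];
          double cval = xp[h1[oh] + (R_xlen_t)H * w0[ow]];
          double d = xp[h1[oh] + (R_xlen_t)H * w1[ow]];
          double top = a + (b - a) * fw[ow];
          double bot = cval + (d - cval) * fw[ow];
          yp[oh + (R_xlen_t)Ho * ow] = top + (bot - top) * fh[oh];
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2x_bw(NumericVector dy, int H, int W) {
  IntegerVector yd = dims_of(dy);
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  std::vector<int> h0, h1, w0, w1;
  std::vector<double> fh, fw;
  up2x_coeffs(H, h0, h1, fh);
  up2x_coeffs(W, w0, w1, fw);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* dxp = dx.begin() + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      const double* dyp = dy.begin() + (R_xlen_t)Ho * Wo * (c + (R_xlen_t)C * n);
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          double g = dyp[oh + (R_xlen_t)Ho * ow];
          double a = (1 - fh[oh]) * (1 - fw[ow]);
          double b = (1 - fh[oh]) * fw[ow];
          double cw = fh[oh] * (1 - fw[ow]);
          double d = fh[oh] * fw[ow];
          dxp[h0[oh] + (R_xlen_t)H * w0[ow]] += g * a;
          dxp[h0[oh] + (R_xlen_t)H * w1[ow]] += g * b;
          dxp[h1[oh] + (R_xlen_t)H * w0[ow]] += g * cw;
          dxp[h1[oh] + (R_xlen_t)H * w1[ow]] += g * d;
        }
      }
    }
  }
  return dx;
}

// ---------------------------------------------------------------- resize ----

// Non-differentiable resize for the data pipeline; x is (H, W, C).
// bilinear = false gives nearest-neighbour (used for class masks).
// [[Rcpp::export]]
NumericVector cpp_resize(NumericVector x, int Ho, int Wo, bool bilinear) {
  IntegerVector xd = dims_of(x);
  int H = xd[0], W = xd[1], C = xd[2];
  NumericVector y((R_xlen_t)Ho * Wo * C);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  double sh = (double)H / Ho, sw = (double)W / Wo;
  for (int c = 0; c < C; ++c) {
    const double* xp = x.begin() + (R_xlen_t)H * W * c;
    double* yp = y.begin() + (R_xlen_t)Ho * Wo * c;
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        double v;
        if (bilinear) {
          double py = (oh + 0.5) * sh - 0.5, px = (ow + 0.5) * sw - 0.5;
          if (py < 0) py = 0;
          if (py > H - 1) py = H - 1;
          if (px < 0) px = 0;
          if (px > W - 1) px = W - 1;
          v = bilin_plane(xp, H, W, py, px);
        } else {
          int hi = std::min(H - 1, (int)std::floor((oh + 0.5) * sh));
          int wi = std::min(W - 1, (int)std::floor((ow + 0.5) * sw));
          v = xp[hi + (R_xlen_t)H * wi];
        }
        yp[oh + (R_xlen_t)Ho * ow] = v;
      }
    }
  }
  return y;
}

// ------------------------------------------------------- bilinear samples ----

// Vector of bilinear lookups on one matrix plane; zero outside the support.
// [[Rcpp::export]]
NumericVector cpp_bilinear_points(NumericMatrix x, NumericVector py,
                                  NumericVector px) {
  int H = x.nrow(), W = x.ncol();
  R_xlen_t n = py.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!R_finite(py[i]) || !R_finite(px[i]))
      stop("bilinear_sample: non-finite coordinate");
    out[i] = bilin_plane(x.begin(), H, W, py[i], px[i]);
  }
  return out;
}

// ------------------------------------------------- deformable convolution ----

// 3x3, stride 1, same (zero) padding, one offset group.
// off has channels (dy_0, dx_0, ..., dy_8, dx_8); tap n = ik*3 + jk enumerates
// the receptive field {-1,0,1}^2 row-major (ik = row index, jk = col index).
// [[Rcpp::export]]
NumericVector cpp_deform_fw(NumericVector x, NumericVector w,
                            NumericVector bias, NumericVector off) {
  IntegerVector xd = dims_of(x), wd = dims_of(w), od = dims_of(off);
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int Cout = wd[3];
  if (od[2] != 18) stop("deformable_conv: offset field must have 18 channels (2N, N = 9), got %d", od[2]);
  if (od[0] != H || od[1] != W) stop("deformable_conv: offset field spatial size must match the output");
  R_xlen_t L = (R_xlen_t)H * W, R = 9 * (R_xlen_t)Cin;
  NumericVector y(L * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wall(w.begin(), R, Cout, false, true);
  arma::mat colT(L * N, R);
  for (int n = 0; n < N; ++n) {
    // fill rows [n*L, (n+1)*L) of colT
    for (int c = 0; c < Cin; ++c) {
      const double* xp = x.begin() + L * (c + (R_xlen_t)Cin * n);
      const double* op = off.begin() + L * 18 * (R_xlen_t)n;
      for (int jk = 0; jk < 3; ++jk) {
        for (int ik = 0; ik < 3; ++ik) {
          int tap = ik * 3 + jk;
          const double* oy = op + L * (2 * tap);
          const double* ox = op + L * (2 * tap + 1);
          double* colcol = colT.colptr(ik + 3 * (jk + 3 * c)) + L * n;
          for (int wo = 0; wo < W; ++wo) {
            for (int ho = 0; ho < H; ++ho) {
              R_xlen_t l = ho + (R_xlen_t)H * wo;
              colcol[l] = bilin_plane(xp, H, W, ho + (ik - 1) + oy[l],
                                      wo + (jk - 1) + ox[l]);
            }
          }
        }
      }
    }
  }
  arma::mat Y = colT * Wall; // (L*N, Cout)
  for (int n = 0; n < N; ++n) {
    for (int o = 0; o < Cout; ++o) {
      const double* src = Y.colptr(o) + L * n;
      double* yc = y.begin() + L * ((R_xlen_t)o + (R_xlen_t)Cout * n);
      if (bias.size() > 0) {
        double b = bias[o];
        for (R_xlen_t l = 0; l < L; ++l) yc[l] = src[l] + b;
      } else {
        std::copy(src, src + L, yc);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_deform_bw(NumericVector x, NumericVector w, NumericVector off,
                   NumericVector dy, bool has_bias) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int Cout = wd[3];
  R_xlen_t L = (R_xlen_t)H * W, R = 9 * (R_xlen_t)Cin;

  NumericVector dx(x.size());  dx.attr("dim") = xd;
  NumericVector dw(w.size());  dw.attr("dim") = wd;
  NumericVector doff(off.size()); doff.attr("dim") = off.attr("dim");
  NumericVector db(has_bias ? Cout : 0);

  arma::mat Wall(w.begin(), R, Cout, false, true);
  arma::mat dWall(dw.begin(), R, Cout, false, true);
  arma::mat colT(L * N, R);

  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < Cin; ++c) {
      const double* xp = x.begin() + L * (c + (R_xlen_t)Cin * n);
      const double* op = off.begin() + L * 18 * (R_xlen_t)n;
      for (int jk = 0; jk < 3; ++jk) {
        for (int ik = 0; ik < 3; ++ik) {
          int tap = ik * 3 + jk;
          const double* oy = op + L * (2 * tap);
          const double* ox = op + L * (2 * tap + 1);
          double* colcol = colT.colptr(ik + 3 * (jk + 3 * c)) + L * n;
          for (int wo = 0; wo < W; ++wo) {
            for (int ho = 0; ho < H; ++ho) {
              R_xlen_t l = ho + (R_xlen_t)H * wo;
              colcol[l] = bilin_plane(xp, H, W, ho + (ik - 1) + oy[l],
                                      wo + (jk - 1) + ox[l]);
            }
          }
        }
      }
    }
  }
  arma::mat dYall(L * N, Cout);
  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + L * (R_xlen_t)Cout * n;
    for (int o = 0; o < Cout; ++o) {
      const double* dyc = dyp + L * o;
      std::copy(dyc, dyc + L, dYall.colptr(o) + L * n);
      if (has_bias) {
        double s = 0.0;
        for (R_xlen_t l = 0; l < L; ++l) s += dyc[l];
        db[o] += s;
      }
    }
  }
  dWall += colT.t() * dYall;
  arma::mat dColT = dYall * Wall.t(); // (L*N, R)

  for (int n = 0; n < N; ++n) {
    const double* op = off.begin() + L * 18 * (R_xlen_t)n;
    double* dop = doff.begin() + L * 18 * (R_xlen_t)n;
    for (int c = 0; c < Cin; ++c) {
      const double* xp = x.begin() + L * (c + (R_xlen_t)Cin * n);
      double* dxp = dx.begin() + L * (c + (R_xlen_t)Cin * n);
      for (int jk = 0; jk < 3; ++jk) {
        for (int ik = 0; ik < 3; ++ik) {
          int tap = ik * 3 + jk;
          const double* oy = op + L * (2 * tap);
          const double* ox = op + L * (2 * tap + 1);
          double* doy = dop + L * (2 * tap);
          double* dox = dop + L * (2 * tap + 1);
          const double* dc = dColT.colptr(ik + 3 * (jk + 3 * c)) + L * n;
          for (int wo = 0; wo < W; ++wo) {
            for (int ho = 0; ho < H; ++ho) {
              R_xlen_t l = ho + (R_xlen_t)H * wo;
              double g = dc[l];
              if (g == 0.0) continue;
              double py = ho + (ik - 1) + oy[l];
              double px = wo + (jk - 1) + ox[l];
              double y0f = std::floor(py), x0f = std::floor(px);
              int y0 = (int)y0f, x0 = (int)x0f;
              double fy = py - y0f, fx = px - x0f;
              double dvy = 0.0, dvx = 0.0;
              for (int a = 0; a <= 1; ++a) {
                int yy = y0 + a;
                if (yy < 0 || yy >= H) continue;
                double wy = a ? fy : 1.0 - fy;
                double sy = a ? 1.0 : -1.0;
                for (int b = 0; b <= 1; ++b) {
                  int xx = x0 + b;
                  if (xx < 0 || xx >= W) continue;
                  double wx = b ? fx : 1.0 - fx;
                  double sx = b ? 1.0 : -1.0;
                  double xv = xp[yy + (R_xlen_t)H * xx];
                  dxp[yy + (R_xlen_t)H * xx] += g * wy * wx;
                  dvy += xv * sy * wx;
                  dvx += xv * sx * wy;
                }
              }
              doy[l] += g * dvy;
              dox[l] += g * dvx;
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db,
                      _["doff"] = doff);
}

// --------------------------------------------------------- Adam update ----

// In-place Adam with decoupled-from-R allocation: p, m, v are modified
// directly (they are owned solely by the parameter store and optimizer).
// [[Rcpp::export]]
void cpp_adam_update(NumericVector p, NumericVector g, NumericVector m,
                     NumericVector v, double lr, double b1, double b2,
                     double eps, double wd, double corr1, double corr2) {
  R_xlen_t n = p.size();
  double* pp = p.begin();
  const double* gp = g.begin();
  double* mp = m.begin();
  double* vp = v.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = gp[i] + wd * pp[i];
    mp[i] = b1 * mp[i] + (1 - b1) * gi;
    vp[i] = b2 * vp[i] + (1 - b2) * gi * gi;
    pp[i] -= lr * (mp[i] / corr1) / (std::sqrt(vp[i] / corr2) + eps);
  }
}

// ------------------------------------------------ PNG checksum helpers ----
// CRC-32 (ISO 3309) and Adler-32, needed by the indexed-palette PNG writer.

// [[Rcpp::export]]
double cpp_crc32(RawVector data) {
  static uint32_t table[256];
  static bool have = false;
  if (!have) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k) c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[i] = c;
    }
    have = true;
  }
  uint32_t c = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    c = table[(c ^ data[i]) & 0xFFu] ^ (c >> 8);
  return (double)(c ^ 0xFFFFFFFFu);
}

// ------------------------------------------------------ batch normalization ----

// Per-channel moments over (H, W, N) and the normalized, scaled output in one
// pass; avoids R-level transposes on the training path.
// [[Rcpp::export]]
List cpp_bn_fw(NumericVector x, NumericVector gamma, NumericVector beta,
               bool training, NumericVector run_mean, NumericVector run_var) {
  IntegerVector xd = dims_of(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  R_xlen_t plane = (R_xlen_t)H * W;
  double m = (double)plane * N;
  NumericVector mu(C), va(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* xp = x.begin() + plane * (c + (R_xlen_t)C * n);
        for (R_xlen_t i = 0; i < plane; ++i) { s += xp[i]; s2 += xp[i] * xp[i]; }
      }
      mu[c] = s / m;
      double v = s2 / m - mu[c] * mu[c];
      va[c] = v > 0 ? v : 0;
    }
  } else {
    mu = clone(run_mean);
    va = clone(run_var);
  }
  NumericVector y(x.size());
  y.attr("dim") = xd;
  const double eps = 1e-5;
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(va[c] + eps);
    double a = gamma[c] * inv, b = beta[c] - gamma[c] * inv * mu[c];
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + plane * (c + (R_xlen_t)C * n);
      double* yp = y.begin() + plane * (c + (R_xlen_t)C * n);
      for (R_xlen_t i = 0; i < plane; ++i) yp[i] = a * xp[i] + b;
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["va"] = va);
}

// [[Rcpp::export]]
List cpp_bn_bw(NumericVector x, NumericVector g, NumericVector gamma,
               NumericVector mu, NumericVector va, bool training) {
  IntegerVector xd = dims_of(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  R_xlen_t plane = (R_xlen_t)H * W;
  double m = (double)plane * N;
  const double eps = 1e-5;
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(va[c] + eps);
    double s1 = 0, s2 = 0, sg = 0, sgx = 0;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + plane * (c + (R_xlen_t)C * n);
      const double* gp = g.begin() + plane * (c + (R_xlen_t)C * n);
      for (R_xlen_t i = 0; i < plane; ++i) {
        double xh = (xp[i] - mu[c]) * inv;
        sg += gp[i];
        sgx += gp[i] * xh;
      }
    }
    dgamma[c] = sgx;
    dbeta[c] = sg;
    double gh1 = gamma[c] * sg / m, gh2 = gamma[c] * sgx / m;
    s1 = gh1; s2 = gh2;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + plane * (c + (R_xlen_t)C * n);
      const double* gp = g.begin() + plane * (c + (R_xlen_t)C * n);
      double* dp = dx.begin() + plane * (c + (R_xlen_t)C * n);
      if (training) {
        for (R_xlen_t i = 0; i < plane; ++i) {
          double xh = (xp[i] - mu[c]) * inv;
          dp[i] = inv * (gamma[c] * gp[i] - s1 - xh * s2);
        }
      } else {
        double a = gamma[c] * inv;
        for (R_xlen_t i = 0; i < plane; ++i) dp[i] = a * gp[i];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ------------------------------------------------------------------ relu ----

// [[Rcpp::export]]
NumericVector cpp_relu_fw(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bw(NumericVector x, NumericVector g) {
  NumericVector dx(g.size());
  dx.attr("dim") = g.attr("dim");
  const double* xp = x.begin();
  const double* gp = g.begin();
  double* dp = dx.begin();
  for (R_xlen_t i = 0; i < g.size(); ++i) dp[i] = xp[i] > 0 ? gp[i] : 0.0;
  return dx;
}
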