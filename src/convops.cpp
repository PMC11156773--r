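// Low-level array kernels for the neural-network layers.
// Layout convention everywhere: images are (H, W, C, N) column-major R arrays,
// convolution weights are (k, k, Cin, Cout) with odd k and zero 'same' padding.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void dims4(SEXP x, int &H, int &W, int &C, int &N) {
  IntegerVector d = Rf_getAttrib(x, R_DimSymbol);
  H = d[0]; W = d[1];
  C = (d.size() > 2) ? d[2] : 1;
  N = (d.size() > 3) ? d[3] : 1;
}

// Gather x into a (k*k*Cin) x (H*W*N) matrix; row index = kh + k*kw + k*k*c,
// column index = h + H*w + H*W*n, reading x[h+kh-pad, w+kw-pad, c, n].
// Column-major friendly: each output column (= output pixel) is filled
// contiguously; row order within a column is (kh, kw, c), matching the
// (k, k, Cin, Cout) weight layout.
static arma::mat im2col(const double *x, int H, int W, int C, int N, int k) {
  int pad = k / 2;
  arma::uword nrow = (arma::uword)k * k * C;
  arma::mat M(nrow, (arma::uword)H * W * N);
  for (int n = 0; n < N; ++n) {
    const double *xn = x + (size_t)n * H * W * C;
    for (int wo = 0; wo < W; ++wo) {
      for (int h = 0; h < H; ++h) {
        double *p = M.colptr((size_t)H * W * n + (size_t)H * wo + h);
        for (int c = 0; c < C; ++c) {
          const double *xc = xn + (size_t)c * H * W;
          for (int kw = 0; kw < k; ++kw) {
            int xw = wo + kw - pad;
            if (xw < 0 || xw >= W) {
              for (int kh = 0; kh < k; ++kh) *p++ = 0.0;
              continue;
            }
            const double *xcol = xc + (size_t)xw * H;
            for (int kh = 0; kh < k; ++kh) {
              int xh = h + kh - pad;
              *p++ = (xh < 0 || xh >= H) ? 0.0 : xcol[xh];
            }
          }
        }
      }
    }
  }
  return M;
}

// Scatter-add adjoint of im2col (same traversal; reads contiguous).
static void col2im(const arma::mat &G, double *dx, int H, int W, int C, int N, int k) {
  int pad = k / 2;
  for (int n = 0; n < N; ++n) {
    double *xn = dx + (size_t)n * H * W * C;
    for (int wo = 0; wo < W; ++wo) {
      for (int h = 0; h < H; ++h) {
        const double *p = G.colptr((size_t)H * W * n + (size_t)H * wo + h);
        for (int c = 0; c < C; ++c) {
          double *xc = xn + (size_t)c * H * W;
          for (int kw = 0; kw < k; ++kw) {
            int xw = wo + kw - pad;
            if (xw < 0 || xw >= W) { p += k; continue; }
            double *xcol = xc + (size_t)xw * H;
            for (int kh = 0; kh < k; ++kh) {
              int xh = h + kh - pad;
              if (xh >= 0 && xh < H) xcol[xh] += *p;
              ++p;
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  arma::mat M = im2col(x.begin(), H, W, C, N, k);
  arma::mat Wm(w.begin(), k * k * Cin, Cout, false);
  arma::mat Y = Wm.t() * M; // Cout x (HWN)
  NumericVector out((size_t)H * W * Cout * N);
  size_t HW = (size_t)H * W;
  double *po = out.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double *dst = po + ((size_t)n * Cout + co) * HW;
      for (size_t p = 0; p < HW; ++p) dst[p] = Y(co, (size_t)n * HW + p);
    }
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
                   bool want_dx, bool want_dw) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  size_t HW = (size_t)H * W;
  arma::mat dY(Cout, HW * N);
  const double *pdy = dy.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double *src = pdy + ((size_t)n * Cout + co) * HW;
      for (size_t p = 0; p < HW; ++p) dY(co, (size_t)n * HW + p) = src[p];
    }
  List res;
  arma::mat M;
  if (want_dw || want_dx) M = im2col(x.begin(), H, W, C, N, k);
  if (want_dw) {
    arma::mat dW = M * dY.t(); // (kkC) x Cout
    NumericVector dwv(dW.begin(), dW.end());
    dwv.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
    res["dw"] = dwv;
  }
  if (want_dx) {
    arma::mat Wm(w.begin(), k * k * Cin, Cout, false);
    arma::mat G = Wm * dY; // (kkC) x (HWN)
    NumericVector dxv((size_t)H * W * C * N); // zero-initialised
    col2im(G, dxv.begin(), H, W, C, N, k);
    dxv.attr("dim") = IntegerVector::create(H, W, C, N);
    res["dx"] = dxv;
  }
  return res;
}

// 2x average-pool downsample.
// [[Rcpp::export]]
NumericVector cpp_down2(NumericVector x) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)Ho * Wo * C * N);
  const double *px = x.begin();
  double *po = out.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double *xs = px + cn * H * W;
    double *os = po + cn * Ho * Wo;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        os[h + (size_t)Ho * w] =
            0.25 * (xs[2 * h + (size_t)H * (2 * w)] + xs[2 * h + 1 + (size_t)H * (2 * w)] +
                    xs[2 * h + (size_t)H * (2 * w + 1)] + xs[2 * h + 1 + (size_t)H * (2 * w + 1)]);
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_down2_bw(NumericVector dy) {
  int Ho, Wo, C, N;
  dims4(dy, Ho, Wo, C, N);
  int H = Ho * 2, W = Wo * 2;
  NumericVector out((size_t)H * W * C * N);
  const double *pd = dy.begin();
  double *po = out.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double *ds = pd + cn * Ho * Wo;
    double *os = po + cn * H * W;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        double g = 0.25 * ds[h + (size_t)Ho * w];
        os[2 * h + (size_t)H * (2 * w)] += g;
        os[2 * h + 1 + (size_t)H * (2 * w)] += g;
        os[2 * h + (size_t)H * (2 * w + 1)] += g;
        os[2 * h + 1 + (size_t)H * (2 * w + 1)] += g;
      }
  }
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}

// Separable 2x bilinear upsample:
// out[2i]   = (3*in[i] + in[i-1]) / 4
// out[2i+1] = (3*in[i] + in[i+1]) / 4   (zeros outside)
// [[Rcpp::export]]
NumericVector cpp_up2(NumericVector x) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((size_t)Ho * Wo * C * N);
  std::vector<double> tmp((size_t)Ho * W);
  const double *px = x.begin();
  double *po = out.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double *xs = px + cn * H * W;
    // rows (H axis)
    for (int w = 0; w < W; ++w) {
      const double *col = xs + (size_t)H * w;
      double *tcol = tmp.data() + (size_t)Ho * w;
      for (int i = 0; i < H; ++i) {
        double prev = (i > 0) ? col[i - 1] : 0.0;
        double next = (i < H - 1) ? col[i + 1] : 0.0;
        tcol[2 * i] = 0.25 * (3.0 * col[i] + prev);
        tcol[2 * i + 1] = 0.25 * (3.0 * col[i] + next);
      }
    }
    // cols (W axis)
    double *os = po + cn * Ho * Wo;
    for (int i = 0; i < Ho; ++i) {
      for (int w = 0; w < W; ++w) {
        double prev = (w > 0) ? tmp[i + (size_t)Ho * (w - 1)] : 0.0;
        double next = (w < W - 1) ? tmp[i + (size_t)Ho * (w + 1)] : 0.0;
        double cur = tmp[i + (size_t)Ho * w];
        os[i + (size_t)Ho * (2 * w)] = 0.25 * (3.0 * cur + prev);
        os[i + (size_t)Ho * (2 * w + 1)] = 0.25 * (3.0 * cur + next);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return out;
}

// Adjoint of cpp_up2: din[i] = (3*(d[2i]+d[2i+1]) + d[2i-1] + d[2i+2]) / 4 per axis.
static void up_axis_adj(const double *d, double *out, int n /* input length */) {
  for (int i = 0; i < n; ++i) {
    double acc = 3.0 * (d[2 * i] + d[2 * i + 1]);
    if (2 * i - 1 >= 0) acc += d[2 * i - 1];
    if (2 * i + 2 < 2 * n) acc += d[2 * i + 2];
    out[i] = 0.25 * acc;
  }
}

// [[Rcpp::export]]
NumericVector cpp_up2_bw(NumericVector dy) {
  int Ho, Wo, C, N;
  dims4(dy, Ho, Wo, C, N);
  int H = Ho / 2, W = Wo / 2;
  NumericVector out((size_t)H * W * C * N);
  std::vector<double> tmp((size_t)Ho * W);
  std::vector<double> colbuf(Wo), colout(W);
  const double *pd = dy.begin();
  double *po = out.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double *ds = pd + cn * Ho * Wo;
    // adjoint of W-axis pass first (reverse order of forward)
    for (int i = 0; i < Ho; ++i) {
      for (int w = 0; w < Wo; ++w) colbuf[w] = ds[i + (size_t)Ho * w];
      up_axis_adj(colbuf.data(), colout.data(), W);
      for (int w = 0; w < W; ++w) tmp[i + (size_t)Ho * w] = colout[w];
    }
    // adjoint of H-axis pass
    double *os = po + cn * H * W;
    for (int w = 0; w < W; ++w) {
      const double *tcol = tmp.data() + (size_t)Ho * w;
      up_axis_adj(tcol, os + (size_t)H * w, H);
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}
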