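// Dense numeric kernels for the network layers.
//
// Tensor layout everywhere: column-major R arrays with dim (H, W, C, N),
// i.e. flat index h + H*(w + W*(c + C*n)). Convolution is im2col + GEMM;
// the backward passes are the exact adjoints of the forward ones.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline IntegerVector dims4(const NumericVector &x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H, W, C, N) array");
  return d;
}

// Fill the im2col matrix (K x Ho*Wo) for image n. K = kh*kw*Cin with
// k-index i + kh*(j + kw*ci); column index q = ho + Ho*wo.
static void im2col(const double *x, int H, int W, int Cin, long noff,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat &col) {
  col.zeros();
  for (int ci = 0; ci < Cin; ++ci) {
    const double *xc = x + noff + (long)ci * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int krow = i + kh * (j + kw * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + j;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + i;
            if (hi < 0 || hi >= H) continue;
            col(krow, ho + Ho * wo) = xc[hi + (long)H * wi];
          }
        }
      }
    }
  }
}

// Adjoint of im2col: scatter-add columns back into the image gradient.
static void col2im(const arma::mat &col, double *dx, int H, int W, int Cin,
                   long noff, int kh, int kw, int stride, int pad,
                   int Ho, int Wo) {
  for (int ci = 0; ci < Cin; ++ci) {
    double *xc = dx + noff + (long)ci * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int krow = i + kh * (j + kw * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + j;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + i;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (long)H * wi] += col(krow, ho + Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  IntegerVector dx = dims4(x), dw = dims4(w);
  int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  int kh = dw[0], kw = dw[1], Cout = dw[3];
  if (dw[2] != Cin) stop("kernel input channels do not match input");
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  int K = kh * kw * Cin;

  arma::mat Wm(const_cast<double *>(w.begin()), K, Cout, false, true);
  arma::mat Wt = Wm.t();                       // Cout x K
  arma::colvec bv(const_cast<double *>(b.begin()), Cout, false, true);

  NumericVector y((long)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(K, (long)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, Cin, (long)n * H * W * Cin,
           kh, kw, stride, pad, Ho, Wo, col);
    arma::mat out = Wt * col;                  // Cout x (Ho*Wo)
    out.each_col() += bv;
    double *yp = y.begin() + (long)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co)
      for (long q = 0; q < (long)Ho * Wo; ++q)
        yp[q + (long)Ho * Wo * co] = out(co, q);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector dy, NumericVector x, NumericVector w,
                    int stride, int pad) {
  IntegerVector dxd = dims4(x), dwd = dims4(w), dyd = dims4(dy);
  int H = dxd[0], W = dxd[1], Cin = dxd[2], N = dxd[3];
  int kh = dwd[0], kw = dwd[1], Cout = dwd[3];
  int Ho = dyd[0], Wo = dyd[1];
  int K = kh * kw * Cin;

  arma::mat Wm(const_cast<double *>(w.begin()), K, Cout, false, true);

  NumericVector dxv((long)H * W * Cin * N);
  dxv.attr("dim") = dxd;
  NumericVector dwv((long)K * Cout);
  dwv.attr("dim") = dwd;
  NumericVector dbv(Cout);
  arma::mat dWacc(K, Cout, arma::fill::zeros);
  arma::colvec dbacc(Cout, arma::fill::zeros);

  arma::mat col(K, (long)Ho * Wo);
  arma::mat dyM(Cout, (long)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double *dyp = dy.begin() + (long)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co)
      for (long q = 0; q < (long)Ho * Wo; ++q)
        dyM(co, q) = dyp[q + (long)Ho * Wo * co];
    im2col(x.begin(), H, W, Cin, (long)n * H * W * Cin,
           kh, kw, stride, pad, Ho, Wo, col);
    dWacc += col * dyM.t();                    // K x Cout
    dbacc += arma::sum(dyM, 1);
    arma::mat colg = Wm * dyM;                 // K x (Ho*Wo)
    col2im(colg, dxv.begin(), H, W, Cin, (long)n * H * W * Cin,
           kh, kw, stride, pad, Ho, Wo);
  }
  std::copy(dWacc.begin(), dWacc.end(), dwv.begin());
  std::copy(dbacc.begin(), dbacc.end(), dbv.begin());
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export]]
NumericVector avgpool2_fwd_cpp(NumericVector x) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("avgpool2 requires even spatial size");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((long)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double *xp = x.begin() + cn * H * W;
    double *yp = y.begin() + cn * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double *p = xp + 2 * ho + (long)H * 2 * wo;
        yp[ho + (long)Ho * wo] = 0.25 * (p[0] + p[1] + p[H] + p[H + 1]);
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool2_bwd_cpp(NumericVector dy) {
  IntegerVector d = dims4(dy);
  int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  int H = Ho * 2, W = Wo * 2;
  NumericVector dx((long)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double *dyp = dy.begin() + cn * Ho * Wo;
    double *dxp = dx.begin() + cn * H * W;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double g = 0.25 * dyp[ho + (long)Ho * wo];
        double *p = dxp + 2 * ho + (long)H * 2 * wo;
        p[0] += g; p[1] += g; p[H] += g; p[H + 1] += g;
      }
  }
  return dx;
}

// Half-pixel-center bilinear sampling (the align_corners = FALSE
// convention); the backward pass scatters with identical weights, so it
// is the exact transpose of the forward map.
static void bilin_coef(int in, int out, std::vector<int> &i0,
                       std::vector<int> &i1, std::vector<double> &w1) {
  double scale = (double)in / out;
  i0.resize(out); i1.resize(out); w1.resize(out);
  for (int o = 0; o < out; ++o) {
    double s = (o + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    int lo = (int)std::floor(s);
    if (lo > in - 1) lo = in - 1;
    int hi = lo + 1 < in ? lo + 1 : in - 1;
    i0[o] = lo; i1[o] = hi; w1[o] = s - lo;
    if (w1[o] < 0) w1[o] = 0;
    if (w1[o] > 1) w1[o] = 1;
  }
}

// [[Rcpp::export]]
NumericVector bilinear_fwd_cpp(NumericVector x, int oh, int ow) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  std::vector<int> h0, h1, w0, w1v;
  std::vector<double> hw, ww;
  bilin_coef(H, oh, h0, h1, hw);
  bilin_coef(W, ow, w0, w1v, ww);
  NumericVector y((long)oh * ow * C * N);
  y.attr("dim") = IntegerVector::create(oh, ow, C, N);
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double *xp = x.begin() + cn * H * W;
    double *yp = y.begin() + cn * oh * ow;
    for (int wo = 0; wo < ow; ++wo) {
      double bw = ww[wo];
      long cA = (long)H * w0[wo], cB = (long)H * w1v[wo];
      for (int ho = 0; ho < oh; ++ho) {
        double bh = hw[ho];
        double top = (1 - bw) * xp[h0[ho] + cA] + bw * xp[h0[ho] + cB];
        double bot = (1 - bw) * xp[h1[ho] + cA] + bw * xp[h1[ho] + cB];
        yp[ho + (long)oh * wo] = (1 - bh) * top + bh * bot;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector bilinear_bwd_cpp(NumericVector dy, int H, int W) {
  IntegerVector d = dims4(dy);
  int oh = d[0], ow = d[1], C = d[2], N = d[3];
  std::vector<int> h0, h1, w0, w1v;
  std::vector<double> hw, ww;
  bilin_coef(H, oh, h0, h1, hw);
  bilin_coef(W, ow, w0, w1v, ww);
  NumericVector dx((long)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double *dyp = dy.begin() + cn * oh * ow;
    double *dxp = dx.begin() + cn * H * W;
    for (int wo = 0; wo < ow; ++wo) {
      double bw = ww[wo];
      long cA = (long)H * w0[wo], cB = (long)H * w1v[wo];
      for (int ho = 0; ho < oh; ++ho) {
        double bh = hw[ho];
        double g = dyp[ho + (long)oh * wo];
        dxp[h0[ho] + cA] += (1 - bh) * (1 - bw) * g;
        dxp[h0[ho] + cB] += (1 - bh) * bw * g;
        dxp[h1[ho] + cA] += bh * (1 - bw) * g;
        dxp[h1[ho] + cB] += bh * bw * g;
      }
    }
  }
  return dx;
}
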