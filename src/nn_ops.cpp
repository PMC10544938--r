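#include <Rcpp.h>
using namespace Rcpp;

// Dense tensors are R arrays in column-major order:
//   feature maps x: dim (C, H, W), weights w: dim (K, C, kh, kw).
// Stride and zero padding are shared across both spatial axes.

static inline int outSize(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// [[Rcpp::export]]
NumericVector convForwardCpp(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2];
  int K = wd[0], Cw = wd[1], kh = wd[2], kw = wd[3];
  if (Cw != C) stop("channel mismatch in convForward");
  int OH = outSize(H, kh, stride, pad), OW = outSize(W, kw, stride, pad);
  NumericVector y(K * OH * OW);
  y.attr("dim") = IntegerVector::create(K, OH, OW);
  const double *px = x.begin(), *pw = w.begin();
  double *py = y.begin();
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      for (int k = 0; k < K; ++k) {
        double acc = b[k];
        int h0 = oh * stride - pad, w0 = ow * stride - pad;
        for (int dw = 0; dw < kw; ++dw) {
          int iw = w0 + dw;
          if (iw < 0 || iw >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            int ih = h0 + dh;
            if (ih < 0 || ih >= H) continue;
            const double *xc = px + (size_t)C * (ih + (size_t)H * iw);
            const double *wc = pw + k + (size_t)K * C * (dh + (size_t)kh * dw);
            for (int c = 0; c < C; ++c) acc += xc[c] * wc[(size_t)K * c];
          }
        }
        py[k + (size_t)K * (oh + (size_t)OH * ow)] = acc;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List convBackwardCpp(NumericVector x, NumericVector w, NumericVector gy,
                     int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2];
  int K = wd[0], kh = wd[2], kw = wd[3];
  int OH = gd[1], OW = gd[2];
  NumericVector gx(C * H * W), gw(w.size()), gb(K);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  const double *px = x.begin(), *pw = w.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      int h0 = oh * stride - pad, w0 = ow * stride - pad;
      for (int k = 0; k < K; ++k) {
        double g = pg[k + (size_t)K * (oh + (size_t)OH * ow)];
        if (g == 0.0) continue;
        pgb[k] += g;
        for (int dw = 0; dw < kw; ++dw) {
          int iw = w0 + dw;
          if (iw < 0 || iw >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            int ih = h0 + dh;
            if (ih < 0 || ih >= H) continue;
            size_t xoff = (size_t)C * (ih + (size_t)H * iw);
            size_t woff = k + (size_t)K * C * (dh + (size_t)kh * dw);
            for (int c = 0; c < C; ++c) {
              pgx[xoff + c] += g * pw[woff + (size_t)K * c];
              pgw[woff + (size_t)K * c] += g * px[xoff + c];
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Nearest-neighbour 2x upsampling, (C,H,W) -> (C,2H,2W).
// [[Rcpp::export]]
NumericVector upsample2ForwardCpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2];
  NumericVector y((size_t)C * 4 * H * W);
  y.attr("dim") = IntegerVector::create(C, 2 * H, 2 * W);
  const double *px = x.begin();
  double *py = y.begin();
  int H2 = 2 * H;
  for (int w2 = 0; w2 < 2 * W; ++w2)
    for (int h2 = 0; h2 < H2; ++h2) {
      const double *src = px + (size_t)C * ((h2 / 2) + (size_t)H * (w2 / 2));
      double *dst = py + (size_t)C * (h2 + (size_t)H2 * w2);
      for (int c = 0; c < C; ++c) dst[c] = src[c];
    }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2BackwardCpp(NumericVector gy) {
  IntegerVector gd = gy.attr("dim");
  int C = gd[0], H2 = gd[1], W2 = gd[2];
  int H = H2 / 2, W = W2 / 2;
  NumericVector gx((size_t)C * H * W);
  gx.attr("dim") = IntegerVector::create(C, H, W);
  const double *pg = gy.begin();
  double *px = gx.begin();
  for (int w2 = 0; w2 < W2; ++w2)
    for (int h2 = 0; h2 < H2; ++h2) {
      const double *src = pg + (size_t)C * (h2 + (size_t)H2 * w2);
      double *dst = px + (size_t)C * ((h2 / 2) + (size_t)H * (w2 / 2));
      for (int c = 0; c < C; ++c) dst[c] += src[c];
    }
  return gx;
}
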