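#include <Rcpp.h>
using namespace Rcpp;

// Image layout throughout: x is an (H, W, C) numeric array (column-major,
// H fastest). im2col rows are ordered kh-fastest, then kw, then channel, so
// that a kernel array of dim (kh, kw, Cin, Cout) flattens to a conforming
// (kh*kw*Cin) x Cout matrix.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  int Ho = (H + 2 * ph - kh) / sh + 1;
  int Wo = (W + 2 * pw - kw) / sw + 1;
  NumericMatrix out(kh * kw * C, Ho * Wo);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* col = op + (wo * Ho + ho) * (kh * kw * C);
      int h0 = ho * sh - ph, w0 = wo * sw - pw;
      for (int c = 0; c < C; ++c) {
        const double* xc = xp + c * H * W;
        for (int j = 0; j < kw; ++j) {
          int wi = w0 + j;
          for (int i = 0; i < kh; ++i) {
            int hi = h0 + i;
            double v = 0.0;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W) v = xc[wi * H + hi];
            col[c * kh * kw + j * kh + i] = v;
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  int Ho = (H + 2 * ph - kh) / sh + 1;
  int Wo = (W + 2 * pw - kw) / sw + 1;
  NumericVector x(H * W * C);
  double* xp = x.begin();
  const double* cp = cols.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* col = cp + (wo * Ho + ho) * (kh * kw * C);
      int h0 = ho * sh - ph, w0 = wo * sw - pw;
      for (int c = 0; c < C; ++c) {
        double* xc = xp + c * H * W;
        for (int j = 0; j < kw; ++j) {
          int wi = w0 + j;
          if (wi < 0 || wi >= W) continue;
          for (int i = 0; i < kh; ++i) {
            int hi = h0 + i;
            if (hi < 0 || hi >= H) continue;
            xc[wi * H + hi] += col[c * kh * kw + j * kh + i];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}

// Depthwise convolution: weight dim (kh, kw, C).
// [[Rcpp::export]]
NumericVector dwconv_fwd_cpp(NumericVector x, NumericVector w, int H, int W, int C,
                             int kh, int kw, int sh, int sw, int ph, int pw) {
  int Ho = (H + 2 * ph - kh) / sh + 1;
  int Wo = (W + 2 * pw - kw) / sw + 1;
  NumericVector y(Ho * Wo * C);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + c * H * W;
    const double* wc = wp + c * kh * kw;
    double* yc = yp + c * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        int h0 = ho * sh - ph, w0 = wo * sw - pw;
        double acc = 0.0;
        for (int j = 0; j < kw; ++j) {
          int wi = w0 + j;
          if (wi < 0 || wi >= W) continue;
          for (int i = 0; i < kh; ++i) {
            int hi = h0 + i;
            if (hi < 0 || hi >= H) continue;
            acc += xc[wi * H + hi] * wc[j * kh + i];
          }
        }
        yc[wo * Ho + ho] = acc;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return y;
}

// [[Rcpp::export]]
NumericVector dwconv_bwd_x_cpp(NumericVector dy, NumericVector w, int H, int W, int C,
                               int kh, int kw, int sh, int sw, int ph, int pw) {
  int Ho = (H + 2 * ph - kh) / sh + 1;
  int Wo = (W + 2 * pw - kw) / sw + 1;
  NumericVector dx(H * W * C);
  const double* dyp = dy.begin();
  const double* wp = w.begin();
  double* dxp = dx.begin();
  for (int c = 0; c < C; ++c) {
    double* dxc = dxp + c * H * W;
    const double* wc = wp + c * kh * kw;
    const double* dyc = dyp + c * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double g = dyc[wo * Ho + ho];
        if (g == 0.0) continue;
        int h0 = ho * sh - ph, w0 = wo * sw - pw;
        for (int j = 0; j < kw; ++j) {
          int wi = w0 + j;
          if (wi < 0 || wi >= W) continue;
          for (int i = 0; i < kh; ++i) {
            int hi = h0 + i;
            if (hi < 0 || hi >= H) continue;
            dxc[wi * H + hi] += g * wc[j * kh + i];
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// [[Rcpp::export]]
NumericVector dwconv_bwd_w_cpp(NumericVector x, NumericVector dy, int H, int W, int C,
                               int kh, int kw, int sh, int sw, int ph, int pw) {
  int Ho = (H + 2 * ph - kh) / sh + 1;
  int Wo = (W + 2 * pw - kw) / sw + 1;
  NumericVector dw(kh * kw * C);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dwp = dw.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + c * H * W;
    double* dwc = dwp + c * kh * kw;
    const double* dyc = dyp + c * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double g = dyc[wo * Ho + ho];
        if (g == 0.0) continue;
        int h0 = ho * sh - ph, w0 = wo * sw - pw;
        for (int j = 0; j < kw; ++j) {
          int wi = w0 + j;
          if (wi < 0 || wi >= W) continue;
          for (int i = 0; i < kh; ++i) {
            int hi = h0 + i;
            if (hi < 0 || hi >= H) continue;
            dwc[j * kh + i] += g * xc[wi * H + hi];
          }
        }
      }
    }
  }
  dw.attr("dim") = IntegerVector::create(kh, kw, C);
  return dw;
}

// B-spline basis (order k) and its derivative on an extended knot vector,
// evaluated by the local de Boor recursion. Returns dense matrices with
// (length(knots) - 1 - k) columns.
// [[Rcpp::export]]
List bspline_eval_cpp(NumericVector t, NumericVector knots, int k) {
  int n = t.size();
  int nk = knots.size();
  int nb = nk - 1 - k;
  NumericMatrix B(n, nb), D(n, nb);
  double h0 = knots[1] - knots[0];
  std::vector<double> N(k + 1), Nlow(k + 1), left(k + 1), right(k + 1);
  for (int p = 0; p < n; ++p) {
    double x = t[p];
    // containing interval m (0-based): knots[m] <= x < knots[m+1]
    // (arithmetic lookup for the uniform grids used here, then a local fixup)
    int m = (int)std::floor((x - knots[0]) / h0);
    if (m < 0) m = 0;
    if (m > nk - 2) m = nk - 2;
    while (m > 0 && x < knots[m]) --m;
    while (m < nk - 2 && x >= knots[m + 1]) ++m;
    if (m < k) m = k;
    if (m > nk - 2 - k) m = nk - 2 - k;
    N[0] = 1.0;
    for (int j = 1; j <= k; ++j) {
      if (j == k) for (int r = 0; r < k; ++r) Nlow[r] = N[r];
      left[j] = x - knots[m + 1 - j];
      right[j] = knots[m + j] - x;
      double saved = 0.0;
      for (int r = 0; r < j; ++r) {
        double temp = N[r] / (right[r + 1] + left[j - r]);
        N[r] = saved + right[r + 1] * temp;
        saved = left[j - r] * temp;
      }
      N[j] = saved;
    }
    // order-k basis indices m-k .. m
    for (int r = 0; r <= k; ++r) {
      int i = m - k + r;
      if (i >= 0 && i < nb) B(p, i) = N[r];
    }
    // derivative from order-(k-1) values (indices m-k+1 .. m)
    for (int r = 0; r <= k; ++r) {
      int i = m - k + r;
      if (i < 0 || i >= nb) continue;
      double lo = 0.0, hi = 0.0;
      int rl = r - 1;                       // Nlow index for basis i (order k-1)
      if (rl >= 0 && rl < k) lo = Nlow[rl] / (knots[i + k] - knots[i]);
      if (r < k) hi = Nlow[r] / (knots[i + k + 1] - knots[i + 1]);
      D(p, i) = k * (lo - hi);
    }
  }
  return List::create(_["B"] = B, _["D"] = D);
}
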