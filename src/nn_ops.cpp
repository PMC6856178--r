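#include <Rcpp.h>
using namespace Rcpp;

// Layout conventions shared with the R side:
//  - activation tensors are column-major arrays with dim (H, W, C, N)
//  - im2col rows are ordered ci*k*k + kj*k + ki (ki = row offset within the
//    kernel, kj = column offset), matching how conv weights are flattened
//  - im2col columns are ordered n*(Ho*Wo) + wo*Ho + ho

// [[Rcpp::export]]
NumericMatrix nn_im2col(NumericVector x, int H, int W, int C, int N,
                        int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix cols(C * k * k, Ho * Wo * N);
  const double *px = x.begin();
  double *pc = cols.begin();
  const int nrow = C * k * k;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const long col = (long)n * Ho * Wo + (long)wo * Ho + ho;
        double *dst = pc + col * nrow;
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int ci = 0; ci < C; ++ci) {
          const long base = ((long)n * C + ci) * H * W;
          for (int kj = 0; kj < k; ++kj) {
            const int wi = w0 + kj;
            for (int ki = 0; ki < k; ++ki) {
              const int hi = h0 + ki;
              double v = 0.0;
              if (hi >= 0 && hi < H && wi >= 0 && wi < W)
                v = px[base + (long)wi * H + hi];
              dst[ci * k * k + kj * k + ki] = v;
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector nn_col2im(NumericMatrix cols, int H, int W, int C, int N,
                        int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector x((long)H * W * C * N);
  double *px = x.begin();
  const double *pc = cols.begin();
  const int nrow = C * k * k;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const long col = (long)n * Ho * Wo + (long)wo * Ho + ho;
        const double *src = pc + col * nrow;
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int ci = 0; ci < C; ++ci) {
          const long base = ((long)n * C + ci) * H * W;
          for (int kj = 0; kj < k; ++kj) {
            const int wi = w0 + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int hi = h0 + ki;
              if (hi < 0 || hi >= H) continue;
              px[base + (long)wi * H + hi] += src[ci * k * k + kj * k + ki];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}

// In-place Nadam parameter update. par, m and v are modified directly (the
// R side guarantees they are privately owned by the layer environment).
// [[Rcpp::export]]
void nn_nadam_update(NumericVector par, NumericVector m, NumericVector v,
                     NumericVector g, double lr, double beta1, double beta2,
                     double bc1, double bc2, double eps) {
  const R_xlen_t n = par.size();
  double *pp = par.begin(), *pm = m.begin(), *pv = v.begin(),
         *pg = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = pg[i];
    pm[i] = beta1 * pm[i] + (1.0 - beta1) * gi;
    pv[i] = beta2 * pv[i] + (1.0 - beta2) * gi * gi;
    const double mhat = pm[i] / bc1;
    const double vhat = pv[i] / bc2;
    const double step = (beta1 * mhat + (1.0 - beta1) * gi / bc1) /
                        (std::sqrt(vhat) + eps);
    pp[i] -= lr * step;
  }
}
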