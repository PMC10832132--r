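#include <Rcpp.h>
#include <limits>
#include <vector>
using namespace Rcpp;

// Rectangular linear assignment by shortest augmenting paths with dual
// updates (Jonker-Volgenant). Rows are assigned to distinct columns,
// ncol >= nrow required. Returns 1-based column index per row; the
// assignment attains the global minimum of sum(cost[i, col[i]]).
// [[Rcpp::export]]
IntegerVector lapjv_cpp(NumericMatrix cost) {
  const int n = cost.nrow(), m = cost.ncol();
  if (m < n) stop("cost matrix must have ncol >= nrow");
  const double INF = std::numeric_limits<double>::infinity();
  // row-major copy so the per-row scans below are contiguous
  std::vector<double> C((size_t)n * m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) C[(size_t)i * m + j] = cost(i, j);
  std::vector<double> u(n, 0.0), v(m, 0.0);
  std::vector<int> row4col(m, -1), col4row(n, -1);

  for (int curRow = 0; curRow < n; ++curRow) {
    std::vector<double> shortest(m, INF);
    std::vector<int> pred(m, -1);
    std::vector<char> SR(n, 0), SC(m, 0);
    double minVal = 0.0;
    int i = curRow, sink = -1;
    while (sink == -1) {
      SR[i] = 1;
      double lowest = INF;
      int jLow = -1;
      const double* ci = &C[(size_t)i * m];
      const double ui = u[i];
      for (int j = 0; j < m; ++j) {
        if (SC[j]) continue;
        double r = minVal + ci[j] - ui - v[j];
        if (r < shortest[j]) { shortest[j] = r; pred[j] = i; }
        if (shortest[j] < lowest ||
            (shortest[j] == lowest && jLow >= 0 && row4col[j] == -1 && row4col[jLow] != -1)) {
          lowest = shortest[j];
          jLow = j;
        }
      }
      minVal = lowest;
      if (jLow < 0 || minVal == INF) stop("assignment infeasible");
      if (row4col[jLow] == -1) {
        sink = jLow;
      } else {
        SC[jLow] = 1;
        i = row4col[jLow];
      }
    }
    u[curRow] += minVal;
    for (int k = 0; k < n; ++k)
      if (SR[k] && k != curRow) u[k] += minVal - shortest[col4row[k]];
    for (int j = 0; j < m; ++j)
      if (SC[j]) v[j] -= minVal - shortest[j];
    int j = sink;
    while (true) {
      int ii = pred[j];
      row4col[j] = ii;
      int tmp = col4row[ii];
      col4row[ii] = j;
      j = tmp;
      if (ii == curRow) break;
    }
  }
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) out[k] = col4row[k] + 1;
  return out;
}

// Patch extraction for stride-1 "valid" convolution. X holds one sample
// per column with flat layout index(c,h,w) = ((c-1)*H + h-1)*W + w
// (w fastest). Output: (C*kh*kw) x (N*OH*OW), patch columns ordered
// sample-major, then output row, then output col (fastest).
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericMatrix X, int C, int H, int W, int kh, int kw) {
  const int N = X.ncol();
  const int OH = H - kh + 1, OW = W - kw + 1;
  NumericMatrix P(C * kh * kw, N * OH * OW);
  for (int n = 0; n < N; ++n) {
    const double* xc = &X(0, n);
    for (int oh = 0; oh < OH; ++oh) {
      for (int ow = 0; ow < OW; ++ow) {
        double* pc = &P(0, (n * OH + oh) * OW + ow);
        int r = 0;
        for (int c = 0; c < C; ++c)
          for (int ki = 0; ki < kh; ++ki) {
            const double* src = xc + (c * H + oh + ki) * W + ow;
            for (int kj = 0; kj < kw; ++kj) pc[r++] = src[kj];
          }
      }
    }
  }
  return P;
}

// Adjoint of im2col_cpp: scatter-add patch gradients back to input.
// [[Rcpp::export]]
NumericMatrix col2im_cpp(NumericMatrix dP, int C, int H, int W, int kh, int kw, int N) {
  const int OH = H - kh + 1, OW = W - kw + 1;
  NumericMatrix dX(C * H * W, N);
  for (int n = 0; n < N; ++n) {
    double* xc = &dX(0, n);
    for (int oh = 0; oh < OH; ++oh) {
      for (int ow = 0; ow < OW; ++ow) {
        const double* pc = &dP(0, (n * OH + oh) * OW + ow);
        int r = 0;
        for (int c = 0; c < C; ++c)
          for (int ki = 0; ki < kh; ++ki) {
            double* dst = xc + (c * H + oh + ki) * W + ow;
            for (int kj = 0; kj < kw; ++kj) dst[kj] += pc[r++];
          }
      }
    }
  }
  return dX;
}

// Overlapping max pooling (pool x pool window, stride 1) per channel.
// Returns pooled values and 1-based linear argmax indices into X.
// [[Rcpp::export]]
List maxpool_cpp(NumericMatrix X, int C, int H, int W, int pool) {
  const int N = X.ncol();
  const int OH = H - pool + 1, OW = W - pool + 1;
  NumericMatrix out(C * OH * OW, N);
  IntegerMatrix amax(C * OH * OW, N);
  for (int n = 0; n < N; ++n) {
    const double* xc = &X(0, n);
    for (int c = 0; c < C; ++c) {
      for (int oh = 0; oh < OH; ++oh) {
        for (int ow = 0; ow < OW; ++ow) {
          double best = -std::numeric_limits<double>::infinity();
          int bestIdx = -1;
          for (int pi = 0; pi < pool; ++pi)
            for (int pj = 0; pj < pool; ++pj) {
              int idx = (c * H + oh + pi) * W + ow + pj;
              if (xc[idx] > best) { best = xc[idx]; bestIdx = idx; }
            }
          int o = (c * OH + oh) * OW + ow;
          out(o, n) = best;
          amax(o, n) = n * (C * H * W) + bestIdx + 1;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// Backward of maxpool_cpp: route gradients to the argmax positions.
// [[Rcpp::export]]
NumericMatrix maxpool_bwd_cpp(NumericMatrix dY, IntegerMatrix amax, int inRows) {
  const int N = dY.ncol();
  NumericMatrix dX(inRows, N);
  double* px = dX.begin();
  const double* py = dY.begin();
  const int* pa = amax.begin();
  const R_xlen_t len = (R_xlen_t)dY.nrow() * N;
  for (R_xlen_t k = 0; k < len; ++k) px[pa[k] - 1] += py[k];
  return dX;
}
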