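#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Unrolls a (H, W, N, C) tensor into a (OH*OW*N) x (KH*KW*C) matrix so a
// strided 2D convolution becomes one GEMM.  Row index runs (oh, ow, n) with
// oh fastest; column index runs (ki, kj, c) with ki fastest.  Out-of-bounds
// taps (zero padding) stay zero.  The channel-last layout lets the R side
// reshape GEMM results back to tensors without transposes.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int N, int C,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  const int OH = (H + 2 * ph - kh) / sh + 1;
  const int OW = (W + 2 * pw - kw) / sw + 1;
  NumericMatrix out(OH * OW * N, kh * kw * C);
  const double* xp = x.begin();
  double* op = out.begin();
  const R_xlen_t nrow = (R_xlen_t)OH * OW * N;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const R_xlen_t col = ki + (R_xlen_t)kh * (kj + (R_xlen_t)kw * c);
        double* ocol = op + col * nrow;
        for (int n = 0; n < N; ++n) {
          const double* xc = xp + (R_xlen_t)H * W * (n + (R_xlen_t)N * c);
          for (int ow = 0; ow < OW; ++ow) {
            const int w = ow * sw - pw + kj;
            if (w < 0 || w >= W) continue;
            const double* xcol = xc + (R_xlen_t)H * w;
            double* orow = ocol + (R_xlen_t)OH * (ow + (R_xlen_t)OW * n);
            for (int oh = 0; oh < OH; ++oh) {
              const int h = oh * sh - ph + ki;
              if (h < 0 || h >= H) continue;
              orow[oh] = xcol[h];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatters/accumulates a column matrix back onto a
// (H, W, N, C) tensor.  Used for conv input-gradients and for transposed
// convolution forward passes.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int N, int C,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  const int OH = (H + 2 * ph - kh) / sh + 1;
  const int OW = (W + 2 * pw - kw) / sw + 1;
  NumericVector x((R_xlen_t)H * W * C * N);
  const double* cp = cols.begin();
  double* xp = x.begin();
  const R_xlen_t nrow = (R_xlen_t)OH * OW * N;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const R_xlen_t col = ki + (R_xlen_t)kh * (kj + (R_xlen_t)kw * c);
        const double* ccol = cp + col * nrow;
        for (int n = 0; n < N; ++n) {
          double* xc = xp + (R_xlen_t)H * W * (n + (R_xlen_t)N * c);
          for (int ow = 0; ow < OW; ++ow) {
            const int w = ow * sw - pw + kj;
            if (w < 0 || w >= W) continue;
            double* xcol = xc + (R_xlen_t)H * w;
            const double* crow = ccol + (R_xlen_t)OH * (ow + (R_xlen_t)OW * n);
            for (int oh = 0; oh < OH; ++oh) {
              const int h = oh * sh - ph + ki;
              if (h < 0 || h >= H) continue;
              xcol[h] += crow[oh];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, N, C);
  return x;
}

// 3D connected-component labelling on a logical array (dims d1 x d2 x d3).
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, int d1, int d2, int d3,
                                   int connectivity) {
  IntegerVector lab((R_xlen_t)d1 * d2 * d3, 0);
  std::vector<std::array<int, 3> > offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dx, dy, dz});
      }
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < lab.size(); ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int i = v % d1, j = (v / d1) % d2, k = v / ((R_xlen_t)d1 * d2);
      for (size_t o = 0; o < offs.size(); ++o) {
        int ii = i + offs[o][0], jj = j + offs[o][1], kk = k + offs[o][2];
        if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
          continue;
        R_xlen_t w = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
        if (mask[w] && lab[w] == 0) { lab[w] = cur; q.push(w); }
      }
    }
  }
  lab.attr("dim") = IntegerVector::create(d1, d2, d3);
  return lab;
}

// Binary dilation (op = 1) or erosion (op = 0) with a Euclidean ball
// structuring element of the given voxel radius.
// [[Rcpp::export]]
LogicalVector morph_ball_cpp(LogicalVector mask, int d1, int d2, int d3,
                             double radius, int op) {
  std::vector<std::array<int, 3> > offs;
  int r = (int)std::floor(radius);
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if (dx * dx + dy * dy + dz * dz <= radius * radius + 1e-9)
          offs.push_back({dx, dy, dz});
  LogicalVector out((R_xlen_t)d1 * d2 * d3);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        bool acc = (op == 1) ? false : true;
        for (size_t o = 0; o < offs.size(); ++o) {
          int ii = i + offs[o][0], jj = j + offs[o][1], kk = k + offs[o][2];
          bool v;
          if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
            v = false;  // outside the volume counts as background
          else
            v = mask[ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk)];
          if (op == 1) { if (v) { acc = true; break; } }
          else         { if (!v) { acc = false; break; } }
        }
        out[i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k)] = acc;
      }
  out.attr("dim") = IntegerVector::create(d1, d2, d3);
  return out;
}

// 2D global gamma: for every evaluated-grid point, minimise
// sqrt((dD/dd_abs)^2 + (r/dta)^2) over reference-grid points within
// radius_mm.  Both grids share the physical origin at pixel (1,1); pixel
// centres at (i-1)*spacing.  Points excluded by mask get NA.
// [[Rcpp::export]]
NumericMatrix gamma_kernel_cpp(NumericMatrix evald, NumericMatrix refd,
                               NumericVector sp_eval, NumericVector sp_ref,
                               double dd_abs, double dta_mm, double radius_mm,
                               LogicalMatrix include) {
  const int ner = evald.nrow(), nec = evald.ncol();
  const int nrr = refd.nrow(), nrc = refd.ncol();
  NumericMatrix g(ner, nec);
  const double inv_dd2 = 1.0 / (dd_abs * dd_abs);
  const double inv_dta2 = 1.0 / (dta_mm * dta_mm);
  for (int j = 0; j < nec; ++j) {
    const double yj = j * sp_eval[1];
    for (int i = 0; i < ner; ++i) {
      if (!include(i, j)) { g(i, j) = NA_REAL; continue; }
      const double xi = i * sp_eval[0];
      const double de = evald(i, j);
      int a0 = (int)std::ceil((xi - radius_mm) / sp_ref[0]);
      int a1 = (int)std::floor((xi + radius_mm) / sp_ref[0]);
      int b0 = (int)std::ceil((yj - radius_mm) / sp_ref[1]);
      int b1 = (int)std::floor((yj + radius_mm) / sp_ref[1]);
      if (a0 < 0) a0 = 0;
      if (b0 < 0) b0 = 0;
      if (a1 > nrr - 1) a1 = nrr - 1;
      if (b1 > nrc - 1) b1 = nrc - 1;
      double best = R_PosInf;
      for (int b = b0; b <= b1; ++b) {
        const double dy = b * sp_ref[1] - yj;
        for (int a = a0; a <= a1; ++a) {
          const double dx = a * sp_ref[0] - xi;
          const double r2 = (dx * dx + dy * dy) * inv_dta2;
          if (r2 >= best) continue;
          const double dd = de - refd(a, b);
          const double val = dd * dd * inv_dd2 + r2;
          if (val < best) best = val;
        }
      }
      g(i, j) = std::sqrt(best);
    }
  }
  return g;
}
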