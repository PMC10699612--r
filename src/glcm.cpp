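#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Focal grey-level co-occurrence textures.
//
// levels: quantized level indices (0..n_levels-1), NA_INTEGER for nodata.
// win: odd window side in pixels; windows are truncated at raster edges.
// offsets: k x 2 integer matrix of (row, col) displacements.
// symmetric: count each pair in both orders.
//
// Returns mean, variance, contrast and entropy of the per-window GLCM in a
// single pass; pixels whose window holds no valid pair are NA. The window
// histogram is maintained incrementally along each output row: only the
// pair-columns entering and leaving the window are updated, so the cost per
// pixel is O(win * k) rather than O(win^2 * k).

struct GlcmAcc {
  std::vector<long> hist;
  long total;
  int n;
  GlcmAcc(int n_levels) : hist((size_t)n_levels * n_levels, 0), total(0), n(n_levels) {}
  inline void bump(int a, int b, int delta, bool symmetric) {
    hist[(size_t)a * n + b] += delta;
    total += delta;
    if (symmetric) { hist[(size_t)b * n + a] += delta; total += delta; }
  }
  void reset() { std::fill(hist.begin(), hist.end(), 0L); total = 0; }
};

// add (delta=+1) or remove (delta=-1) every pair touching base/partner
// column `col` for one offset, inside window rows [r0,r1], cols [c0,c1]
static inline void update_column(const IntegerMatrix& lv, GlcmAcc& acc,
                                 int r0, int r1, int c0, int c1,
                                 int dr, int dc, int col, int delta,
                                 bool symmetric, int nr, int nc) {
  // pairs with base pixel in column `col`
  int pc = col + dc;
  if (pc >= c0 && pc <= c1 && pc >= 0 && pc < nc) {
    for (int i = r0; i <= r1; ++i) {
      int pi = i + dr;
      if (pi < r0 || pi > r1 || pi < 0 || pi >= nr) continue;
      int a = lv(i, col), b = lv(pi, pc);
      if (a == NA_INTEGER || b == NA_INTEGER) continue;
      acc.bump(a, b, delta, symmetric);
    }
  }
  // pairs whose partner falls in column `col` (distinct from above when dc != 0)
  if (dc != 0) {
    int bc = col - dc;
    if (bc >= c0 && bc <= c1 && bc >= 0 && bc < nc && bc != col) {
      for (int i = r0; i <= r1; ++i) {
        int pi = i + dr;
        if (pi < r0 || pi > r1 || pi < 0 || pi >= nr) continue;
        int a = lv(i, bc), b = lv(pi, col);
        if (a == NA_INTEGER || b == NA_INTEGER) continue;
        acc.bump(a, b, delta, symmetric);
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_focal_glcm(IntegerMatrix levels, int win, int n_levels,
                    IntegerMatrix offsets, bool symmetric) {
  int nr = levels.nrow(), nc = levels.ncol();
  int h = win / 2;
  int k = offsets.nrow();
  NumericMatrix out_mean(nr, nc), out_var(nr, nc),
                out_con(nr, nc), out_ent(nr, nc);
  std::fill(out_mean.begin(), out_mean.end(), NA_REAL);
  std::fill(out_var.begin(), out_var.end(), NA_REAL);
  std::fill(out_con.begin(), out_con.end(), NA_REAL);
  std::fill(out_ent.begin(), out_ent.end(), NA_REAL);

  GlcmAcc acc(n_levels);
  for (int r = 0; r < nr; ++r) {
    int r0 = std::max(0, r - h), r1 = std::min(nr - 1, r + h);
    acc.reset();
    // build histogram for the window centred at column 0
    int c0 = 0, c1 = std::min(nc - 1, h);
    for (int o = 0; o < k; ++o) {
      int dr = offsets(o, 0), dc = offsets(o, 1);
      for (int j = c0; j <= c1; ++j) {
        int pc = j + dc;
        if (pc < c0 || pc > c1) continue;
        for (int i = r0; i <= r1; ++i) {
          int pi = i + dr;
          if (pi < r0 || pi > r1) continue;
          int a = levels(i, j), b = levels(pi, pc);
          if (a == NA_INTEGER || b == NA_INTEGER) continue;
          acc.bump(a, b, 1, symmetric);
        }
      }
    }
    for (int c = 0; c < nc; ++c) {
      if (c > 0) {
        int nc0 = std::max(0, c - h), nc1 = std::min(nc - 1, c + h);
        if (nc0 > c0) { // column c0 leaves the window
          for (int o = 0; o < k; ++o)
            update_column(levels, acc, r0, r1, c0, c1,
                          offsets(o, 0), offsets(o, 1), c0, -1, symmetric, nr, nc);
          c0 = nc0;
        }
        if (nc1 > c1) { // column nc1 enters the window
          c1 = nc1;
          for (int o = 0; o < k; ++o)
            update_column(levels, acc, r0, r1, c0, c1,
                          offsets(o, 0), offsets(o, 1), c1, +1, symmetric, nr, nc);
        }
      }
      if (acc.total > 0) {
        double T = (double)acc.total;
        double mu = 0.0, con = 0.0, ent = 0.0;
        for (int a = 0; a < n_levels; ++a) {
          for (int b = 0; b < n_levels; ++b) {
            long cnt = acc.hist[(size_t)a * n_levels + b];
            if (!cnt) continue;
            double p = cnt / T;
            mu += a * p;
            con += (double)(a - b) * (a - b) * p;
            ent -= p * std::log(p);
          }
        }
        double var = 0.0;
        for (int a = 0; a < n_levels; ++a) {
          for (int b = 0; b < n_levels; ++b) {
            long cnt = acc.hist[(size_t)a * n_levels + b];
            if (!cnt) continue;
            var += (a - mu) * (a - mu) * (cnt / T);
          }
        }
        out_mean(r, c) = mu; out_var(r, c) = var;
        out_con(r, c) = con; out_ent(r, c) = ent;
      }
    }
  }
  return List::create(_["mean"] = out_mean, _["variance"] = out_var,
                      _["contrast"] = out_con, _["entropy"] = out_ent);
}

// Mean of a numeric matrix in a truncated square focal window (integral
// image); NA cells are excluded from both numerator and denominator.
// [[Rcpp::export]]
NumericMatrix cpp_focal_mean(NumericMatrix m, int win) {
  int nr = m.nrow(), nc = m.ncol(), h = win / 2;
  std::vector<double> S((nr + 1) * (nc + 1), 0.0), N((nr + 1) * (nc + 1), 0.0);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double v = m(i, j);
      bool na = NumericMatrix::is_na(v);
      S[(i + 1) * (nc + 1) + (j + 1)] = (na ? 0.0 : v) + S[i * (nc + 1) + j + 1] +
        S[(i + 1) * (nc + 1) + j] - S[i * (nc + 1) + j];
      N[(i + 1) * (nc + 1) + (j + 1)] = (na ? 0.0 : 1.0) + N[i * (nc + 1) + j + 1] +
        N[(i + 1) * (nc + 1) + j] - N[i * (nc + 1) + j];
    }
  }
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    int r0 = std::max(0, i - h), r1 = std::min(nr - 1, i + h);
    for (int j = 0; j < nc; ++j) {
      int c0 = std::max(0, j - h), c1 = std::min(nc - 1, j + h);
      double sum = S[(r1 + 1) * (nc + 1) + c1 + 1] - S[r0 * (nc + 1) + c1 + 1] -
        S[(r1 + 1) * (nc + 1) + c0] + S[r0 * (nc + 1) + c0];
      double nval = N[(r1 + 1) * (nc + 1) + c1 + 1] - N[r0 * (nc + 1) + c1 + 1] -
        N[(r1 + 1) * (nc + 1) + c0] + N[r0 * (nc + 1) + c0];
      out(i, j) = nval > 0 ? sum / nval : NA_REAL;
    }
  }
  return out;
}

// Percent cover of 1-pixels of a binary raster in a truncated square focal
// window: 100 * (# ones) / (# non-NA pixels), NA where the window holds no
// valid pixel.
// [[Rcpp::export]]
NumericMatrix cpp_percent_cover(NumericMatrix binary, int win) {
  int nr = binary.nrow(), nc = binary.ncol(), h = win / 2;
  // integral images over ones and valid counts
  std::vector<double> S((nr + 1) * (nc + 1), 0.0), N((nr + 1) * (nc + 1), 0.0);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double v = binary(i, j);
      double one = (!NumericMatrix::is_na(v) && v != 0) ? 1.0 : 0.0;
      double val = NumericMatrix::is_na(v) ? 0.0 : 1.0;
      S[(i + 1) * (nc + 1) + (j + 1)] = one + S[i * (nc + 1) + j + 1] +
        S[(i + 1) * (nc + 1) + j] - S[i * (nc + 1) + j];
      N[(i + 1) * (nc + 1) + (j + 1)] = val + N[i * (nc + 1) + j + 1] +
        N[(i + 1) * (nc + 1) + j] - N[i * (nc + 1) + j];
    }
  }
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    int r0 = std::max(0, i - h), r1 = std::min(nr - 1, i + h);
    for (int j = 0; j < nc; ++j) {
      int c0 = std::max(0, j - h), c1 = std::min(nc - 1, j + h);
      double ones = S[(r1 + 1) * (nc + 1) + c1 + 1] - S[r0 * (nc + 1) + c1 + 1] -
        S[(r1 + 1) * (nc + 1) + c0] + S[r0 * (nc + 1) + c0];
      double nval = N[(r1 + 1) * (nc + 1) + c1 + 1] - N[r0 * (nc + 1) + c1 + 1] -
        N[(r1 + 1) * (nc + 1) + c0] + N[r0 * (nc + 1) + c0];
      out(i, j) = nval > 0 ? 100.0 * ones / nval : NA_REAL;
    }
  }
  return out;
}
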