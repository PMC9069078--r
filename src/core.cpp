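#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Packed genotype storage: 2 bits per call, values in {0,1,2} stored
// literally (code 3 unused), 4 calls per byte, SNP-major rows padded to
// whole bytes.  Matches PLINK bed geometry so bed I/O is a recode, not a
// repack.

static inline int get2(const unsigned char *row, int j) {
  return (row[j >> 2] >> ((j & 3) << 1)) & 3;
}

static inline void set2(unsigned char *row, int j, int val) {
  row[j >> 2] |= (unsigned char)(val << ((j & 3) << 1));
}

// [[Rcpp::export]]
RawVector cpp_pack(const IntegerMatrix &x) {
  const int m = x.nrow(), n = x.ncol();
  const int bpr = (n + 3) / 4;
  RawVector out((R_xlen_t)m * bpr);
  unsigned char *p = RAW(out);
  for (int i = 0; i < m; ++i) {
    unsigned char *row = p + (R_xlen_t)i * bpr;
    for (int j = 0; j < n; ++j) {
      int v = x(i, j);
      if (v < 0 || v > 2)
        stop("genotype out of alphabet {0,1,2} at row %d, column %d", i + 1, j + 1);
      set2(row, j, v);
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_unpack(const RawVector &packed, int m, int n) {
  const int bpr = (n + 3) / 4;
  IntegerMatrix out(m, n);
  const unsigned char *p = RAW(packed);
  for (int i = 0; i < m; ++i) {
    const unsigned char *row = p + (R_xlen_t)i * bpr;
    for (int j = 0; j < n; ++j) out(i, j) = get2(row, j);
  }
  return out;
}

// Decode a PLINK bed body (no 3-byte magic) into packed {0,1,2} storage.
// bed 2-bit codes: 00 hom A1 (dosage 2), 01 missing, 10 het (1), 11 hom A2
// (0); dosage counts the A1 allele.  Missing calls are imputed to the
// rounded per-SNP mean of the observed calls (0 when a SNP is entirely
// missing); the number of imputed calls and all-missing SNPs is returned.
// [[Rcpp::export]]
List cpp_bed_to_packed(const RawVector &body, int m, int n) {
  const int bpr = (n + 3) / 4;
  if ((R_xlen_t)body.size() != (R_xlen_t)m * bpr)
    stop("bed body has %d bytes; expected %d (m = %d SNPs, n = %d samples)",
         (int)body.size(), (int)((R_xlen_t)m * bpr), m, n);
  RawVector packed((R_xlen_t)m * bpr);
  const unsigned char *src = RAW(body);
  unsigned char *dst = RAW(packed);
  R_xlen_t n_imputed = 0;
  int n_all_missing = 0;
  std::vector<int> geno(n);
  for (int i = 0; i < m; ++i) {
    const unsigned char *row = src + (R_xlen_t)i * bpr;
    int sum = 0, obs = 0, miss = 0;
    for (int j = 0; j < n; ++j) {
      int code = get2(row, j);
      int g;
      switch (code) {
      case 0: g = 2; break;          // hom A1
      case 2: g = 1; break;          // het
      case 3: g = 0; break;          // hom A2
      default: g = -1; ++miss; break; // 01 missing
      }
      geno[j] = g;
      if (g >= 0) { sum += g; ++obs; }
    }
    int fill = 0;
    if (miss > 0) {
      if (obs > 0) {
        double mean = (double)sum / obs;
        fill = (int)std::lround(mean);
        if (fill < 0) fill = 0;
        if (fill > 2) fill = 2;
      } else {
        ++n_all_missing;
      }
      n_imputed += miss;
    }
    unsigned char *out = dst + (R_xlen_t)i * bpr;
    for (int j = 0; j < n; ++j) set2(out, j, geno[j] < 0 ? fill : geno[j]);
  }
  return List::create(_["packed"] = packed,
                      _["n_imputed"] = (double)n_imputed,
                      _["n_all_missing"] = n_all_missing);
}

// Re-encode packed {0,1,2} storage as a PLINK bed body (no missing calls).
// [[Rcpp::export]]
RawVector cpp_packed_to_bed(const RawVector &packed, int m, int n) {
  const int bpr = (n + 3) / 4;
  RawVector body((R_xlen_t)m * bpr);
  const unsigned char *src = RAW(packed);
  unsigned char *dst = RAW(body);
  for (int i = 0; i < m; ++i) {
    const unsigned char *row = src + (R_xlen_t)i * bpr;
    unsigned char *out = dst + (R_xlen_t)i * bpr;
    for (int j = 0; j < n; ++j) {
      int g = get2(row, j);
      int code;
      switch (g) {
      case 2: code = 0; break;
      case 1: code = 2; break;
      default: code = 3; break;
      }
      set2(out, j, code);
    }
  }
  return body;
}

// Per-column heterozygote counts: since 2x - x^2 is 1 for x = 1 and 0 for
// x in {0, 2}, the diagonal d_j = (het count in column j) / m.
// [[Rcpp::export]]
IntegerVector cpp_het_counts(const RawVector &packed, int m, int n) {
  const int bpr = (n + 3) / 4;
  IntegerVector out(n);
  const unsigned char *p = RAW(packed);
  for (int i = 0; i < m; ++i) {
    const unsigned char *row = p + (R_xlen_t)i * bpr;
    for (int j = 0; j < n; ++j)
      if (get2(row, j) == 1) ++out[j];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Mailman finite-alphabet multiplication.
//
// Rows are grouped into segments of d = ceil(log3 n) rows.  Each column of a
// segment is a d-digit base-3 number (digit r = row r of the segment, least
// significant first); the codes are computed once and reused across all
// products.  A segment-level product then costs O(n + 3^d) = O(n) instead of
// O(d n), giving O(mn / log3 n) per full product.  Rows left over after the
// last full segment are multiplied naively.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_mailman_codes(const RawVector &packed, int m, int n,
                                int d, int nseg) {
  const int bpr = (n + 3) / 4;
  IntegerVector codes((R_xlen_t)nseg * n);
  const unsigned char *p = RAW(packed);
  int *c = INTEGER(codes);
  for (int s = 0; s < nseg; ++s) {
    int *cs = c + (R_xlen_t)s * n;
    for (int j = 0; j < n; ++j) cs[j] = 0;
    int pow3 = 1;
    for (int r = 0; r < d; ++r) {
      const unsigned char *row = p + (R_xlen_t)(s * d + r) * bpr;
      for (int j = 0; j < n; ++j) cs[j] += pow3 * get2(row, j);
      pow3 *= 3;
    }
  }
  return codes;
}

// y = X v exactly, via Mailman segments plus a naive tail.
// [[Rcpp::export]]
NumericVector cpp_matvec(const RawVector &packed, int m, int n,
                         const IntegerVector &codes, int d, int nseg,
                         const NumericVector &v) {
  if (v.size() != n) stop("length(v) = %d but X has %d columns", (int)v.size(), n);
  const int bpr = (n + 3) / 4;
  NumericVector out(m);
  const unsigned char *p = RAW(packed);
  const double *vv = REAL(v);
  double *y = REAL(out);
  int pd = 1;
  for (int r = 0; r < d; ++r) pd *= 3;
  std::vector<double> z(nseg > 0 ? pd : 0);
  const int *c = nseg > 0 ? INTEGER(codes) : nullptr;
  for (int s = 0; s < nseg; ++s) {
    std::fill(z.begin(), z.end(), 0.0);
    const int *cs = c + (R_xlen_t)s * n;
    for (int j = 0; j < n; ++j) z[cs[j]] += vv[j];
    // peel digits from most significant (row s*d + d - 1) downwards
    int len = pd / 3;
    for (int r = d - 1; r >= 0; --r) {
      double s1 = 0.0, s2 = 0.0;
      for (int i = 0; i < len; ++i) {
        s1 += z[len + i];
        s2 += z[2 * len + i];
        z[i] += z[len + i] + z[2 * len + i];
      }
      y[s * d + r] = s1 + 2.0 * s2;
      len /= 3;
    }
  }
  for (int i = nseg * d; i < m; ++i) {
    const unsigned char *row = p + (R_xlen_t)i * bpr;
    double acc = 0.0;
    for (int j = 0; j < n; ++j) {
      int g = get2(row, j);
      if (g) acc += g * vv[j];
    }
    y[i] = acc;
  }
  return out;
}

// y = X^T w, reusing the same column codes: for each segment build the
// lookup S with S[c] = sum_r digit_r(c) * w[row r], then scatter S[code_j].
// [[Rcpp::export]]
NumericVector cpp_rmatvec(const RawVector &packed, int m, int n,
                          const IntegerVector &codes, int d, int nseg,
                          const NumericVector &w) {
  if (w.size() != m) stop("length(w) = %d but X has %d rows", (int)w.size(), m);
  const int bpr = (n + 3) / 4;
  NumericVector out(n);
  const unsigned char *p = RAW(packed);
  const double *ww = REAL(w);
  double *y = REAL(out);
  int pd = 1;
  for (int r = 0; r < d; ++r) pd *= 3;
  std::vector<double> S(nseg > 0 ? pd : 0);
  const int *c = nseg > 0 ? INTEGER(codes) : nullptr;
  for (int s = 0; s < nseg; ++s) {
    S[0] = 0.0;
    int len = 1;
    for (int r = 0; r < d; ++r) {
      double wr = ww[s * d + r];
      for (int i = 0; i < len; ++i) {
        S[len + i] = S[i] + wr;
        S[2 * len + i] = S[i] + 2.0 * wr;
      }
      len *= 3;
    }
    const int *cs = c + (R_xlen_t)s * n;
    for (int j = 0; j < n; ++j) y[j] += S[cs[j]];
  }
  for (int i = nseg * d; i < m; ++i) {
    const unsigned char *row = p + (R_xlen_t)i * bpr;
    double wi = ww[i];
    if (wi == 0.0) continue;
    for (int j = 0; j < n; ++j) {
      int g = get2(row, j);
      if (g) y[j] += g * wi;
    }
  }
  return out;
}

// Batched products against a skinny dense matrix: one pass over the column
// codes serves all k right-hand sides, so the code array (the dominant
// memory traffic) is read once per product instead of once per column.

// Y = X M for n x k dense M.
// [[Rcpp::export]]
NumericMatrix cpp_matmat(const RawVector &packed, int m, int n,
                         const IntegerVector &codes, int d, int nseg,
                         const NumericMatrix &M) {
  if (M.nrow() != n) stop("nrow(M) = %d but X has %d columns", M.nrow(), n);
  const int k = M.ncol();
  const int bpr = (n + 3) / 4;
  NumericMatrix out(m, k);
  const unsigned char *p = RAW(packed);
  int pd = 1;
  for (int r = 0; r < d; ++r) pd *= 3;
  // transpose M so the k values per sample are contiguous
  std::vector<double> Mt((R_xlen_t)n * k);
  for (int l = 0; l < k; ++l)
    for (int j = 0; j < n; ++j) Mt[(R_xlen_t)j * k + l] = M(j, l);
  std::vector<double> z(nseg > 0 ? (R_xlen_t)pd * k : 0);
  std::vector<double> acc(2 * k);
  const int *c = nseg > 0 ? INTEGER(codes) : nullptr;
  for (int s = 0; s < nseg; ++s) {
    std::fill(z.begin(), z.end(), 0.0);
    const int *cs = c + (R_xlen_t)s * n;
    for (int j = 0; j < n; ++j) {
      double *zj = &z[(R_xlen_t)cs[j] * k];
      const double *mj = &Mt[(R_xlen_t)j * k];
      for (int l = 0; l < k; ++l) zj[l] += mj[l];
    }
    int len = pd / 3;
    for (int r = d - 1; r >= 0; --r) {
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int i = 0; i < len; ++i) {
        double *z0 = &z[(R_xlen_t)i * k];
        const double *z1 = &z[(R_xlen_t)(len + i) * k];
        const double *z2 = &z[(R_xlen_t)(2 * len + i) * k];
        for (int l = 0; l < k; ++l) {
          acc[l] += z1[l];
          acc[k + l] += z2[l];
          z0[l] += z1[l] + z2[l];
        }
      }
      const int row = s * d + r;
      for (int l = 0; l < k; ++l) out(row, l) = acc[l] + 2.0 * acc[k + l];
      len /= 3;
    }
  }
  for (int i = nseg * d; i < m; ++i) {
    const unsigned char *row = p + (R_xlen_t)i * bpr;
    std::fill(acc.begin(), acc.begin() + k, 0.0);
    for (int j = 0; j < n; ++j) {
      int g = get2(row, j);
      if (g) {
        const double *mj = &Mt[(R_xlen_t)j * k];
        for (int l = 0; l < k; ++l) acc[l] += g * mj[l];
      }
    }
    for (int l = 0; l < k; ++l) out(i, l) = acc[l];
  }
  return out;
}

// Y = X' W for m x k dense W.
// [[Rcpp::export]]
NumericMatrix cpp_rmatmat(const RawVector &packed, int m, int n,
                          const IntegerVector &codes, int d, int nseg,
                          const NumericMatrix &W) {
  if (W.nrow() != m) stop("nrow(W) = %d but X has %d rows", W.nrow(), m);
  const int k = W.ncol();
  const int bpr = (n + 3) / 4;
  const unsigned char *p = RAW(packed);
  int pd = 1;
  for (int r = 0; r < d; ++r) pd *= 3;
  std::vector<double> outT((R_xlen_t)n * k, 0.0);
  std::vector<double> S(nseg > 0 ? (R_xlen_t)pd * k : 0);
  const int *c = nseg > 0 ? INTEGER(codes) : nullptr;
  for (int s = 0; s < nseg; ++s) {
    std::fill(S.begin(), S.begin() + k, 0.0);
    R_xlen_t len = 1;
    for (int r = 0; r < d; ++r) {
      const int row = s * d + r;
      for (R_xlen_t i = 0; i < len; ++i) {
        const double *Si = &S[i * k];
        double *S1 = &S[(len + i) * k];
        double *S2 = &S[(2 * len + i) * k];
        for (int l = 0; l < k; ++l) {
          double wr = W(row, l);
          S1[l] = Si[l] + wr;
          S2[l] = Si[l] + 2.0 * wr;
        }
      }
      len *= 3;
    }
    const int *cs = c + (R_xlen_t)s * n;
    for (int j = 0; j < n; ++j) {
      const double *Sj = &S[(R_xlen_t)cs[j] * k];
      double *oj = &outT[(R_xlen_t)j * k];
      for (int l = 0; l < k; ++l) oj[l] += Sj[l];
    }
  }
  for (int i = nseg * d; i < m; ++i) {
    const unsigned char *row = p + (R_xlen_t)i * bpr;
    for (int j = 0; j < n; ++j) {
      int g = get2(row, j);
      if (g) {
        double *oj = &outT[(R_xlen_t)j * k];
        for (int l = 0; l < k; ++l) oj[l] += g * W(i, l);
      }
    }
  }
  NumericMatrix out(n, k);
  for (int j = 0; j < n; ++j)
    for (int l = 0; l < k; ++l) out(j, l) = outT[(R_xlen_t)j * k + l];
  return out;
}

// ---------------------------------------------------------------------------
// Euclidean projection onto the probability simplex, one column at a time
// (sort-based algorithm).
// ---------------------------------------------------------------------------

static void project_simplex_one(const double *y, double *out, int k,
                                std::vector<double> &buf) {
  buf.assign(y, y + k);
  std::sort(buf.begin(), buf.end(), std::greater<double>());
  double css = 0.0, tau = 0.0;
  int rho = 0;
  for (int i = 0; i < k; ++i) {
    css += buf[i];
    double t = (css - 1.0) / (i + 1);
    if (buf[i] - t > 0) { rho = i + 1; tau = t; }
  }
  for (int i = 0; i < k; ++i) {
    double v = y[i] - tau;
    out[i] = v > 0 ? v : 0.0;
  }
  (void)rho;
}

// [[Rcpp::export]]
NumericMatrix cpp_project_simplex_cols(const NumericMatrix &Y) {
  const int k = Y.nrow(), n = Y.ncol();
  NumericMatrix out(k, n);
  std::vector<double> buf(k);
  for (int j = 0; j < n; ++j)
    project_simplex_one(&Y(0, j), &out(0, j), k, buf);
  return out;
}

// ---------------------------------------------------------------------------
// Exact linear assignment (Hungarian algorithm with potentials, O(k^3)).
// Returns, for each row of the square cost matrix, the 1-based column it is
// assigned to in a minimum-total-cost perfect matching.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_solve_assignment(const NumericMatrix &cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector assign(n);
  for (int j = 1; j <= n; ++j) assign[p[j] - 1] = j;
  return assign;
}
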