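// Bit-plane genotype encoding and the pooled-within-cell-variance screening
// F test for two-locus interaction, computed from 9-cell summaries obtained
// by ANDing bit planes (popcount for counts, set-bit iteration for trait
// sums). One genotype occupies one bit in each of four planes per SNP:
// class 0, class 1, class 2 and a called mask.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int popcnt64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

static inline int ctz64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_ctzll(x);
#else
  int c = 0; while (!(x & 1)) { x >>= 1; ++c; } return c;
#endif
}

// words per plane
static inline R_xlen_t nwords(int nSamples) { return (nSamples + 63) / 64; }

// [[Rcpp::export(name = ".cpp_bit_encode")]]
RawVector cpp_bit_encode(IntegerMatrix g) {
  const int n = g.nrow(), m = g.ncol();
  const R_xlen_t nw = nwords(n);
  RawVector out(nw * 8 * 4 * (R_xlen_t)m);
  uint64_t* w = (uint64_t*)RAW(out);
  std::memset(w, 0, nw * 8 * 4 * (size_t)m);
  for (int j = 0; j < m; ++j) {
    uint64_t* base = w + (R_xlen_t)j * 4 * nw;
    for (int i = 0; i < n; ++i) {
      int v = g(i, j);
      if (v == NA_INTEGER) continue;
      if (v < 0 || v > 2) stop("genotypes must be 0/1/2/NA");
      base[(R_xlen_t)v * nw + (i >> 6)] |= (uint64_t)1 << (i & 63);
      base[(R_xlen_t)3 * nw + (i >> 6)] |= (uint64_t)1 << (i & 63);
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_bit_decode")]]
IntegerMatrix cpp_bit_decode(RawVector bits, int nSamples, int nSnps) {
  const R_xlen_t nw = nwords(nSamples);
  if ((R_xlen_t)bits.size() != nw * 8 * 4 * (R_xlen_t)nSnps)
    stop("bit buffer has unexpected length");
  const uint64_t* w = (const uint64_t*)RAW(bits);
  IntegerMatrix g(nSamples, nSnps);
  for (int j = 0; j < nSnps; ++j) {
    const uint64_t* base = w + (R_xlen_t)j * 4 * nw;
    for (int i = 0; i < nSamples; ++i) {
      uint64_t mask = (uint64_t)1 << (i & 63);
      R_xlen_t wd = i >> 6;
      if (!(base[3 * nw + wd] & mask)) { g(i, j) = NA_INTEGER; continue; }
      if (base[0 * nw + wd] & mask) g(i, j) = 0;
      else if (base[1 * nw + wd] & mask) g(i, j) = 1;
      else g(i, j) = 2;
    }
  }
  return g;
}

// [[Rcpp::export(name = ".cpp_plane_counts")]]
IntegerMatrix cpp_plane_counts(RawVector bits, int nSamples, int nSnps) {
  const R_xlen_t nw = nwords(nSamples);
  const uint64_t* w = (const uint64_t*)RAW(bits);
  IntegerMatrix out(4, nSnps);
  for (int j = 0; j < nSnps; ++j) {
    const uint64_t* base = w + (R_xlen_t)j * 4 * nw;
    for (int k = 0; k < 4; ++k) {
      int c = 0;
      for (R_xlen_t t = 0; t < nw; ++t) c += popcnt64(base[k * nw + t]);
      out(k, j) = c;
    }
  }
  return out;
}

// 9-cell summaries for one SNP pair over pairwise-complete samples.
static void pair_summaries(const uint64_t* w, R_xlen_t nw,
                           int i1, int i2, const double* y,
                           double* S, double* Q, int* N) {
  const uint64_t* a = w + (R_xlen_t)i1 * 4 * nw;
  const uint64_t* b = w + (R_xlen_t)i2 * 4 * nw;
  for (int ci = 0; ci < 3; ++ci) {
    for (int cj = 0; cj < 3; ++cj) {
      int cell = ci * 3 + cj;
      double s = 0, q = 0; int n = 0;
      for (R_xlen_t t = 0; t < nw; ++t) {
        uint64_t x = a[ci * nw + t] & b[cj * nw + t];
        n += popcnt64(x);
        while (x) {
          int bit = ctz64(x);
          double v = y[(t << 6) + bit];
          s += v; q += v * v;
          x &= x - 1;
        }
      }
      S[cell] = s; Q[cell] = q; N[cell] = n;
    }
  }
}

// Weighted least-squares "explained SS" of the two-locus main-effect model
// (intercept + additive + dominance per locus, 5 columns) fitted to the 9
// cell means with cell-count weights. Returns explained SS above the grand
// mean; sets rank.
static double main_effect_ss(const double* S, const int* N, int& rank) {
  double A[5][5] = {{0}}, bvec[5] = {0};
  double tot = 0; long ntot = 0;
  for (int ci = 0; ci < 3; ++ci) for (int cj = 0; cj < 3; ++cj) {
    int cell = ci * 3 + cj;
    if (!N[cell]) continue;
    double x[5] = {1.0, (double)ci, ci == 1 ? 1.0 : 0.0,
                   (double)cj, cj == 1 ? 1.0 : 0.0};
    for (int r = 0; r < 5; ++r) {
      bvec[r] += x[r] * S[cell];
      for (int c = 0; c < 5; ++c) A[r][c] += (double)N[cell] * x[r] * x[c];
    }
    tot += S[cell]; ntot += N[cell];
  }
  // Gauss-Jordan with full pivoting; rank from pivot tolerance.
  int colperm[5] = {0, 1, 2, 3, 4};
  double beta[5] = {0};
  double maxdiag = 0;
  for (int r = 0; r < 5; ++r) if (A[r][r] > maxdiag) maxdiag = A[r][r];
  double tol = 1e-10 * (maxdiag > 0 ? maxdiag : 1.0);
  int r = 0;
  for (; r < 5; ++r) {
    // find pivot in submatrix
    int pr = -1, pc = -1; double pv = tol;
    for (int i = r; i < 5; ++i) for (int j = r; j < 5; ++j)
      if (std::abs(A[i][j]) > pv) { pv = std::abs(A[i][j]); pr = i; pc = j; }
    if (pr < 0) break;
    // swap rows pr<->r in A and b
    for (int j = 0; j < 5; ++j) std::swap(A[pr][j], A[r][j]);
    std::swap(bvec[pr], bvec[r]);
    // swap cols pc<->r in A and record permutation
    for (int i = 0; i < 5; ++i) std::swap(A[i][pc], A[i][r]);
    std::swap(colperm[pc], colperm[r]);
    double piv = A[r][r];
    for (int i = 0; i < 5; ++i) {
      if (i == r) continue;
      double f = A[i][r] / piv;
      if (f == 0) continue;
      for (int j = r; j < 5; ++j) A[i][j] -= f * A[r][j];
      bvec[i] -= f * bvec[r];
    }
  }
  rank = r;
  for (int i = 0; i < r; ++i) beta[i] = bvec[i] / A[i][i];
  // explained SS = beta' b (in permuted coords b was transformed; recompute
  // via the solved system: after elimination bvec[i]/A[i][i] are the pivot
  // solutions and non-pivot coords are 0, so beta' (original b) needs the
  // original b. Rebuild original b contribution:
  // Easier: explained SS = sum_cells n_c * (fit_c)^2 ... compute fits.
  double betaOrig[5] = {0};
  for (int i = 0; i < r; ++i) betaOrig[colperm[i]] = beta[i];
  double ss = 0;
  for (int ci = 0; ci < 3; ++ci) for (int cj = 0; cj < 3; ++cj) {
    int cell = ci * 3 + cj;
    if (!N[cell]) continue;
    double x[5] = {1.0, (double)ci, ci == 1 ? 1.0 : 0.0,
                   (double)cj, cj == 1 ? 1.0 : 0.0};
    double fit = 0;
    for (int k = 0; k < 5; ++k) fit += x[k] * betaOrig[k];
    ss += (double)N[cell] * fit * fit;
  }
  double grand = (ntot > 0) ? tot * tot / (double)ntot : 0;
  return ss - grand;
}

// [[Rcpp::export(name = ".cpp_pair_cells")]]
List cpp_pair_cells(RawVector bits, int nSamples, int nSnps,
                    int i1, int i2, NumericVector y) {
  if (i1 < 1 || i1 > nSnps || i2 < 1 || i2 > nSnps) stop("SNP index out of range");
  if (y.size() != nSamples) stop("trait length mismatch");
  // pad y into a 64-aligned buffer so (word<<6)+bit never reads past the end
  const R_xlen_t nw = nwords(nSamples);
  std::vector<double> yy(nw * 64, 0.0);
  std::copy(y.begin(), y.end(), yy.begin());
  double S[9], Q[9]; int N[9];
  pair_summaries((const uint64_t*)RAW(bits), nw, i1 - 1, i2 - 1, yy.data(),
                 S, Q, N);
  IntegerMatrix counts(3, 3); NumericMatrix sums(3, 3), sumsq(3, 3);
  int ntot = 0;
  for (int ci = 0; ci < 3; ++ci) for (int cj = 0; cj < 3; ++cj) {
    counts(ci, cj) = N[ci * 3 + cj];
    sums(ci, cj) = S[ci * 3 + cj];
    sumsq(ci, cj) = Q[ci * 3 + cj];
    ntot += N[ci * 3 + cj];
  }
  return List::create(_["counts"] = counts, _["sums"] = sums,
                      _["sumsq"] = sumsq, _["n"] = ntot);
}

// [[Rcpp::export(name = ".cpp_pair_screen")]]
DataFrame cpp_pair_screen(RawVector bits, int nSamples, int nSnps,
                          IntegerVector idx1, IntegerVector idx2,
                          NumericVector y) {
  if (idx1.size() != idx2.size()) stop("index vectors differ in length");
  if (y.size() != nSamples) stop("trait length mismatch");
  const R_xlen_t nw = nwords(nSamples);
  std::vector<double> yy(nw * 64, 0.0);
  std::copy(y.begin(), y.end(), yy.begin());
  const uint64_t* w = (const uint64_t*)RAW(bits);
  R_xlen_t np = idx1.size();
  NumericVector Fv(np), df1v(np), df2v(np);
  IntegerVector nv(np);
  double S[9], Q[9]; int N[9];
  for (R_xlen_t k = 0; k < np; ++k) {
    int i1 = idx1[k], i2 = idx2[k];
    if (i1 < 1 || i1 > nSnps || i2 < 1 || i2 > nSnps)
      stop("SNP index out of range");
    pair_summaries(w, nw, i1 - 1, i2 - 1, yy.data(), S, Q, N);
    double tot = 0, totq = 0, cellExpl = 0; long n = 0; int cells = 0;
    for (int c = 0; c < 9; ++c) {
      if (!N[c]) continue;
      tot += S[c]; totq += Q[c]; n += N[c]; ++cells;
      cellExpl += S[c] * S[c] / (double)N[c];
    }
    nv[k] = (int)n;
    if (n < 2 || cells < 2) {
      Fv[k] = NA_REAL; df1v[k] = NA_REAL; df2v[k] = NA_REAL; continue;
    }
    double grand = tot * tot / (double)n;
    double ssWithin = totq - cellExpl;       // residual around cell means
    cellExpl -= grand;                        // cells model above grand mean
    int rank = 0;
    double mainExpl = main_effect_ss(S, N, rank);
    int df1 = cells - rank;
    long df2 = n - cells;
    if (df1 <= 0 || df2 <= 0) {
      Fv[k] = NA_REAL; df1v[k] = df1; df2v[k] = (double)df2; continue;
    }
    double num = (cellExpl - mainExpl) / df1;
    double den = ssWithin / (double)df2;
    double F;
    if (den <= 0) {
      F = (num <= 1e-12 * (std::abs(grand) + 1)) ? 0.0 : R_PosInf;
    } else {
      F = num / den;
      if (F < 0) F = 0;  // numerical underflow of nested SS difference
    }
    Fv[k] = F; df1v[k] = df1; df2v[k] = (double)df2;
  }
  return DataFrame::create(_["idx1"] = idx1, _["idx2"] = idx2, _["n"] = nv,
                           _["df1"] = df1v, _["df2"] = df2v, _["F"] = Fv);
}
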