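#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Bit-packed genotype storage: one class (controls or cases) is an integer
// matrix with 3*W rows and N columns, W = ceil(n_samples/32).  Column `loc`
// holds three W-word bit-vectors, one per genotype code 0/1/2; bit s of
// vector g is set iff sample s has genotype g at locus `loc`.  Contingency
// cells are then word-wise AND chains followed by popcounts.

static inline int popcnt32(uint32_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcount(x);
#else
  x = x - ((x >> 1) & 0x55555555u);
  x = (x & 0x33333333u) + ((x >> 2) & 0x33333333u);
  x = (x + (x >> 4)) & 0x0F0F0F0Fu;
  return (int)((x * 0x01010101u) >> 24);
#endif
}

// [[Rcpp::export]]
IntegerMatrix pack_genotype_masks(const IntegerMatrix& geno) {
  const int S = geno.nrow(), N = geno.ncol();
  const int W = (S + 31) / 32;
  IntegerMatrix out(3 * W, N);
  uint32_t* o = reinterpret_cast<uint32_t*>(INTEGER(out));
  const int* g = INTEGER(geno);
  for (int loc = 0; loc < N; ++loc) {
    uint32_t* col = o + (size_t)loc * 3 * W;
    const int* gc = g + (size_t)loc * S;
    for (int s = 0; s < S; ++s) {
      int code = gc[s];
      if (code < 0 || code > 2)
        stop("genotype code out of range {0,1,2} at sample %d, locus %d",
             s + 1, loc + 1);
      col[code * W + (s >> 5)] |= (1u << (s & 31));
    }
  }
  return out;
}

struct MaskView {
  const uint32_t* base;  // 3*W x N, column-major
  int W;
  const uint32_t* locus(int loc, int g) const {
    return base + (size_t)loc * 3 * W + (size_t)g * W;
  }
};

static inline MaskView view(const IntegerMatrix& m) {
  MaskView v;
  v.base = reinterpret_cast<const uint32_t*>(INTEGER(m));
  v.W = m.nrow() / 3;
  return v;
}

// Recursively enumerate the 3^L genotype configurations of `combo`
// (combo[0] varies fastest in the emitted cell order), carrying AND
// accumulators for both classes; calls `leaf(m0, m1)` per cell.
template <typename Leaf>
static void enumerate_cells(const MaskView& a, const MaskView& b,
                            const int* combo, int L, int depth,
                            const uint32_t* accA, const uint32_t* accB,
                            std::vector<uint32_t>& scratch, Leaf&& leaf) {
  const int loc = combo[L - 1 - depth];  // last locus outermost
  uint32_t* bufA = scratch.data() + (size_t)depth * (a.W + b.W);
  uint32_t* bufB = bufA + a.W;
  for (int g = 0; g < 3; ++g) {
    const uint32_t* mA = a.locus(loc, g);
    const uint32_t* mB = b.locus(loc, g);
    const uint32_t *curA, *curB;
    if (depth == 0) {
      curA = mA;
      curB = mB;
    } else {
      for (int w = 0; w < a.W; ++w) bufA[w] = accA[w] & mA[w];
      for (int w = 0; w < b.W; ++w) bufB[w] = accB[w] & mB[w];
      curA = bufA;
      curB = bufB;
    }
    if (depth == L - 1) {
      int m0 = 0, m1 = 0;
      for (int w = 0; w < a.W; ++w) m0 += popcnt32(curA[w]);
      for (int w = 0; w < b.W; ++w) m1 += popcnt32(curB[w]);
      leaf(m0, m1);
    } else {
      enumerate_cells(a, b, combo, L, depth + 1, curA, curB, scratch, leaf);
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix contingency_counts(const IntegerMatrix& ctrl_masks,
                                 const IntegerMatrix& case_masks,
                                 const IntegerVector& combo0) {
  const int L = combo0.size();
  std::vector<int> combo(combo0.begin(), combo0.end());
  MaskView a = view(ctrl_masks), b = view(case_masks);
  int ncell = 1;
  for (int i = 0; i < L; ++i) ncell *= 3;
  IntegerMatrix out(ncell, 2);
  std::vector<uint32_t> scratch((size_t)L * (a.W + b.W));
  int pos = 0;
  enumerate_cells(a, b, combo.data(), L, 0, nullptr, nullptr, scratch,
                  [&](int m0, int m1) {
                    out(pos, 0) = m0;
                    out(pos, 1) = m1;
                    ++pos;
                  });
  return out;
}

// Negative-log K2: sum over cells of ln((m0+m1+1)!) - ln(m0!) - ln(m1!).
// lnfact[i] = ln(i!) (0-based), precomputed once per dataset.
static double k2_combo(const MaskView& a, const MaskView& b, const int* combo,
                       int L, const double* lnfact,
                       std::vector<uint32_t>& scratch) {
  double k2 = 0.0;
  enumerate_cells(a, b, combo, L, 0, nullptr, nullptr, scratch,
                  [&](int m0, int m1) {
                    k2 += lnfact[m0 + m1 + 1] - lnfact[m0] - lnfact[m1];
                  });
  return k2;
}

// [[Rcpp::export]]
double k2_from_masks(const IntegerMatrix& ctrl_masks,
                     const IntegerMatrix& case_masks,
                     const NumericVector& lnfact, const IntegerVector& combo0) {
  const int L = combo0.size();
  std::vector<int> combo(combo0.begin(), combo0.end());
  MaskView a = view(ctrl_masks), b = view(case_masks);
  std::vector<uint32_t> scratch((size_t)L * (a.W + b.W));
  return k2_combo(a, b, combo.data(), L, REAL(lnfact), scratch);
}

// Greedy first-improvement pruning: repeatedly delete the first SNP whose
// removal strictly lowers the K2 score, restarting the scan after each
// accepted deletion; stop at a local minimum or when one SNP remains.
// [[Rcpp::export]]
List prune_k2_cpp(const IntegerMatrix& ctrl_masks,
                  const IntegerMatrix& case_masks, const NumericVector& lnfact,
                  const IntegerVector& combo0) {
  std::vector<int> x(combo0.begin(), combo0.end());
  int l = (int)x.size();
  MaskView a = view(ctrl_masks), b = view(case_masks);
  std::vector<uint32_t> scratch((size_t)l * (a.W + b.W));
  const double* lf = REAL(lnfact);
  double k2x = k2_combo(a, b, x.data(), l, lf, scratch);
  const double k2_initial = k2x;
  std::vector<int> xx;
  while (l > 1) {
    bool found = false;
    for (int i = 0; i < l; ++i) {
      xx.clear();
      for (int j = 0; j < l; ++j)
        if (j != i) xx.push_back(x[j]);
      double k2xx = k2_combo(a, b, xx.data(), l - 1, lf, scratch);
      if (k2xx < k2x) {
        x = xx;
        k2x = k2xx;
        --l;
        found = true;
        break;
      }
    }
    if (!found) break;
  }
  return List::create(_["snps"] = IntegerVector(x.begin(), x.end()),
                      _["k2"] = k2x, _["k2_initial"] = k2_initial);
}

// Exhaustive scan of all SNP pairs by K2; reference search used by the
// evaluation harness and tests.
// [[Rcpp::export]]
List best_pair_k2(const IntegerMatrix& ctrl_masks,
                  const IntegerMatrix& case_masks,
                  const NumericVector& lnfact) {
  MaskView a = view(ctrl_masks), b = view(case_masks);
  const int N = ctrl_masks.ncol();
  std::vector<uint32_t> scratch(2 * (size_t)(a.W + b.W));
  const double* lf = REAL(lnfact);
  double best = R_PosInf;
  int bi = -1, bj = -1;
  int combo[2];
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      combo[0] = i;
      combo[1] = j;
      double v = k2_combo(a, b, combo, 2, lf, scratch);
      if (v < best) {
        best = v;
        bi = i;
        bj = j;
      }
    }
  }
  return List::create(_["pair"] = IntegerVector::create(bi, bj),
                      _["k2"] = best);
}
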