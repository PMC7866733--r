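// Index core: suffix array (prefix doubling), Kasai LCP, sparse-table RMQ,
// constant-time literal LCE, kangaroo walks with a mismatch budget, and the
// gap-swallowing per-centre inverted-repeat enumeration.
//
// Conventions in this file: all positions are 0-based. The indexed text is
// X . s1 . rc(X) . s2 where X is the IUPAC code sequence (codes 1..15,
// alphabetical A,B,C,D,G,H,K,M,N,R,S,T,V,W,Y), rc(X)[i] is the simple
// (unique-symbol) complement of X[n-1-i], and the sentinels s1 = -1, s2 = -2
// are distinct and smaller than every alphabet code. Literal equality on this
// text under-approximates both matching schemes (a symbol equal to the simple
// complement of its partner always scheme-matches it), so every literal LCE
// stop is adjudicated against the active 15x15 match matrix: a degenerate
// match continues the walk for free, anything else is a true mismatch.

#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <vector>
using namespace Rcpp;

static std::vector<int> sa_doubling(const int* t, int N) {
  std::vector<int> sa(N), rnk(N), tmp(N);
  for (int i = 0; i < N; ++i) { sa[i] = i; rnk[i] = t[i]; }
  for (int len = 1;; len <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
      int ra = a + len < N ? rnk[a + len] : INT_MIN;
      int rb = b + len < N ? rnk[b + len] : INT_MIN;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < N; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rnk.swap(tmp);
    if (rnk[sa[N - 1]] == N - 1) break;
  }
  return sa;
}

static std::vector<int> lcp_kasai(const int* t, int N, const std::vector<int>& sa,
                                  const std::vector<int>& inv) {
  std::vector<int> lcp(N, 0);
  int h = 0;
  for (int i = 0; i < N; ++i) {
    if (inv[i] > 0) {
      int j = sa[inv[i] - 1];
      while (i + h < N && j + h < N && t[i + h] == t[j + h]) ++h;
      lcp[inv[i]] = h;
      if (h) --h;
    } else {
      h = 0;
    }
  }
  return lcp;
}

// [[Rcpp::export]]
List cpp_build_index(IntegerVector text) {
  int N = text.size();
  if (N < 1) stop("empty text");
  const int* t = INTEGER(text);
  std::vector<int> sa = sa_doubling(t, N);
  std::vector<int> inv(N);
  for (int r = 0; r < N; ++r) inv[sa[r]] = r;
  std::vector<int> lcp = lcp_kasai(t, N, sa, inv);

  std::vector<int> logt(N + 1, 0);
  for (int i = 2; i <= N; ++i) logt[i] = logt[i / 2] + 1;
  int levels = logt[N] + 1;
  IntegerVector sp(static_cast<R_xlen_t>(levels) * N);
  int* spp = INTEGER(sp);
  for (int i = 0; i < N; ++i) spp[i] = lcp[i];
  for (int k = 1; k < levels; ++k) {
    int half = 1 << (k - 1);
    for (int i = 0; i + (1 << k) <= N; ++i)
      spp[(R_xlen_t)k * N + i] =
          std::min(spp[(R_xlen_t)(k - 1) * N + i], spp[(R_xlen_t)(k - 1) * N + i + half]);
  }
  return List::create(_["sa"] = IntegerVector(sa.begin(), sa.end()),
                      _["inv"] = IntegerVector(inv.begin(), inv.end()),
                      _["lcp"] = IntegerVector(lcp.begin(), lcp.end()),
                      _["sp"] = sp,
                      _["logt"] = IntegerVector(logt.begin(), logt.end()),
                      _["levels"] = levels);
}

struct Ctx {
  const int* text;
  int N;          // full text length (2n + 2)
  int n;          // sequence length
  const int* inv;
  const int* sp;  // sparse table, levels x N row-major by level
  const int* logt;
  const int* mat; // 15x15 row-major match matrix (0/1)
};

static inline int ctx_lce(const Ctx& C, int i, int j) {
  if (i == j) return C.N - i;
  int ri = C.inv[i], rj = C.inv[j];
  if (ri > rj) std::swap(ri, rj);
  int l = ri + 1, r = rj;
  int k = C.logt[r - l + 1];
  return std::min(C.sp[(R_xlen_t)k * C.N + l],
                  C.sp[(R_xlen_t)k * C.N + r - (1 << k) + 1]);
}

static inline bool ctx_match(const Ctx& C, int a, int b) {
  return C.mat[(a - 1) * 15 + (b - 1)] != 0;
}

// Incremental kangaroo walk between X position f (moving right) and rc(X)
// position q (moving right), i.e. outward pair t compares X[f+t] with the
// symbol underlying rc(X)[q+t], namely X[n-1-q-t]. Mismatch offsets are
// produced one at a time so callers only pay for what they need.
struct Walk {
  const Ctx* C;
  int f, q, limit, t;
  bool done;
  std::vector<int> mism;

  void init(const Ctx& Cc, int f_, int q_, int cap) {
    C = &Cc; f = f_; q = q_; t = 0; done = false;
    limit = std::min(Cc.n - f_, Cc.n - q_);
    if (cap >= 0 && cap < limit) limit = cap;
    if (limit <= 0) { limit = limit < 0 ? 0 : limit; done = true; }
    mism.clear();
  }
  // advance until the next true mismatch is recorded or the walk ends
  void step() {
    while (t < limit) {
      int l = ctx_lce(*C, f + t, C->n + 1 + q + t);
      t += l;
      if (t >= limit) { t = limit; break; }
      int a = C->text[f + t];              // X-side symbol
      int b = C->text[C->n - 1 - q - t];   // symbol underlying the rc side
      if (ctx_match(*C, a, b)) { ++t; continue; }
      mism.push_back(t);
      ++t;
      return;
    }
    done = true;
  }
  bool ensure(size_t need) {
    while (mism.size() < need && !done) step();
    return mism.size() >= need;
  }
};

static Ctx make_ctx(IntegerVector text, int n, IntegerVector inv, IntegerVector sp,
                    IntegerVector logt, IntegerVector mat) {
  if (mat.size() != 225) stop("match matrix must be 15x15");
  Ctx C;
  C.text = INTEGER(text); C.N = text.size(); C.n = n;
  C.inv = INTEGER(inv); C.sp = INTEGER(sp); C.logt = INTEGER(logt);
  C.mat = INTEGER(mat);
  return C;
}

// [[Rcpp::export]]
int cpp_lce(IntegerVector text, IntegerVector inv, IntegerVector sp,
            IntegerVector logt, int i, int j) {
  int N = text.size();
  if (i < 0 || j < 0 || i >= N || j >= N) stop("text position out of range");
  Ctx C; C.text = INTEGER(text); C.N = N; C.n = 0;
  C.inv = INTEGER(inv); C.sp = INTEGER(sp); C.logt = INTEGER(logt); C.mat = 0;
  return ctx_lce(C, i, j);
}

// [[Rcpp::export]]
List cpp_kangaroo(IntegerVector text, int n, IntegerVector inv, IntegerVector sp,
                  IntegerVector logt, IntegerVector mat, int fwd_pos, int rc_pos,
                  int budget, int max_pairs) {
  if (fwd_pos < 0 || fwd_pos >= n) stop("fwd_pos outside the forward segment");
  if (rc_pos < 0 || rc_pos >= n) stop("rc_pos outside the reverse-complement segment");
  if (budget < 0) stop("budget must be >= 0");
  Ctx C = make_ctx(text, n, inv, sp, logt, mat);
  Walk W;
  W.init(C, fwd_pos, rc_pos, max_pairs);
  // walk until the (budget+1)-th true mismatch or the end
  while (!W.done && (int)W.mism.size() <= budget) W.step();
  int matched;
  if ((int)W.mism.size() > budget) matched = W.mism.back();
  else matched = W.t;
  return List::create(_["matched_length"] = matched,
                      _["mismatch_offsets"] = IntegerVector(W.mism.begin(), W.mism.end()));
}

// centre geometry: twice_centre tc in 0..2n-2; even tc sits on a symbol
// (one unpaired central symbol => odd gaps), odd tc sits between symbols
// (even gaps). Innermost pair (l0, r0), pair t = (l0-t, r0+t).
static inline bool centre_geom(int tc, int n, int& l0, int& r0, int& par) {
  if (tc % 2 == 0) { l0 = tc / 2 - 1; r0 = tc / 2 + 1; par = 1; }
  else             { l0 = (tc - 1) / 2; r0 = (tc + 1) / 2; par = 0; }
  return l0 >= 0 && r0 <= n - 1;
}

// Gap-swallowing enumeration at one centre. For j = 0,1,2,... the innermost
// retained pair s_j excludes the first j true mismatches (s_0 = 0,
// s_j = mism[j-1]+1); the implied gap is 2*s_j + parity. The arm extends
// outward to just inside the (k+1)-th remaining mismatch, the max-arm cap or
// the boundary, then is trimmed inward to the nearest matching outermost pair.
static void emit_centre(const Ctx& C, int tc, int m, int M, int g, int k,
                        std::vector<int>& out) {
  int l0, r0, par;
  if (!centre_geom(tc, C.n, l0, r0, par)) return;
  Walk W;
  W.init(C, r0, C.n - 1 - l0, -1);
  if (W.limit <= 0) return;
  for (int j = 0;; ++j) {
    int s;
    if (j == 0) s = 0;
    else {
      if (!W.ensure(j)) break;
      s = W.mism[j - 1] + 1;
    }
    int gap = 2 * s + par;
    if (gap > g) break;
    if (s >= W.limit) break;
    W.ensure((size_t)j + k + 1);
    int e;
    if ((int)W.mism.size() >= j + k + 1) e = W.mism[j + k] - 1;
    else e = W.limit - 1;
    if (e > s + M - 1) e = s + M - 1;
    while (e >= s && std::binary_search(W.mism.begin(), W.mism.end(), e)) --e;
    int L = e - s + 1;
    if (L >= m) {
      int nm = (int)(std::upper_bound(W.mism.begin(), W.mism.end(), e) -
                     std::lower_bound(W.mism.begin(), W.mism.end(), s));
      out.push_back(l0 - e);       // ls
      out.push_back(l0 - s + 1);   // le (half-open)
      out.push_back(r0 + s);       // rs
      out.push_back(r0 + e + 1);   // re (half-open)
      out.push_back(nm);
    }
  }
}

static IntegerMatrix pack_irs(const std::vector<int>& out) {
  int nr = (int)(out.size() / 5);
  IntegerMatrix res(nr, 5);
  for (int i = 0; i < nr; ++i)
    for (int c = 0; c < 5; ++c) res(i, c) = out[(size_t)i * 5 + c];
  colnames(res) = CharacterVector::create("ls", "le", "rs", "re", "mismatches");
  return res;
}

// [[Rcpp::export]]
IntegerMatrix cpp_enumerate_centre(IntegerVector text, int n, IntegerVector inv,
                                   IntegerVector sp, IntegerVector logt,
                                   IntegerVector mat, int tc, int m, int M, int g,
                                   int k) {
  if (tc < 0 || tc > 2 * n - 2) stop("centre out of range");
  Ctx C = make_ctx(text, n, inv, sp, logt, mat);
  std::vector<int> out;
  emit_centre(C, tc, m, M, g, k, out);
  return pack_irs(out);
}

// [[Rcpp::export]]
IntegerVector cpp_centre_mismatches(IntegerVector text, int n, IntegerVector inv,
                                    IntegerVector sp, IntegerVector logt,
                                    IntegerVector mat, int tc, int needed) {
  if (tc < 0 || tc > 2 * n - 2) stop("centre out of range");
  if (needed < 1) stop("needed must be >= 1");
  Ctx C = make_ctx(text, n, inv, sp, logt, mat);
  int l0, r0, par;
  if (!centre_geom(tc, n, l0, r0, par)) return IntegerVector(0);
  Walk W;
  W.init(C, r0, n - 1 - l0, -1);
  W.ensure((size_t)needed);
  int got = std::min((int)W.mism.size(), needed);
  return IntegerVector(W.mism.begin(), W.mism.begin() + got);
}

// [[Rcpp::export]]
IntegerMatrix cpp_search(IntegerVector text, int n, IntegerVector inv,
                         IntegerVector sp, IntegerVector logt, IntegerVector mat,
                         int m, int M, int g, int k) {
  Ctx C = make_ctx(text, n, inv, sp, logt, mat);
  std::vector<int> out;
  for (int tc = 0; tc <= 2 * n - 2; ++tc) emit_centre(C, tc, m, M, g, k, out);
  return pack_irs(out);
}
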