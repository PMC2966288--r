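// Core engines for stem-based motif search.
//
// k-mers travel between R and C++ as flat RawVectors of symbol codes,
// row-major, one byte per position: 0..sigma-1 are alphabet symbols and
// sigma is the wildcard. All coordinates are 0-based.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <map>
#include <unordered_set>
#include <algorithm>
#include <string>

using namespace Rcpp;

typedef uint64_t u64;
typedef int64_t i64;
typedef uint8_t u8;

static inline int ceil_log2(int x) {
  int b = 0;
  while ((1 << b) < x) ++b;
  return b;
}

static double choose_d(int n, int r) {
  if (r < 0 || r > n) return 0.0;
  double v = 1.0;
  for (int i = 0; i < r; ++i) v = v * (n - i) / (i + 1);
  return v;
}

// Visit all r-subsets of {0..n-1} in lexicographic order.
template <typename F>
static void for_each_combination(int n, int r, F f) {
  if (r < 0 || r > n) return;
  std::vector<int> idx(r);
  for (int i = 0; i < r; ++i) idx[i] = i;
  if (r == 0) { f(idx); return; }
  while (true) {
    f(idx);
    int i = r - 1;
    while (i >= 0 && idx[i] == n - r + i) --i;
    if (i < 0) break;
    ++idx[i];
    for (int j = i + 1; j < r; ++j) idx[j] = idx[j - 1] + 1;
  }
}

// ---------------------------------------------------------------------------
// Record matcher: for each query pattern (wildcards allowed, code == sigma),
// accumulate the set of records having at least one window within masked
// Hamming distance d. Exact by construction: a window matches iff the two
// strings agree on some (keptlen - d)-subset of the query's non-wildcard
// positions, which is what the counting-sort rounds enumerate; a direct
// masked scan is used where it is cheaper. Both paths give identical masks.
// ---------------------------------------------------------------------------

struct MatchArgs {
  const u8* Q; int nq;
  const u8* W; int nw;
  const int* wrec;
  int k, d, sigma, N, nb, q;
  // windows grouped by record, plus suffix counts of non-empty records,
  // for the quorum-abort scan path
  const std::vector<std::vector<int>>* by_rec;
  const std::vector<int>* nonempty_after;
};

// Direct masked scan, record by record, with quorum abort: once the records
// still ahead cannot lift the match count to q, the query is abandoned (its
// membership decision is already final; only selected/surviving queries need
// exact masks, and those always run to completion).
static void scan_group(const MatchArgs& A, const std::vector<int>& qidx,
                       const std::vector<int>& kept, std::vector<u64>& mask) {
  const int L0 = (int)kept.size();
  const int bits = ceil_log2(A.sigma);
  const bool packed = (L0 * bits <= 124) && bits > 0;

  std::vector<u64> wpk, qpk;
  u64 low0 = 0, low1 = 0;
  int n0 = 0; // symbols packed into word 0
  if (packed) {
    n0 = std::min(L0, 62 / bits);
    for (int t = 0; t < n0; ++t) low0 |= (1ull << (t * bits));
    for (int t = n0; t < L0; ++t) low1 |= (1ull << ((t - n0) * bits));
    wpk.resize((size_t)A.nw * 2);
    for (int wi = 0; wi < A.nw; ++wi) {
      const u8* wp = A.W + (size_t)wi * A.k;
      u64 c0 = 0, c1 = 0;
      for (int t = 0; t < L0; ++t) {
        if (t < n0) c0 |= ((u64)wp[kept[t]]) << (t * bits);
        else c1 |= ((u64)wp[kept[t]]) << ((t - n0) * bits);
      }
      wpk[(size_t)wi * 2] = c0;
      wpk[(size_t)wi * 2 + 1] = c1;
    }
  }

  for (int qi : qidx) {
    u64* qm = &mask[(size_t)qi * A.nb];
    const u8* qp = A.Q + (size_t)qi * A.k;
    u64 q0 = 0, q1 = 0;
    if (packed) {
      for (int t = 0; t < L0; ++t) {
        if (t < n0) q0 |= ((u64)qp[kept[t]]) << (t * bits);
        else q1 |= ((u64)qp[kept[t]]) << ((t - n0) * bits);
      }
    }
    int matched = 0;
    for (int r = 0; r < A.N; ++r) {
      const std::vector<int>& wlist = (*A.by_rec)[r];
      for (int wi : wlist) {
        int mis;
        if (packed) {
          u64 x = q0 ^ wpk[(size_t)wi * 2];
          u64 y = x;
          for (int b = 1; b < bits; ++b) y |= x >> b;
          mis = __builtin_popcountll(y & low0);
          if (mis <= A.d && low1) {
            x = q1 ^ wpk[(size_t)wi * 2 + 1];
            y = x;
            for (int b = 1; b < bits; ++b) y |= x >> b;
            mis += __builtin_popcountll(y & low1);
          }
        } else {
          const u8* wp = A.W + (size_t)wi * A.k;
          mis = 0;
          for (int t = 0; t < L0; ++t) {
            const int p = kept[t];
            if (qp[p] != wp[p] && ++mis > A.d) break;
          }
        }
        if (mis <= A.d) {
          qm[r >> 6] |= (1ull << (r & 63));
          ++matched;
          break;
        }
      }
      if (matched + (*A.nonempty_after)[r] < A.q) break;
    }
  }
}

// Bit-segment descriptor for extracting a round key from a packed code.
struct Seg { int start; u64 m; int out; };

static void rounds_group(const MatchArgs& A, const std::vector<int>& qidx,
                         const std::vector<int>& kept, std::vector<u64>& mask,
                         const std::vector<u64>& allrec) {
  const int L0 = (int)kept.size();
  const int d = A.d;
  const int keylen = L0 - d;
  const int nb = A.nb;
  const int bits = ceil_log2(A.sigma);
  const bool packed = ((1 << bits) == A.sigma) && (L0 * bits <= 62);
  const size_t S = qidx.size();

  // Pre-gather kept-position symbols (packed codes, or contiguous byte rows).
  std::vector<u64> qcode, wcode;
  std::vector<u8> qsym, wsym;
  if (packed) {
    qcode.resize(S);
    wcode.resize(A.nw);
    for (size_t i = 0; i < S; ++i) {
      const u8* qp = A.Q + (size_t)qidx[i] * A.k;
      u64 c = 0;
      for (int t = 0; t < L0; ++t) c |= ((u64)qp[kept[t]]) << (t * bits);
      qcode[i] = c;
    }
    for (int wi = 0; wi < A.nw; ++wi) {
      const u8* wp = A.W + (size_t)wi * A.k;
      u64 c = 0;
      for (int t = 0; t < L0; ++t) c |= ((u64)wp[kept[t]]) << (t * bits);
      wcode[wi] = c;
    }
  } else {
    qsym.resize(S * L0);
    wsym.resize((size_t)A.nw * L0);
    for (size_t i = 0; i < S; ++i) {
      const u8* qp = A.Q + (size_t)qidx[i] * A.k;
      for (int t = 0; t < L0; ++t) qsym[i * L0 + t] = qp[kept[t]];
    }
    for (int wi = 0; wi < A.nw; ++wi) {
      const u8* wp = A.W + (size_t)wi * A.k;
      for (int t = 0; t < L0; ++t) wsym[(size_t)wi * L0 + t] = wp[kept[t]];
    }
  }

  // Bucket table sized to the key space.
  size_t tabsize = 1;
  if (packed) {
    tabsize = (size_t)1 << (keylen * bits);
  } else {
    for (int t = 0; t < keylen; ++t) tabsize *= (size_t)A.sigma;
  }
  std::vector<u64> table(tabsize * nb, 0);
  std::vector<size_t> touched;
  touched.reserve(A.nw);

  // Active queries: drop a query once its mask equals the attainable union.
  std::vector<int> active(S);
  for (size_t i = 0; i < S; ++i) active[i] = (int)i;
  auto full = [&](int gi) {
    const u64* qm = &mask[(size_t)qidx[gi] * nb];
    for (int b = 0; b < nb; ++b) if (qm[b] != allrec[b]) return false;
    return true;
  };

  std::vector<u64> mult;
  if (!packed) {
    mult.resize(keylen);
    u64 v = 1;
    for (int t = 0; t < keylen; ++t) { mult[t] = v; v *= (u64)A.sigma; }
  }

  for_each_combination(L0, d, [&](const std::vector<int>& rem) {
    if (active.empty()) return;

    // Key extractors for this round.
    std::vector<Seg> segs;   // packed mode
    std::vector<int> keyidx; // byte mode
    if (packed) {
      int prev = 0, out = 0;
      for (int ri = 0; ri <= d; ++ri) {
        const int stop = (ri < d) ? rem[ri] : L0;
        const int len = stop - prev;
        if (len > 0) {
          Seg s;
          s.start = prev * bits;
          s.m = (len * bits == 64) ? ~0ull : ((1ull << (len * bits)) - 1);
          s.out = out;
          segs.push_back(s);
          out += len * bits;
        }
        prev = stop + 1;
      }
    } else {
      keyidx.reserve(keylen);
      int ri = 0;
      for (int t = 0; t < L0; ++t) {
        if (ri < d && rem[ri] == t) { ++ri; continue; }
        keyidx.push_back(t);
      }
    }

    // Clear touched buckets from the previous round.
    for (size_t key : touched) std::memset(&table[key * nb], 0, nb * sizeof(u64));
    touched.clear();

    // Scatter windows.
    if (packed) {
      for (int wi = 0; wi < A.nw; ++wi) {
        const u64 c = wcode[wi];
        u64 key = 0;
        for (const Seg& s : segs) key |= ((c >> s.start) & s.m) << s.out;
        u64* tb = &table[key * nb];
        bool empty = true;
        for (int b = 0; b < nb; ++b) if (tb[b]) { empty = false; break; }
        if (empty) touched.push_back(key);
        const int r = A.wrec[wi];
        tb[r >> 6] |= (1ull << (r & 63));
      }
    } else {
      for (int wi = 0; wi < A.nw; ++wi) {
        const u8* row = &wsym[(size_t)wi * L0];
        u64 key = 0;
        for (int t = 0; t < keylen; ++t) key += (u64)row[keyidx[t]] * mult[t];
        u64* tb = &table[key * nb];
        bool empty = true;
        for (int b = 0; b < nb; ++b) if (tb[b]) { empty = false; break; }
        if (empty) touched.push_back(key);
        const int r = A.wrec[wi];
        tb[r >> 6] |= (1ull << (r & 63));
      }
    }

    // Gather for queries.
    size_t i = 0;
    while (i < active.size()) {
      const int gi = active[i];
      u64 key = 0;
      if (packed) {
        const u64 c = qcode[gi];
        for (const Seg& s : segs) key |= ((c >> s.start) & s.m) << s.out;
      } else {
        const u8* row = &qsym[(size_t)gi * L0];
        for (int t = 0; t < keylen; ++t) key += (u64)row[keyidx[t]] * mult[t];
      }
      const u64* tb = &table[key * nb];
      u64* qm = &mask[(size_t)qidx[gi] * nb];
      for (int b = 0; b < nb; ++b) qm[b] |= tb[b];
      if (full(gi)) {
        active[i] = active.back();
        active.pop_back();
      } else {
        ++i;
      }
    }
  });
}

static void match_core(MatchArgs& A, std::vector<u64>& mask) {
  const int nb = A.nb;
  std::vector<u64> allrec(nb, 0);
  for (int wi = 0; wi < A.nw; ++wi) {
    const int r = A.wrec[wi];
    allrec[r >> 6] |= (1ull << (r & 63));
  }

  std::vector<std::vector<int>> by_rec(A.N);
  for (int wi = 0; wi < A.nw; ++wi) by_rec[A.wrec[wi]].push_back(wi);
  std::vector<int> nonempty_after(A.N, 0);
  for (int r = A.N - 2; r >= 0; --r)
    nonempty_after[r] = nonempty_after[r + 1] + (by_rec[r + 1].empty() ? 0 : 1);
  A.by_rec = &by_rec;
  A.nonempty_after = &nonempty_after;

  // Group queries by wildcard position mask (k <= 64 enforced at R level).
  std::map<u64, std::vector<int>> groups;
  for (int qi = 0; qi < A.nq; ++qi) {
    const u8* qp = A.Q + (size_t)qi * A.k;
    u64 wm = 0;
    for (int p = 0; p < A.k; ++p) if (qp[p] == A.sigma) wm |= (1ull << p);
    groups[wm].push_back(qi);
  }

  for (auto& g : groups) {
    std::vector<int> kept;
    kept.reserve(A.k);
    for (int p = 0; p < A.k; ++p) if (!((g.first >> p) & 1ull)) kept.push_back(p);
    const int L0 = (int)kept.size();

    if (A.d >= L0) {
      // Degenerate: every window matches.
      for (int qi : g.second) {
        u64* qm = &mask[(size_t)qi * nb];
        for (int b = 0; b < nb; ++b) qm[b] |= allrec[b];
      }
      continue;
    }

    const int keylen = L0 - A.d;
    const int bits = ceil_log2(A.sigma);
    const double S = (double)g.second.size();
    const double nrounds = choose_d(L0, A.d);
    double tabsize = 1.0;
    for (int t = 0; t < keylen; ++t) tabsize *= A.sigma;
    const bool packed = ((1 << bits) == A.sigma);
    if (packed) tabsize = std::pow(2.0, keylen * bits);
    const bool rounds_ok = (L0 * bits <= 62 || !packed) &&
                           ((double)keylen * bits <= 62) &&
                           tabsize <= (double)(1 << 24) &&
                           nrounds <= 2e6;
    const double c_rounds = nrounds * (A.nw + S) * (A.d + 2.0);
    // quorum abort makes the scan roughly per-record when q == N
    const double nw_eff = (A.q >= A.N && A.N > 1) ? (2.0 * A.nw / A.N + 64.0)
                                                  : (double)A.nw;
    const double c_scan = S * nw_eff * ((L0 * bits <= 124) ? 6.0 : L0);
    if (rounds_ok && c_rounds <= c_scan) {
      rounds_group(A, g.second, kept, mask, allrec);
    } else {
      scan_group(A, g.second, kept, mask);
    }
  }
}

// [[Rcpp::export]]
List cpp_match_records(RawVector queries, RawVector windows, IntegerVector win_rec,
                       int k, int d, int sigma, int N, int q, bool want_masks) {
  MatchArgs A;
  A.k = k; A.d = d; A.sigma = sigma; A.N = N; A.q = q;
  A.nb = (N + 63) / 64;
  A.nq = (int)(queries.size() / k);
  A.nw = (int)(windows.size() / k);
  A.Q = (const u8*)RAW(queries);
  A.W = (const u8*)RAW(windows);
  std::vector<int> wrec(A.nw);
  for (int i = 0; i < A.nw; ++i) wrec[i] = win_rec[i];
  A.wrec = wrec.data();

  std::vector<u64> mask((size_t)A.nq * A.nb, 0);
  if (A.nw > 0 && A.nq > 0) match_core(A, mask);

  IntegerVector counts(A.nq);
  for (int qi = 0; qi < A.nq; ++qi) {
    int c = 0;
    for (int b = 0; b < A.nb; ++b) {
      u64 v = mask[(size_t)qi * A.nb + b];
      while (v) { v &= v - 1; ++c; }
    }
    counts[qi] = c;
  }

  if (!want_masks) return List::create(_["counts"] = counts);

  List masks(A.nq);
  for (int qi = 0; qi < A.nq; ++qi) {
    std::vector<int> recs;
    for (int r = 0; r < N; ++r)
      if (mask[(size_t)qi * A.nb + (r >> 6)] & (1ull << (r & 63))) recs.push_back(r);
    masks[qi] = IntegerVector(recs.begin(), recs.end());
  }
  return List::create(_["counts"] = counts, _["masks"] = masks);
}

// Row subset of a flat code buffer (idx0 are 0-based row indices).
// [[Rcpp::export]]
RawVector cpp_subset_rows(RawVector x, int k, IntegerVector idx0) {
  RawVector out((R_xlen_t)idx0.size() * k);
  const u8* xp = (const u8*)RAW(x);
  u8* op = (u8*)RAW(out);
  for (R_xlen_t i = 0; i < idx0.size(); ++i)
    std::memcpy(op + i * k, xp + (size_t)idx0[i] * k, k);
  return out;
}

// ---------------------------------------------------------------------------
// Stem generation over k-mer pairs with deduplication.
// ---------------------------------------------------------------------------

struct StemSink {
  // mode 0: bitmap over (sigma+1)^k codes; 1: hash set of codes; 2: hash set
  // of code strings (alphabet/length too large for 63-bit codes).
  int mode;
  std::vector<bool> bitmap;
  std::unordered_set<u64> hs;
  std::unordered_set<std::string> ss;

  void insert_code(i64 c) {
    if (mode == 0) bitmap[(size_t)c] = true; else hs.insert((u64)c);
  }
  void insert_str(const u8* s, int k) { ss.emplace((const char*)s, (size_t)k); }
};

// Allocation-free combination stepper (r <= 48).
struct CombIter {
  int n, r, idx[48];
  bool first;
  void init(int n_, int r_) {
    n = n_; r = r_;
    for (int i = 0; i < r; ++i) idx[i] = i;
    first = true;
  }
  bool next() {
    if (first) { first = false; return r <= n; }
    int i = r - 1;
    while (i >= 0 && idx[i] == n - r + i) --i;
    if (i < 0) return false;
    ++idx[i];
    for (int j = i + 1; j < r; ++j) idx[j] = idx[j - 1] + 1;
    return true;
  }
};

// Unified stem enumeration for one pair. The printed two-branch rule for
// d <= m / d > m is subsumed by these ranges (and the d > m branch alone
// under-covers the intersection); see the package vignette.
//   i  in [max(0, d-m), min(d, m)]   mismatch positions set to b's symbol
//   j1 in [0, d-i]                   wildcards inside the mismatch region
//   j2 in [0, m - max(i+j1, d-i)]    wildcards in the match region
struct PairGen {
  int k, m, sigma;
  const i64* pw;
  StemSink* sink;
  int D[48], Mg[48], rest[48];
  char inB[48];
  CombIter cb, cw1, cw2;

  void gen(const u8* a, const u8* b, i64 codeA) {
    int d = 0, nM = 0;
    for (int p = 0; p < k; ++p) {
      if (a[p] != b[p]) D[d++] = p; else Mg[nM++] = p;
    }
    if (d > 2 * m) return;
    for (int t = 0; t < d; ++t) inB[t] = 0;

    const int ilo = (d - m > 0) ? d - m : 0;
    const int ihi = (d < m) ? d : m;
    for (int i = ilo; i <= ihi; ++i) {
      cb.init(d, i);
      while (cb.next()) {
        i64 dB = 0;
        for (int t = 0; t < i; ++t) {
          const int p = D[cb.idx[t]];
          dB += (i64)(b[p] - a[p]) * pw[p];
          inB[cb.idx[t]] = 1;
        }
        int nr = 0;
        for (int t = 0; t < d; ++t) if (!inB[t]) rest[nr++] = D[t];
        for (int j1 = 0; j1 <= nr; ++j1) {
          const int base1 = (i + j1 > d - i) ? i + j1 : d - i;
          const int jmax = m - base1;
          if (jmax < 0) break;
          cw1.init(nr, j1);
          while (cw1.next()) {
            i64 dW1 = 0;
            for (int t = 0; t < j1; ++t) {
              const int p = rest[cw1.idx[t]];
              dW1 += (i64)(sigma - a[p]) * pw[p];
            }
            const i64 c01 = codeA + dB + dW1;
            for (int j2 = 0; j2 <= jmax; ++j2) {
              cw2.init(nM, j2);
              while (cw2.next()) {
                i64 dW2 = 0;
                for (int t = 0; t < j2; ++t) {
                  const int p = Mg[cw2.idx[t]];
                  dW2 += (i64)(sigma - a[p]) * pw[p];
                }
                sink->insert_code(c01 + dW2);
              }
            }
          }
        }
        for (int t = 0; t < i; ++t) inB[cb.idx[t]] = 0;
      }
    }
  }
};

static void gen_pair_bytes(const u8* a, const u8* b, int k, int m, int sigma,
                           StemSink& sink) {
  std::vector<int> D, Mg;
  for (int p = 0; p < k; ++p) (a[p] != b[p] ? D : Mg).push_back(p);
  const int d = (int)D.size();
  if (d > 2 * m) return;
  const int nM = (int)Mg.size();
  std::vector<u8> stem(a, a + k);

  for (int i = std::max(0, d - m); i <= std::min(d, m); ++i) {
    for_each_combination(d, i, [&](const std::vector<int>& Bi) {
      std::vector<char> inB(d, 0);
      for (int t : Bi) { stem[D[t]] = b[D[t]]; inB[t] = 1; }
      std::vector<int> rest;
      for (int t = 0; t < d; ++t) if (!inB[t]) rest.push_back(D[t]);
      const int nr = (int)rest.size();
      for (int j1 = 0; j1 <= nr; ++j1) {
        const int jmax = m - std::max(i + j1, d - i);
        if (jmax < 0) continue;
        for_each_combination(nr, j1, [&](const std::vector<int>& W1) {
          for (int t : W1) stem[rest[t]] = (u8)sigma;
          for (int j2 = 0; j2 <= jmax; ++j2) {
            for_each_combination(nM, j2, [&](const std::vector<int>& W2) {
              for (int t : W2) stem[Mg[t]] = (u8)sigma;
              sink.insert_str(stem.data(), k);
              for (int t : W2) stem[Mg[t]] = a[Mg[t]];
            });
          }
          for (int t : W1) stem[rest[t]] = a[rest[t]];
        });
      }
      for (int t : Bi) stem[D[t]] = a[D[t]];
    });
  }
}

// Choose a dedup representation for patterns of length k over sigma symbols
// plus a wildcard (base sigma+1 codes).
static int pick_mode(int k, int base, double space_limit_bitmap) {
  double space = 1.0;
  for (int p = 0; p < k; ++p) space *= base;
  if (space <= space_limit_bitmap) return 0;
  if (space <= 9.0e18) return 1;
  return 2;
}

static void sink_to_output(StemSink& sink, int k, int base, RawVector& out,
                           IntegerVector& nwild, int sigma) {
  std::vector<u64> codes;
  std::vector<std::string> strs;
  size_t n = 0;
  if (sink.mode == 0) {
    for (size_t c = 0; c < sink.bitmap.size(); ++c)
      if (sink.bitmap[c]) codes.push_back((u64)c);
    n = codes.size();
  } else if (sink.mode == 1) {
    codes.assign(sink.hs.begin(), sink.hs.end());
    std::sort(codes.begin(), codes.end());
    n = codes.size();
  } else {
    strs.assign(sink.ss.begin(), sink.ss.end());
    std::sort(strs.begin(), strs.end());
    n = strs.size();
  }

  out = RawVector((R_xlen_t)n * k);
  nwild = IntegerVector((R_xlen_t)n);
  u8* op = (u8*)RAW(out);
  if (sink.mode == 2) {
    for (size_t i = 0; i < n; ++i) {
      int w = 0;
      for (int p = 0; p < k; ++p) {
        const u8 s = (u8)strs[i][p];
        op[i * k + p] = s;
        if (s == sigma) ++w;
      }
      nwild[i] = w;
    }
  } else {
    for (size_t i = 0; i < n; ++i) {
      u64 c = codes[i];
      int w = 0;
      for (int p = 0; p < k; ++p) {
        const u8 s = (u8)(c % base);
        c /= base;
        op[i * k + p] = s;
        if (s == sigma) ++w;
      }
      nwild[i] = w;
    }
  }
}

// [[Rcpp::export]]
List cpp_pair_stems(RawVector kmers, int k, int sigma, int m,
                    IntegerVector own_rec, bool cross_only) {
  const int nk = (int)(kmers.size() / k);
  const u8* K = (const u8*)RAW(kmers);
  const int base = sigma + 1;

  StemSink sink;
  sink.mode = pick_mode(k, base, std::pow(2.0, 31));
  std::vector<i64> pw;
  if (sink.mode == 0) {
    size_t space = 1;
    for (int p = 0; p < k; ++p) space *= (size_t)base;
    sink.bitmap.assign(space, false);
  }
  if (sink.mode != 2) {
    pw.resize(k);
    i64 v = 1;
    for (int p = 0; p < k; ++p) { pw[p] = v; v *= base; }
  }

  std::vector<i64> codeA(sink.mode != 2 ? nk : 0);
  if (sink.mode != 2) {
    for (int i = 0; i < nk; ++i) {
      i64 c = 0;
      for (int p = 0; p < k; ++p) c += (i64)K[(size_t)i * k + p] * pw[p];
      codeA[i] = c;
    }
  }

  PairGen pg;
  pg.k = k; pg.m = m; pg.sigma = sigma; pg.sink = &sink;
  pg.pw = pw.empty() ? nullptr : pw.data();

  double n_pairs = 0.0, n_close = 0.0;
  const int dmax = 2 * m;

  // Self-pairs first (d = 0 stems), then all admissible unordered pairs.
  for (int i = 0; i < nk; ++i) {
    const u8* a = K + (size_t)i * k;
    if (sink.mode != 2) pg.gen(a, a, codeA[i]);
    else gen_pair_bytes(a, a, k, m, sigma, sink);
  }
  for (int i = 0; i < nk; ++i) {
    const u8* a = K + (size_t)i * k;
    for (int j = i + 1; j < nk; ++j) {
      if (cross_only && own_rec[i] >= 0 && own_rec[i] == own_rec[j]) continue;
      n_pairs += 1.0;
      const u8* b = K + (size_t)j * k;
      int d = 0;
      bool close = true;
      for (int p = 0; p < k; ++p)
        if (a[p] != b[p] && ++d > dmax) { close = false; break; }
      if (!close) continue;
      n_close += 1.0;
      if (sink.mode != 2) pg.gen(a, b, codeA[i]);
      else gen_pair_bytes(a, b, k, m, sigma, sink);
    }
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  RawVector out;
  IntegerVector nwild;
  sink_to_output(sink, k, base, out, nwild, sigma);
  return List::create(_["stems"] = out, _["n_wildcards"] = nwild,
                      _["n_pairs"] = n_pairs, _["n_close_pairs"] = n_close);
}

// Stems for a single (a, b) pair (the stem-set H(a,b) of that pair alone).
// [[Rcpp::export]]
List cpp_gen_pair(RawVector a, RawVector b, int sigma, int m) {
  const int k = (int)a.size();
  const int base = sigma + 1;
  StemSink sink;
  sink.mode = pick_mode(k, base, std::pow(2.0, 31));
  if (sink.mode == 0) {
    size_t space = 1;
    for (int p = 0; p < k; ++p) space *= (size_t)base;
    sink.bitmap.assign(space, false);
  }
  const u8* ap = (const u8*)RAW(a);
  const u8* bp = (const u8*)RAW(b);
  if (sink.mode != 2) {
    std::vector<i64> pw(k);
    i64 v = 1;
    for (int p = 0; p < k; ++p) { pw[p] = v; v *= base; }
    i64 cA = 0;
    for (int p = 0; p < k; ++p) cA += (i64)ap[p] * pw[p];
    PairGen pg;
    pg.k = k; pg.m = m; pg.sigma = sigma; pg.sink = &sink;
    pg.pw = pw.data();
    pg.gen(ap, bp, cA);
  } else {
    gen_pair_bytes(ap, bp, k, m, sigma, sink);
  }
  RawVector out;
  IntegerVector nwild;
  sink_to_output(sink, k, base, out, nwild, sigma);
  return List::create(_["stems"] = out, _["n_wildcards"] = nwild);
}

// ---------------------------------------------------------------------------
// Expansion of surviving stems to explicit k-mers + quorum verification.
// ---------------------------------------------------------------------------

// Depth-first assignment of wildcard symbols with quorum pruning: a partial
// assignment is abandoned once fewer than q records retain a window whose
// accumulated masked distance can still stay within m. Emits only verified
// motifs; exact for the supplied window set.
struct DfsExpand {
  int k, m, sigma, q, nw, N;
  const u8* W;
  const int* wrec;
  StemSink* sink;
  const std::vector<i64>* pw;

  std::vector<int> wp;      // wildcard positions of current stem
  std::vector<u8> cur;      // current candidate being built
  std::vector<int> live_wi; // flat live-window stack across depths
  std::vector<int> live_acc;
  std::vector<int> seen;    // per-record stamp
  int stamp;

  int count_recs(int lo, int hi) {
    ++stamp;
    int c = 0;
    for (int t = lo; t < hi; ++t) {
      const int r = wrec[live_wi[t]];
      if (seen[r] != stamp) { seen[r] = stamp; ++c; }
    }
    return c;
  }

  void emit() {
    if (sink->mode == 2) { sink->insert_str(cur.data(), k); return; }
    i64 c = 0;
    for (int p = 0; p < k; ++p) c += (i64)cur[p] * (*pw)[p];
    sink->insert_code(c);
  }

  void dfs(int depth, int lo, int hi) {
    if (count_recs(lo, hi) < q) return;
    if (depth == (int)wp.size()) { emit(); return; }
    const int pos = wp[depth];
    for (int s = 0; s < sigma; ++s) {
      const int nlo = (int)live_wi.size();
      for (int t = lo; t < hi; ++t) {
        const int wi = live_wi[t];
        const int acc = live_acc[t] + (W[(size_t)wi * k + pos] != s ? 1 : 0);
        if (acc <= m) { live_wi.push_back(wi); live_acc.push_back(acc); }
      }
      const int nhi = (int)live_wi.size();
      if (nhi > nlo) {
        cur[pos] = (u8)s;
        dfs(depth + 1, nlo, nhi);
      }
      live_wi.resize(nlo);
      live_acc.resize(nlo);
    }
  }

  void run_stem(const u8* st) {
    wp.clear();
    for (int p = 0; p < k; ++p) if (st[p] == sigma) wp.push_back(p);
    std::memcpy(cur.data(), st, k);
    live_wi.clear();
    live_acc.clear();
    for (int wi = 0; wi < nw; ++wi) {
      const u8* wrow = W + (size_t)wi * k;
      int base = 0;
      bool ok = true;
      for (int p = 0; p < k; ++p) {
        if (st[p] != sigma && st[p] != wrow[p] && ++base > m) { ok = false; break; }
      }
      if (ok) { live_wi.push_back(wi); live_acc.push_back(base); }
    }
    dfs(0, 0, (int)live_wi.size());
  }
};

// [[Rcpp::export]]
List cpp_expand_verify(RawVector stems, RawVector windows, IntegerVector win_rec,
                       int k, int m, int sigma, int N, int q) {
  const int ns = (int)(stems.size() / k);
  const u8* S = (const u8*)RAW(stems);

  // Dedup candidates over sigma^k space (no wildcard in candidates). When the
  // space fits a bitmap, enumerate every instantiation; otherwise (large
  // alphabets, where the selected set is small) use the pruned DFS, which
  // emits verified motifs only.
  StemSink sink;
  sink.mode = pick_mode(k, sigma, std::pow(2.0, 31));
  std::vector<i64> pw;
  if (sink.mode == 0) {
    size_t space = 1;
    for (int p = 0; p < k; ++p) space *= (size_t)sigma;
    sink.bitmap.assign(space, false);
  }
  if (sink.mode != 2) {
    pw.resize(k);
    i64 v = 1;
    for (int p = 0; p < k; ++p) { pw[p] = v; v *= sigma; }
  }

  if (sink.mode == 0) {
    std::vector<int> wp;
    for (int si = 0; si < ns; ++si) {
      const u8* st = S + (size_t)si * k;
      wp.clear();
      for (int p = 0; p < k; ++p) if (st[p] == sigma) wp.push_back(p);
      const int w = (int)wp.size();
      i64 c0 = 0;
      for (int p = 0; p < k; ++p) c0 += (i64)((st[p] == sigma) ? 0 : st[p]) * pw[p];
      if (w == 0) {
        sink.insert_code(c0);
      } else {
        std::vector<int> dig(w, 0);
        i64 c = c0;
        while (true) {
          sink.insert_code(c);
          int t = 0;
          while (t < w) {
            if (++dig[t] < sigma) { c += pw[wp[t]]; break; }
            c -= (i64)(sigma - 1) * pw[wp[t]];
            dig[t] = 0;
            ++t;
          }
          if (t == w) break;
        }
      }
      if ((si & 4095) == 0) Rcpp::checkUserInterrupt();
    }
  } else {
    DfsExpand dx;
    dx.k = k; dx.m = m; dx.sigma = sigma; dx.q = q; dx.N = N;
    dx.nw = (int)(windows.size() / k);
    dx.W = (const u8*)RAW(windows);
    std::vector<int> wrec0(dx.nw);
    for (int i = 0; i < dx.nw; ++i) wrec0[i] = win_rec[i];
    dx.wrec = wrec0.data();
    dx.sink = &sink;
    dx.pw = &pw;
    dx.cur.resize(k);
    dx.seen.assign(N, -1);
    dx.stamp = 0;
    for (int si = 0; si < ns; ++si) {
      dx.run_stem(S + (size_t)si * k);
      if ((si & 255) == 0) Rcpp::checkUserInterrupt();
    }
  }

  RawVector cand;
  IntegerVector nwild;
  sink_to_output(sink, k, sigma, cand, nwild, sigma + 1);
  const int nc = (int)(cand.size() / k);

  // Verify the motif property (quorum q at distance m) for every candidate.
  MatchArgs A;
  A.k = k; A.d = m; A.sigma = sigma; A.N = N; A.q = q;
  A.nb = (N + 63) / 64;
  A.nq = nc;
  A.nw = (int)(windows.size() / k);
  A.Q = (const u8*)RAW(cand);
  A.W = (const u8*)RAW(windows);
  std::vector<int> wrec(A.nw);
  for (int i = 0; i < A.nw; ++i) wrec[i] = win_rec[i];
  A.wrec = wrec.data();
  std::vector<u64> mask((size_t)nc * A.nb, 0);
  if (nc > 0 && A.nw > 0) match_core(A, mask);

  std::vector<int> keep;
  std::vector<int> kcnt;
  for (int ci = 0; ci < nc; ++ci) {
    int c = 0;
    for (int b = 0; b < A.nb; ++b) {
      u64 v = mask[(size_t)ci * A.nb + b];
      while (v) { v &= v - 1; ++c; }
    }
    if (c >= q) { keep.push_back(ci); kcnt.push_back(c); }
  }

  RawVector motifs((R_xlen_t)keep.size() * k);
  u8* mp = (u8*)RAW(motifs);
  const u8* cp = (const u8*)RAW(cand);
  for (size_t i = 0; i < keep.size(); ++i)
    std::memcpy(mp + i * k, cp + (size_t)keep[i] * k, k);

  return List::create(_["motifs"] = motifs,
                      _["n_records"] = IntegerVector(kcnt.begin(), kcnt.end()),
                      _["n_candidates"] = (double)nc);
}
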