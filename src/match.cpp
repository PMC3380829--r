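// Bounded-difference matching of short queries against a set of reference
// reads (global in the query, local in the reference).  A "difference" is a
// single event: one mismatch, or one indel run of length L contributing L
// bases to the indel-base total.  Candidate windows are found by exact k-mer
// seeding with k chosen so that any qualifying alignment must contain an
// intact run of >= k query bases (pigeonhole over at most max_diff damaged
// runs); each candidate diagonal is then verified by exact case analysis
// (0-gap scan, single-gap prefix/suffix combination, two-gap three-segment
// feasibility), which is complete for max_diff <= 2.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const int OOB = 1000;     // sentinel "mismatch" outside the reference

static inline uint8_t base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;           // N or anything else: matches nothing
  }
}

static std::vector<uint8_t> encode_seq(const char* s) {
  std::vector<uint8_t> v;
  for (const char* p = s; *p; ++p) v.push_back(base_code(*p));
  return v;
}

static std::vector<uint8_t> revcomp_codes(const std::vector<uint8_t>& v) {
  std::vector<uint8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint8_t c = v[v.size() - 1 - i];
    r[i] = (c < 4) ? (uint8_t)(3 - c) : (uint8_t)4;
  }
  return r;
}

struct MatchIndex {
  int k;
  std::vector<std::vector<uint8_t>> refs;
  std::vector<uint32_t> bstart;   // bucket offsets, size 4^k + 1
  std::vector<uint32_t> eref;     // entry: reference index
  std::vector<int32_t>  epos;     // entry: k-mer start position in reference
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector refs, int k) {
  if (k < 4 || k > 14) stop("seed length must be in [4, 14]");
  MatchIndex* idx = new MatchIndex();
  idx->k = k;
  size_t nb = ((size_t)1) << (2 * k);
  uint32_t mask = (uint32_t)(nb - 1);
  idx->refs.reserve(refs.size());
  std::vector<uint32_t> counts(nb + 1, 0);

  for (R_xlen_t i = 0; i < refs.size(); ++i)
    idx->refs.push_back(encode_seq(CHAR(STRING_ELT(refs, i))));

  // two passes: count, then fill
  for (int pass = 0; pass < 2; ++pass) {
    if (pass == 1) {
      idx->bstart.assign(nb + 1, 0);
      for (size_t b = 0; b < nb; ++b) idx->bstart[b + 1] = idx->bstart[b] + counts[b];
      idx->eref.resize(idx->bstart[nb]);
      idx->epos.resize(idx->bstart[nb]);
      std::fill(counts.begin(), counts.end(), 0);
    }
    for (size_t ri = 0; ri < idx->refs.size(); ++ri) {
      const std::vector<uint8_t>& r = idx->refs[ri];
      uint32_t code = 0; int run = 0;
      for (size_t p = 0; p < r.size(); ++p) {
        if (r[p] > 3) { run = 0; code = 0; continue; }
        code = ((code << 2) | r[p]) & mask;
        if (++run >= k) {
          uint32_t b = code;
          if (pass == 0) counts[b]++;
          else {
            uint32_t at = idx->bstart[b] + counts[b]++;
            idx->eref[at] = (uint32_t)ri;
            idx->epos[at] = (int32_t)(p - k + 1);
          }
        }
      }
    }
  }
  XPtr<MatchIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
int cpp_index_size(SEXP idx_ptr) {
  XPtr<MatchIndex> idx(idx_ptr);
  return (int)idx->refs.size();
}

static inline int cmp1(const uint8_t* q, const uint8_t* r, int Lr, int i, int j) {
  if (j < 0 || j >= Lr) return OOB;
  uint8_t a = q[i], b = r[j];
  return (a == b && a < 4) ? 0 : 1;
}

struct VR { int e, g, off; bool ok; };

static inline bool lex_lt(int e1, int g1, int e2, int g2) {
  return e1 < e2 || (e1 == e2 && g1 < g2);
}

// Verify alignments of q against r whose segments lie on diagonals
// d-bw .. d+bw.  mode 0: return the first alignment within budgets ("any
// hit").  mode 1: return the minimal (events, indel bases, offset), but only
// if it is lexicographically <= (cap_e, cap_g); alignments strictly worse
// than the cap may be pruned.
//
// Each candidate group is only responsible for alignments ANCHORED on its
// seed diagonal: every qualifying alignment contains an intact run >= k and
// therefore generates its own candidate group, where that run lies on the
// relative diagonal 0.  This justifies (a) the cap pruning and (b) the cheap
// anchoring gate below, which rejects a group early when no alignment can
// use a clean k-window of the seed diagonal.
static VR verify_group(const uint8_t* q, int n, const uint8_t* r, int Lr,
                       int d, int k, int maxd, int maxB, int mode,
                       int cap_e, int cap_g) {
  VR res; res.ok = false; res.e = maxd + 1; res.g = maxB + 1; res.off = 0;

  // 0-gap on the seed diagonal, keeping prefix mismatch counts for the gate
  int P0[65];
  P0[0] = 0;
  for (int i = 0; i < n; ++i) P0[i + 1] = P0[i] + cmp1(q, r, Lr, i, d + i);
  int m0 = P0[n];
  if (m0 <= maxd) {
    if (mode == 0) { res.ok = true; res.e = m0; res.g = 0; res.off = d; return res; }
    if (m0 == 0) { res.ok = true; res.e = 0; res.g = 0; res.off = d; return res; }
    res.e = m0; res.g = 0; res.off = d; res.ok = !lex_lt(cap_e, cap_g, m0, 0);
  }
  // prune: alignment classes involving a gap are all >= (1,1)
  if (mode == 1 && lex_lt(cap_e, cap_g, 1, 1)) return res;
  if (maxB < 1 || maxd < 1) return res;

  // anchoring gate: a gapped alignment anchored here must place one segment
  // on diagonal 0 covering a clean k-window.  Prefix anchor: some split
  // p >= (end of first clean k-window) with <= maxd-1 mismatches before it.
  // Suffix anchor: symmetric.  Middle anchor (two-gap case): some other
  // diagonal offers a clean prefix reaching near the first clean window and
  // some other diagonal a clean suffix from near the last one.
  int emin = -1, bmax = -1;
  for (int e = k; e <= n; ++e)
    if (P0[e] - P0[e - k] == 0) { emin = e; break; }
  for (int b = n - k; b >= 0; --b)
    if (P0[b + k] - P0[b] == 0) { bmax = b; break; }
  if (emin < 0) return res;  // no clean k-window at all (N bases in seed area)
  bool A1 = P0[emin] <= maxd - 1;
  bool A2 = (P0[n] - P0[bmax]) <= maxd - 1;
  bool M = false;
  if (!A1 && !A2 && maxd >= 2 && maxB >= 2) {
    int needpre = (emin - k) - maxB;
    bool mpre = needpre <= 0;
    for (int delta = -maxB; delta <= maxB && !mpre; ++delta) {
      if (delta == 0) continue;
      bool clean = true;
      for (int i = 0; i < needpre; ++i)
        if (cmp1(q, r, Lr, i, d + delta + i)) { clean = false; break; }
      if (clean) mpre = true;
    }
    if (mpre) {
      int sufstart = (bmax + k) + maxB;
      bool msuf = sufstart >= n;
      for (int delta = -maxB; delta <= maxB && !msuf; ++delta) {
        if (delta == 0) continue;
        bool clean = true;
        for (int i = sufstart; i < n; ++i)
          if (cmp1(q, r, Lr, i, d + delta + i)) { clean = false; break; }
        if (clean) msuf = true;
      }
      M = msuf;
    }
  }
  if (!A1 && !A2 && !M) return res;

  // band prefix-mismatch table
  const int bw = maxB;
  const int W = 2 * bw + 1;
  static thread_local std::vector<int> Pbuf;
  Pbuf.assign((size_t)W * (n + 1), 0);
  std::vector<int> F(W), Bsuf(W);
  for (int w = 0; w < W; ++w) {
    int delta = w - bw;
    int* P = &Pbuf[(size_t)w * (n + 1)];
    P[0] = 0;
    for (int i = 0; i < n; ++i) P[i + 1] = P[i] + cmp1(q, r, Lr, i, d + delta + i);
    int f = 0; while (f < n && P[f + 1] == 0) ++f;
    F[w] = f;
    int b = n; while (b > 0 && P[n] - P[b - 1] == 0) --b;
    Bsuf[w] = b;
  }
  #define PW(w) (&Pbuf[(size_t)(w) * (n + 1)])

  auto consider = [&](int e, int g, int off) {
    if (e > maxd || g > maxB) return;
    if (mode == 1 && lex_lt(cap_e, cap_g, e, g)) return;   // worse than cap
    if (lex_lt(e, g, res.e, res.g) ||
        (e == res.e && g == res.g && (!res.ok || off < res.off))) {
      res.e = e; res.g = g; res.off = off; res.ok = true;
    }
  };

  // 0-gap on the other band diagonals
  for (int w = 0; w < W; ++w) {
    if (w == bw) continue;
    int e = PW(w)[n];
    consider(e, 0, d + (w - bw));
    if (mode == 0 && res.ok) return res;
  }

  // single gap: prefix on delta1, one indel run of k bases, suffix
  if (maxd >= 1) {
    for (int w1 = 0; w1 < W; ++w1) {
      const int* Pa = PW(w1);
      for (int k = 1; k <= maxB; ++k) {
        int w2 = w1 - k;                    // deletion of k query bases
        if (w2 >= 0) {
          const int* Pb = PW(w2);
          int base = Pb[n], best = OOB;
          for (int p = 0; p <= n - k; ++p) {
            int mm = Pa[p] + base - Pb[p + k];
            if (mm < best) best = mm;
          }
          if (best <= maxd - 1) {
            consider(1 + best, k, d + (w1 - bw));
            if (mode == 0 && res.ok) return res;
          }
        }
        int w2i = w1 + k;                   // insertion of k reference bases
        if (w2i < W) {
          const int* Pb = PW(w2i);
          int base = Pb[n], best = OOB;
          for (int p = 1; p <= n - 1; ++p) {
            int mm = Pa[p] + base - Pb[p];
            if (mm < best) best = mm;
          }
          if (best <= maxd - 1) {
            consider(1 + best, k, d + (w1 - bw));
            if (mode == 0 && res.ok) return res;
          }
        }
      }
    }
  }

  // two gaps, zero mismatches: three exact segments
  if (maxd >= 2 && maxB >= 2 && !(mode == 1 && lex_lt(cap_e, cap_g, 2, 2))) {
    if (!(res.ok && lex_lt(res.e, res.g, 2, 2))) {
      for (int w1 = 0; w1 < W; ++w1) {
        for (int s1 = -maxB; s1 <= maxB; ++s1) {
          if (s1 == 0) continue;
          int w2 = w1 + s1;
          if (w2 < 0 || w2 >= W) continue;
          int k1 = std::abs(s1);
          for (int s2 = -maxB; s2 <= maxB; ++s2) {
            if (s2 == 0) continue;
            int k2 = std::abs(s2);
            if (k1 + k2 > maxB) continue;
            int w3 = w2 + s2;
            if (w3 < 0 || w3 >= W) continue;
            if (res.ok && !lex_lt(2, k1 + k2, res.e, res.g) &&
                !(res.e == 2 && res.g == k1 + k2)) continue;
            int up1 = (s1 < 0) ? (n - k1) : (n - 1);
            int lo1 = (s1 > 0) ? 1 : 0;
            int p1 = std::min(F[w1], up1);
            if (p1 < lo1) continue;
            int a2 = p1 + (s1 < 0 ? k1 : 0);
            if (a2 > n) continue;
            int lo2 = a2;
            int need = Bsuf[w3] - (s2 < 0 ? k2 : 0);
            if (need > lo2) lo2 = need;
            if (s2 > 0 && lo2 < 1) lo2 = 1;
            int up2 = (s2 < 0) ? (n - k2) : (n - 1);
            if (lo2 > up2 || lo2 < a2) continue;
            const int* Pm = PW(w2);
            if (Pm[lo2] - Pm[a2] != 0) continue;
            consider(2, k1 + k2, d + (w1 - bw));
            if (mode == 0 && res.ok) return res;
          }
        }
      }
    }
  }
  #undef PW
  return res;
}

struct RefScratch {
  std::vector<uint32_t> dstamp;   // (query, strand) stamp for tried diagonals
  std::vector<uint8_t>  ntried;
  std::vector<int16_t>  tried;    // 8 slots per reference
  std::vector<uint32_t> hstamp;   // query-level stamp (counts / hits modes)
  std::vector<int16_t>  he, hg, hoff;  // per-ref best for hits mode
  void init(size_t n) {
    dstamp.assign(n, 0); ntried.assign(n, 0); tried.assign(n * 8, 0);
    hstamp.assign(n, 0); he.assign(n, 0); hg.assign(n, 0); hoff.assign(n, 0);
  }
};

// [[Rcpp::export]]
List cpp_match_query(SEXP idx_ptr, CharacterVector queries, int max_diff,
                     int max_indel, bool both_strands, std::string mode,
                     IntegerVector ref_cluster, NumericVector cluster_prop,
                     std::string policy) {
  XPtr<MatchIndex> idx(idx_ptr);
  if (max_diff < 0 || max_diff > 2)
    stop("max_differences must be 0, 1 or 2");
  if (max_indel < 0 || max_indel > 8)
    stop("max_total_indel_bases must be in [0, 8]");
  const int k = idx->k;
  const size_t nref = idx->refs.size();
  const uint32_t mask = (uint32_t)((((size_t)1) << (2 * k)) - 1);
  const int MODE_HITS = 0, MODE_COUNTS = 1, MODE_ASSIGN = 2;
  int M = (mode == "hits") ? MODE_HITS : (mode == "counts") ? MODE_COUNTS :
          (mode == "assign") ? MODE_ASSIGN : -1;
  if (M < 0) stop("unknown mode");
  bool fractional = (policy == "fractional");

  RefScratch sc; sc.init(nref);
  uint32_t qs_stamp = 0, q_stamp = 0;

  std::vector<double> counts(M == MODE_COUNTS ? nref : 0, 0.0);
  LogicalVector mapped(M != MODE_HITS ? queries.size() : 0);
  IntegerVector assign(M == MODE_ASSIGN ? queries.size() : 0);
  std::vector<int> h_q, h_ref, h_e, h_g, h_off;
  std::vector<int> h_strand;

  std::vector<uint32_t> qhits;     // counts mode: refs hit by this query
  std::vector<uint32_t> touched;   // hits mode: refs touched this strand
  std::vector<uint32_t> bestrefs;  // assign mode

  for (R_xlen_t qi = 0; qi < queries.size(); ++qi) {
    std::vector<uint8_t> qf = encode_seq(CHAR(STRING_ELT(queries, qi)));
    int n = (int)qf.size();
    ++q_stamp;
    qhits.clear(); bestrefs.clear();
    int be = max_diff, bg = max_indel;  // assign cap: budgets
    bool have_best = false;
    if (n > 63) stop("query longer than 63 nt not supported");
    if (n < k) { // too short to seed
      if (M == MODE_COUNTS || M == MODE_ASSIGN) mapped[qi] = false;
      if (M == MODE_ASSIGN) assign[qi] = 0;
      continue;
    }
    int nstr = both_strands ? 2 : 1;
    for (int strand = 0; strand < nstr; ++strand) {
      std::vector<uint8_t> q = (strand == 0) ? qf : revcomp_codes(qf);
      ++qs_stamp;
      touched.clear();
      uint32_t code = 0; int run = 0;
      for (int p = 0; p < n; ++p) {
        if (q[p] > 3) { run = 0; code = 0; continue; }
        code = ((code << 2) | q[p]) & mask;
        if (++run < k) continue;
        int s = p - k + 1;
        uint32_t b0 = idx->bstart[code], b1 = idx->bstart[code + 1];
        for (uint32_t t = b0; t < b1; ++t) {
          uint32_t ref = idx->eref[t];
          int diag = idx->epos[t] - s;
          if (M == MODE_COUNTS && sc.hstamp[ref] == q_stamp) continue;
          if (sc.dstamp[ref] != qs_stamp) { sc.dstamp[ref] = qs_stamp; sc.ntried[ref] = 0; }
          bool seen = false;
          int16_t* tr = &sc.tried[(size_t)ref * 8];
          for (int u = 0; u < sc.ntried[ref]; ++u)
            if (tr[u] == (int16_t)diag) { seen = true; break; }
          if (seen) continue;
          if (sc.ntried[ref] < 8) tr[sc.ntried[ref]++] = (int16_t)diag;
          const std::vector<uint8_t>& r = idx->refs[ref];
          if (M == MODE_COUNTS) {
            VR v = verify_group(q.data(), n, r.data(), (int)r.size(), diag,
                                k, max_diff, max_indel, 0, 0, 0);
            if (v.ok) { sc.hstamp[ref] = q_stamp; qhits.push_back(ref); }
          } else if (M == MODE_ASSIGN) {
            VR v = verify_group(q.data(), n, r.data(), (int)r.size(), diag,
                                k, max_diff, max_indel, 1, be, bg);
            if (v.ok) {
              if (!have_best || lex_lt(v.e, v.g, be, bg)) {
                be = v.e; bg = v.g; have_best = true;
                bestrefs.clear(); bestrefs.push_back(ref);
              } else if (v.e == be && v.g == bg) {
                bestrefs.push_back(ref);
              }
            }
          } else { // hits
            VR v = verify_group(q.data(), n, r.data(), (int)r.size(), diag,
                                k, max_diff, max_indel, 1, max_diff, max_indel);
            if (v.ok) {
              if (sc.hstamp[ref] != qs_stamp) {
                sc.hstamp[ref] = qs_stamp;
                sc.he[ref] = (int16_t)v.e; sc.hg[ref] = (int16_t)v.g;
                sc.hoff[ref] = (int16_t)v.off;
                touched.push_back(ref);
              } else if (lex_lt(v.e, v.g, sc.he[ref], sc.hg[ref]) ||
                         (v.e == sc.he[ref] && v.g == sc.hg[ref] &&
                          v.off < sc.hoff[ref])) {
                sc.he[ref] = (int16_t)v.e; sc.hg[ref] = (int16_t)v.g;
                sc.hoff[ref] = (int16_t)v.off;
              }
            }
          }
        }
      }
      if (M == MODE_HITS) {
        std::sort(touched.begin(), touched.end());
        for (uint32_t ref : touched) {
          h_q.push_back((int)qi + 1);
          h_ref.push_back((int)ref + 1);
          h_strand.push_back(strand);
          h_e.push_back(sc.he[ref]);
          h_g.push_back(sc.hg[ref]);
          h_off.push_back(sc.hoff[ref]);
        }
      }
    }
    if (M == MODE_COUNTS) {
      mapped[qi] = !qhits.empty();
      if (!qhits.empty()) {
        double w = fractional ? 1.0 / (double)qhits.size() : 1.0;
        for (uint32_t ref : qhits) counts[ref] += w;
      }
    } else if (M == MODE_ASSIGN) {
      mapped[qi] = have_best;
      int bestcl = 0; double bestp = -1.0;
      for (uint32_t ref : bestrefs) {
        int cl = (ref < (size_t)ref_cluster.size()) ? ref_cluster[ref] : 0;
        if (cl <= 0) continue;
        double pr = cluster_prop[cl - 1];
        if (bestcl == 0 || pr > bestp || (pr == bestp && cl < bestcl)) {
          bestcl = cl; bestp = pr;
        }
      }
      assign[qi] = bestcl;
    }
  }

  if (M == MODE_HITS) {
    CharacterVector strand_chr(h_strand.size());
    for (size_t i = 0; i < h_strand.size(); ++i)
      strand_chr[i] = h_strand[i] == 0 ? "+" : "-";
    return List::create(
      _["query"] = wrap(h_q), _["reference"] = wrap(h_ref),
      _["strand"] = strand_chr, _["n_differences"] = wrap(h_e),
      _["indel_bases"] = wrap(h_g), _["ref_offset"] = wrap(h_off));
  } else if (M == MODE_COUNTS) {
    return List::create(_["counts"] = wrap(counts), _["mapped"] = mapped);
  }
  return List::create(_["cluster"] = assign, _["mapped"] = mapped);
}
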