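// Local alignment kernels used by read clustering (similarity edges),
// profiling (dotplots, representative-contig extension) and identity
// utilities.  Smith-Waterman with match +1, mismatch -1, linear gap -2.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>
#include <unordered_map>

using namespace Rcpp;

static inline uint8_t bcode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static std::vector<uint8_t> enc(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = bcode(s[i]);
  return v;
}

static std::string rc_str(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[s.size() - 1 - i];
    switch (c) {
      case 'A': case 'a': r[i] = 'T'; break;
      case 'C': case 'c': r[i] = 'G'; break;
      case 'G': case 'g': r[i] = 'C'; break;
      case 'T': case 't': r[i] = 'A'; break;
      default: r[i] = 'N';
    }
  }
  return r;
}

struct SWResult {
  int score;
  int columns, matches;
  int a_start, a_end, b_start, b_end;  // 0-based half-open aligned spans
};

// Smith-Waterman with traceback; direction matrix is rebuilt per call.
static SWResult sw_align(const std::vector<uint8_t>& a,
                         const std::vector<uint8_t>& b) {
  const int MATCH = 1, MISMATCH = -1, GAP = -2;
  int n = (int)a.size(), m = (int)b.size();
  SWResult res; res.score = 0; res.columns = 0; res.matches = 0;
  res.a_start = res.a_end = res.b_start = res.b_end = 0;
  if (n == 0 || m == 0) return res;

  static thread_local std::vector<int> Hprev, Hcur;
  static thread_local std::vector<uint8_t> dir;  // 0 stop, 1 diag, 2 up, 3 left
  Hprev.assign(m + 1, 0); Hcur.assign(m + 1, 0);
  dir.assign((size_t)(n + 1) * (m + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0;
    uint8_t ai = a[i - 1];
    uint8_t* drow = &dir[(size_t)i * (m + 1)];
    for (int j = 1; j <= m; ++j) {
      int s = (ai == b[j - 1] && ai < 4) ? MATCH : MISMATCH;
      int dg = Hprev[j - 1] + s;
      int up = Hprev[j] + GAP;
      int lf = Hcur[j - 1] + GAP;
      int h = dg; uint8_t d = 1;
      if (up > h) { h = up; d = 2; }
      if (lf > h) { h = lf; d = 3; }
      if (h <= 0) { h = 0; d = 0; }
      Hcur[j] = h; drow[j] = d;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }
  res.score = best;
  if (best == 0) return res;

  int i = bi, j = bj, cols = 0, mat = 0;
  while (i > 0 && j > 0) {
    uint8_t d = dir[(size_t)i * (m + 1) + j];
    if (d == 0) break;
    ++cols;
    if (d == 1) {
      if (a[i - 1] == b[j - 1] && a[i - 1] < 4) ++mat;
      --i; --j;
    } else if (d == 2) --i;
    else --j;
  }
  res.columns = cols; res.matches = mat;
  res.a_start = i; res.a_end = bi;
  res.b_start = j; res.b_end = bj;
  return res;
}

// [[Rcpp::export]]
List cpp_local_align(std::string a, std::string b) {
  SWResult r = sw_align(enc(a), enc(b));
  double ident = r.columns > 0 ? (double)r.matches / r.columns : 0.0;
  return List::create(
    _["score"] = r.score, _["identity"] = ident,
    _["columns"] = r.columns, _["matches"] = r.matches,
    _["a_start"] = r.a_start, _["a_end"] = r.a_end,
    _["b_start"] = r.b_start, _["b_end"] = r.b_end);
}

// Does some strand of b align locally to a at >= min_identity covering
// >= min_overlap of the shorter read?
static bool similar_pair(const std::vector<uint8_t>& a,
                         const std::vector<uint8_t>& bf,
                         const std::vector<uint8_t>& br,
                         double min_identity, double min_overlap) {
  int shorter = std::min((int)a.size(), (int)bf.size());
  if (shorter == 0) return false;
  double need = min_overlap * shorter;
  for (int strand = 0; strand < 2; ++strand) {
    const std::vector<uint8_t>& b = strand == 0 ? bf : br;
    SWResult r = sw_align(a, b);
    if (r.columns == 0) continue;
    double ident = (double)r.matches / r.columns;
    int cov = ((int)a.size() <= (int)b.size())
                  ? (r.a_end - r.a_start) : (r.b_end - r.b_start);
    if (ident >= min_identity && (double)cov >= need) return true;
  }
  return false;
}

// [[Rcpp::export]]
List cpp_similarity_edges(CharacterVector reads, double min_identity,
                          double min_overlap, int k) {
  int n = reads.size();
  std::vector<std::vector<uint8_t>> fwd(n), rev(n);
  std::vector<std::string> raw(n);
  for (int i = 0; i < n; ++i) {
    raw[i] = std::string(CHAR(STRING_ELT(reads, i)));
    fwd[i] = enc(raw[i]);
    rev[i] = enc(rc_str(raw[i]));
  }
  // canonical k-mer buckets
  std::unordered_map<uint64_t, std::vector<int>> buckets;
  buckets.reserve((size_t)n * 8);
  uint64_t mask = (k >= 32) ? ~(uint64_t)0 : ((((uint64_t)1) << (2 * k)) - 1);
  for (int i = 0; i < n; ++i) {
    const std::vector<uint8_t>& s = fwd[i];
    if ((int)s.size() < k) continue;
    uint64_t cf = 0, cr = 0; int run = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      if (s[p] > 3) { run = 0; cf = 0; cr = 0; continue; }
      cf = ((cf << 2) | s[p]) & mask;
      cr = (cr >> 2) | (((uint64_t)(3 - s[p])) << (2 * (k - 1)));
      if (++run >= k) {
        uint64_t canon = std::min(cf, cr & mask);
        std::vector<int>& v = buckets[canon];
        if (v.empty() || v.back() != i) v.push_back(i);
      }
    }
  }
  // candidate pairs (dedupe via hash set of packed indices)
  std::unordered_map<uint64_t, bool> tested;
  std::vector<int> e_from, e_to;
  for (auto& kv : buckets) {
    std::vector<int>& v = kv.second;
    if (v.size() < 2) continue;
    for (size_t x = 0; x < v.size(); ++x) {
      for (size_t y = x + 1; y < v.size(); ++y) {
        int a = std::min(v[x], v[y]), b = std::max(v[x], v[y]);
        uint64_t key = ((uint64_t)a << 32) | (uint64_t)b;
        auto it = tested.find(key);
        if (it != tested.end()) continue;
        bool ok = similar_pair(fwd[a], fwd[b], rev[b],
                               min_identity, min_overlap);
        tested[key] = ok;
        if (ok) { e_from.push_back(a + 1); e_to.push_back(b + 1); }
      }
    }
  }
  return List::create(_["from"] = wrap(e_from), _["to"] = wrap(e_to));
}

// Ungapped windowed dotplot: report (pos_a, pos_b) where the w-length windows
// starting there agree at >= min_identity, for b forward and reverse.
// Positions are 0-based; reverse-strand pos_b refers to the reverse
// complement of b.
// [[Rcpp::export]]
List cpp_dotplot(std::string a, std::string b, int window,
                 double min_identity, int step) {
  std::vector<uint8_t> av = enc(a);
  std::vector<int> xs, ys; std::vector<int> strands;
  int need = (int)std::ceil(min_identity * window - 1e-9);
  for (int strand = 0; strand < 2; ++strand) {
    std::vector<uint8_t> bv = enc(strand == 0 ? b : rc_str(b));
    int La = (int)av.size(), Lb = (int)bv.size();
    if (La < window || Lb < window) continue;
    for (int d = -(Lb - window); d <= La - window; ++d) {
      // diagonal: pos_a = pos_b + d; slide window along it
      int i0 = std::max(0, d), j0 = i0 - d;
      int len = std::min(La - i0, Lb - j0);
      if (len < window) continue;
      int m = 0;
      for (int t = 0; t < window; ++t)
        m += (av[i0 + t] == bv[j0 + t] && av[i0 + t] < 4) ? 1 : 0;
      for (int off = 0; ; ++off) {
        int pa = i0 + off;
        if (m >= need && pa % step == 0) {
          xs.push_back(pa); ys.push_back(j0 + off); strands.push_back(strand);
        }
        if (off + window >= len) break;
        m -= (av[pa] == bv[j0 + off] && av[pa] < 4) ? 1 : 0;
        int t = off + window;
        m += (av[i0 + t] == bv[j0 + t] && av[i0 + t] < 4) ? 1 : 0;
      }
    }
  }
  CharacterVector sch(strands.size());
  for (size_t i = 0; i < strands.size(); ++i)
    sch[i] = strands[i] == 0 ? "+" : "-";
  return List::create(_["pos_a"] = wrap(xs), _["pos_b"] = wrap(ys),
                      _["strand"] = sch);
}

// Greedy right-extension step: among candidate variants, find the one whose
// prefix overlaps the contig tail's suffix (ungapped, overlap >= min_overlap
// bases, identity >= min_identity) with the largest extension beyond the
// tail.  Ties: lowest variant index.  Returns index (1-based, 0 = none) and
// the extension string.
// [[Rcpp::export]]
List cpp_best_extension(std::string tail, CharacterVector variants,
                        int min_overlap, double min_identity) {
  std::vector<uint8_t> tv = enc(tail);
  int Lt = (int)tv.size();
  int best_idx = 0, best_ext = 0, best_o = 0;
  for (int vi = 0; vi < variants.size(); ++vi) {
    std::string cs(CHAR(STRING_ELT(variants, vi)));
    std::vector<uint8_t> cv = enc(cs);
    int Lc = (int)cv.size();
    int omax = std::min(Lt, Lc);
    // smallest valid overlap gives the largest extension
    for (int o = min_overlap; o <= omax; ++o) {
      if (Lc - o <= best_ext) break;  // cannot beat current best any more
      int allowed = (int)((1.0 - min_identity) * o + 1e-9);
      int mm = 0; bool ok = true;
      const uint8_t* tp = &tv[Lt - o];
      for (int t = 0; t < o; ++t) {
        if (!(tp[t] == cv[t] && cv[t] < 4)) {
          if (++mm > allowed) { ok = false; break; }
        }
      }
      if (ok) {
        int ext = Lc - o;
        if (ext > best_ext) { best_ext = ext; best_idx = vi + 1; best_o = o; }
        break;
      }
    }
  }
  std::string ext;
  if (best_idx > 0) {
    std::string cs(CHAR(STRING_ELT(variants, best_idx - 1)));
    ext = cs.substr(best_o);
  }
  return List::create(_["index"] = best_idx, _["extension"] = ext,
                      _["overlap"] = best_o);
}

// Mean identity of a sequence against itself shifted by s, for s = 1..smax.
// Used by monomer-length estimation.
// [[Rcpp::export]]
NumericVector cpp_shift_identity(std::string seq, int smax) {
  std::vector<uint8_t> v = enc(seq);
  int L = (int)v.size();
  NumericVector out(smax);
  for (int s = 1; s <= smax; ++s) {
    int n = L - s, m = 0;
    if (n <= 0) { out[s - 1] = NA_REAL; continue; }
    for (int i = 0; i < n; ++i)
      if (v[i] == v[i + s] && v[i] < 4) ++m;
    out[s - 1] = (double)m / n;
  }
  return out;
}
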