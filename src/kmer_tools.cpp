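#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <string>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit base codes; -1 for anything that is not A/C/G/T (uppercase).
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

static inline char comp_char(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_char(r[i]);
  return r;
}

static std::string decode_kmer(uint64_t x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = CODE2BASE[x & 3ULL];
    x >>= 2;
  }
  return s;
}

// Enumerate canonical k-mers of one sequence (k <= 31, packed encoding),
// calling f(canonical_code) for every window free of non-ACGT bases.
template <typename F>
static void for_each_canonical_packed(const std::string& seq, int k, F f) {
  const size_t n = seq.size();
  if (n < (size_t)k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rc = 0;
  int valid = 0;
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
    if (++valid >= k) f(fwd < rc ? fwd : rc);
  }
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  if (k <= 31) {
    std::unordered_map<uint64_t, int> tab;
    tab.reserve(1 << 20);
    for (R_xlen_t s = 0; s < seqs.size(); ++s) {
      std::string seq = as<std::string>(seqs[s]);
      for_each_canonical_packed(seq, k, [&](uint64_t code) { tab[code]++; });
    }
    std::vector<uint64_t> keys;
    keys.reserve(tab.size());
    for (auto& kv : tab) keys.push_back(kv.first);
    std::sort(keys.begin(), keys.end());
    CharacterVector km(keys.size());
    IntegerVector ct(keys.size());
    for (size_t i = 0; i < keys.size(); ++i) {
      km[i] = decode_kmer(keys[i], k);
      ct[i] = tab[keys[i]];
    }
    return List::create(_["kmer"] = km, _["count"] = ct);
  }
  // long k-mers (satellite discovery, k up to 151): string-keyed table
  std::unordered_map<std::string, int> tab;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    const size_t n = seq.size();
    if (n < (size_t)k) continue;
    std::string rcs = revcomp_str(seq);
    // rolling validity: count of invalid chars in window
    std::vector<int> bad(n + 1, 0);
    for (size_t i = 0; i < n; ++i)
      bad[i + 1] = bad[i] + (base_code(seq[i]) < 0 ? 1 : 0);
    for (size_t i = 0; i + k <= n; ++i) {
      if (bad[i + k] - bad[i] > 0) continue;
      std::string f = seq.substr(i, k);
      std::transform(f.begin(), f.end(), f.begin(), ::toupper);
      std::string r = rcs.substr(n - i - k, k);
      tab[f < r ? f : r]++;
    }
  }
  std::vector<std::string> keys;
  keys.reserve(tab.size());
  for (auto& kv : tab) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  CharacterVector km(keys.size());
  IntegerVector ct(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    km[i] = keys[i];
    ct[i] = tab[keys[i]];
  }
  return List::create(_["kmer"] = km, _["count"] = ct);
}

// Per-sequence count of valid k-mer windows and how many of them are members
// of `set` (canonical k-mer strings). Returns a matrix [n x 2]: total, hits.
// [[Rcpp::export]]
IntegerMatrix cpp_kmer_hits(CharacterVector seqs, int k, CharacterVector set) {
  IntegerMatrix out(seqs.size(), 2);
  if (k <= 31) {
    std::unordered_set<uint64_t> memb;
    memb.reserve(set.size() * 2 + 16);
    for (R_xlen_t i = 0; i < set.size(); ++i) {
      std::string s = as<std::string>(set[i]);
      uint64_t fwd = 0, rc = 0;
      bool ok = ((int)s.size() == k);
      const int shift = 2 * (k - 1);
      for (size_t j = 0; ok && j < s.size(); ++j) {
        int c = base_code(s[j]);
        if (c < 0) { ok = false; break; }
        fwd = (fwd << 2) | (uint64_t)c;
        rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
      }
      if (ok) memb.insert(fwd < rc ? fwd : rc);
    }
    for (R_xlen_t s = 0; s < seqs.size(); ++s) {
      std::string seq = as<std::string>(seqs[s]);
      long total = 0, hits = 0;
      for_each_canonical_packed(seq, k, [&](uint64_t code) {
        ++total;
        if (memb.count(code)) ++hits;
      });
      out(s, 0) = (int)total;
      out(s, 1) = (int)hits;
    }
    return out;
  }
  std::unordered_set<std::string> memb;
  for (R_xlen_t i = 0; i < set.size(); ++i) {
    std::string s = as<std::string>(set[i]);
    std::string r = revcomp_str(s);
    memb.insert(s < r ? s : r);
  }
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    const size_t n = seq.size();
    long total = 0, hits = 0;
    if (n >= (size_t)k) {
      std::string rcs = revcomp_str(seq);
      std::vector<int> bad(n + 1, 0);
      for (size_t i = 0; i < n; ++i)
        bad[i + 1] = bad[i] + (base_code(seq[i]) < 0 ? 1 : 0);
      for (size_t i = 0; i + k <= n; ++i) {
        if (bad[i + k] - bad[i] > 0) continue;
        ++total;
        std::string f = seq.substr(i, k);
        std::transform(f.begin(), f.end(), f.begin(), ::toupper);
        std::string r = rcs.substr(n - i - k, k);
        if (memb.count(f < r ? f : r)) ++hits;
      }
    }
    out(s, 0) = (int)total;
    out(s, 1) = (int)hits;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Minimum unique k-mer (MUK) track.
//
// MUK(window) = smallest L in [kmin, cap] such that some length-L substring
// starting inside the window occurs exactly once genome-wide counting both
// strands; cap when no such L exists. Uniqueness is evaluated with 64-bit
// polynomial hashes of the canonical (lexicographically unordered pair
// {S, revcomp(S)} -> min hash) form; windows are resolved by a simultaneous
// per-window binary search over L with one genome-wide counting pass per
// candidate L.
// ---------------------------------------------------------------------------

struct MukGenome {
  std::vector<std::string> seqs, rcs;
  std::vector<std::vector<int>> bad;  // prefix counts of non-ACGT
};

static const uint64_t HB = 0x9E3779B97F4A7C15ULL;  // odd multiplier

// hash of every length-L window of s (positions 0..n-L); invalid windows get 0
static void window_hashes(const std::string& s, int L, std::vector<uint64_t>& out) {
  const size_t n = s.size();
  out.assign(n >= (size_t)L ? n - L + 1 : 0, 0);
  if (out.empty()) return;
  uint64_t h = 0, top = 1;
  for (int i = 0; i < L - 1; ++i) top *= HB;
  for (size_t i = 0; i < (size_t)L; ++i) h = h * HB + (uint64_t)(base_code(s[i]) + 2);
  out[0] = h;
  for (size_t i = 1; i < out.size(); ++i) {
    h -= top * (uint64_t)(base_code(s[i - 1]) + 2);
    h = h * HB + (uint64_t)(base_code(s[i + L - 1]) + 2);
    out[i] = h;
  }
}

// canonical hash of window starting at p in seq i (length L); 0 if invalid
static void canonical_hashes(const MukGenome& g, size_t i, int L,
                             std::vector<uint64_t>& canon) {
  const std::string& s = g.seqs[i];
  const size_t n = s.size();
  std::vector<uint64_t> hf, hr;
  window_hashes(s, L, hf);
  window_hashes(g.rcs[i], L, hr);
  canon.assign(hf.size(), 0);
  for (size_t p = 0; p < hf.size(); ++p) {
    if (g.bad[i][p + L] - g.bad[i][p] > 0) continue;  // window has N
    uint64_t a = hf[p], b = hr[n - p - L];
    canon[p] = (a < b ? a : b);
    if (canon[p] == 0) canon[p] = 1;  // reserve 0 for "invalid"
  }
}

// For candidate length L: per (seq, window) minimum genome-wide occurrence
// count over valid starts inside the window. Returns for each queried window
// whether a unique (count == 1) start exists.
static void unique_at_L(const MukGenome& g, int L, int window,
                        const std::vector<std::pair<int, int>>& queries,
                        std::vector<bool>& ans) {
  std::unordered_map<uint64_t, uint32_t> counts;
  counts.reserve(1 << 20);
  std::vector<std::vector<uint64_t>> canon(g.seqs.size());
  for (size_t i = 0; i < g.seqs.size(); ++i) {
    canonical_hashes(g, i, L, canon[i]);
    for (uint64_t h : canon[i]) if (h) counts[h]++;
  }
  ans.assign(queries.size(), false);
  for (size_t q = 0; q < queries.size(); ++q) {
    int si = queries[q].first;
    long wstart = (long)queries[q].second * window;
    long wend = std::min<long>(wstart + window, (long)canon[si].size());
    for (long p = wstart; p < wend; ++p) {
      uint64_t h = canon[si][p];
      if (h && counts[h] == 1) { ans[q] = true; break; }
    }
  }
}

// [[Rcpp::export]]
List cpp_muk_track(CharacterVector seqs, int window, int kmin, int cap) {
  MukGenome g;
  const size_t ns = seqs.size();
  g.seqs.resize(ns); g.rcs.resize(ns); g.bad.resize(ns);
  for (size_t i = 0; i < ns; ++i) {
    g.seqs[i] = as<std::string>(seqs[i]);
    std::transform(g.seqs[i].begin(), g.seqs[i].end(), g.seqs[i].begin(), ::toupper);
    g.rcs[i] = revcomp_str(g.seqs[i]);
    const size_t n = g.seqs[i].size();
    g.bad[i].assign(n + 1, 0);
    for (size_t p = 0; p < n; ++p)
      g.bad[i][p + 1] = g.bad[i][p] + (base_code(g.seqs[i][p]) < 0 ? 1 : 0);
  }
  // enumerate windows
  struct W { int seq, win; int lo, hi; bool resolved; };
  std::vector<W> ws;
  for (size_t i = 0; i < ns; ++i) {
    int nw = (int)((g.seqs[i].size() + window - 1) / window);
    for (int w = 0; w < nw; ++w) ws.push_back({(int)i, w, kmin, cap, false});
  }
  // shared first passes: evaluate at kmin, then at cap
  auto eval_group = [&](int L, std::vector<size_t>& idx) {
    std::vector<std::pair<int, int>> q;
    for (size_t j : idx) q.push_back({ws[j].seq, ws[j].win});
    std::vector<bool> ans;
    unique_at_L(g, L, window, q, ans);
    return ans;
  };
  {
    std::vector<size_t> all(ws.size());
    for (size_t j = 0; j < ws.size(); ++j) all[j] = j;
    std::vector<bool> a = eval_group(kmin, all);
    for (size_t j = 0; j < ws.size(); ++j)
      if (a[j]) { ws[j].hi = kmin; ws[j].resolved = true; }
    std::vector<size_t> left;
    for (size_t j = 0; j < ws.size(); ++j) if (!ws[j].resolved) left.push_back(j);
    if (!left.empty()) {
      std::vector<bool> b = eval_group(cap, left);
      for (size_t t = 0; t < left.size(); ++t)
        if (!b[t]) { ws[left[t]].lo = cap; ws[left[t]].hi = cap; ws[left[t]].resolved = true; }
    }
  }
  // simultaneous binary search, grouping windows that share a midpoint
  for (;;) {
    std::unordered_map<int, std::vector<size_t>> groups;
    for (size_t j = 0; j < ws.size(); ++j) {
      if (ws[j].resolved || ws[j].lo + 1 >= ws[j].hi) continue;
      int mid = ws[j].lo + (ws[j].hi - ws[j].lo) / 2;
      groups[mid].push_back(j);
    }
    if (groups.empty()) break;
    for (auto& kv : groups) {
      std::vector<bool> a = eval_group(kv.first, kv.second);
      for (size_t t = 0; t < kv.second.size(); ++t) {
        W& w = ws[kv.second[t]];
        if (a[t]) w.hi = kv.first; else w.lo = kv.first;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  List out(ns);
  std::vector<std::vector<int>> res(ns);
  for (size_t i = 0; i < ns; ++i) {
    int nw = (int)((g.seqs[i].size() + window - 1) / window);
    res[i].assign(nw, cap);
  }
  for (auto& w : ws) {
    int v = (w.lo + 1 >= w.hi && !w.resolved) ? w.hi : w.hi;
    res[w.seq][w.win] = v;
  }
  for (size_t i = 0; i < ns; ++i) out[i] = wrap(res[i]);
  out.attr("names") = seqs.attr("names");
  return out;
}

// ---------------------------------------------------------------------------
// Exact k-mer seed pairs for self-comparison (segmental duplications).
// Emits occurrence pairs of k-mers whose canonical genome-wide count lies in
// [2, max_occ]; over-represented seeds (satellite cores) are skipped.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_seed_pairs(CharacterVector seqs, int k, int max_occ) {
  struct Occ { int seq; int pos; bool fwd_is_canon; };
  std::unordered_map<uint64_t, std::vector<Occ>> occs;
  occs.reserve(1 << 20);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    uint64_t fwd = 0, rc = 0;
    int valid = 0;
    for (size_t i = 0; i < seq.size(); ++i) {
      int c = base_code(seq[i]);
      if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
      if (++valid >= k) {
        uint64_t canon = fwd < rc ? fwd : rc;
        auto& v = occs[canon];
        if ((int)v.size() <= max_occ)  // cap storage; >max_occ seeds dropped later
          v.push_back({(int)s, (int)(i + 1 - k), fwd <= rc});
      }
    }
  }
  std::vector<int> s1, p1, s2, p2;
  std::vector<bool> samestrand;
  for (auto& kv : occs) {
    auto& v = kv.second;
    if (v.size() < 2 || (int)v.size() > max_occ) continue;
    for (size_t a = 0; a < v.size(); ++a)
      for (size_t b = a + 1; b < v.size(); ++b) {
        s1.push_back(v[a].seq); p1.push_back(v[a].pos);
        s2.push_back(v[b].seq); p2.push_back(v[b].pos);
        samestrand.push_back(v[a].fwd_is_canon == v[b].fwd_is_canon);
      }
  }
  return DataFrame::create(_["seq1"] = s1, _["pos1"] = p1,
                           _["seq2"] = s2, _["pos2"] = p2,
                           _["same_strand"] = samestrand);
}
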