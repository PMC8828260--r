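#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Exhaustive short-sequence mapper used for desk-scale alignment of mature
// miRNAs and simulated reads against small genomes. Two modes:
//   mismatch: fixed-length windows, substitutions only, count <= k
//   diff:     unit-cost edit distance (subs + indels) <= k
// One hit is reported per qualifying window start; in diff mode the end is
// the smallest end achieving the minimal distance for that start.
// Candidate generation uses exact pigeonhole seeding (k+1 pieces, one must
// match exactly), which is lossless: no qualifying start can be missed.

static const int BIG = 1 << 28;

static inline int enc(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  default: return -1;  // N (and anything else) never matches
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc(s[i]);
  return v;
}

static std::vector<int> revcomp_enc(const std::vector<int>& q) {
  std::vector<int> r(q.size());
  for (size_t i = 0; i < q.size(); ++i) {
    int b = q[q.size() - 1 - i];
    r[i] = (b < 0) ? -1 : 3 - b;
  }
  return r;
}

static inline bool eq(int a, int b) { return a >= 0 && a == b; }

static inline int count_mm(const std::vector<int>& q, const std::vector<int>& t,
                           int s, int k) {
  int n = 0;
  const int m = (int) q.size();
  for (int i = 0; i < m; ++i) {
    if (!eq(q[i], t[s + i]) && ++n > k) return n;
  }
  return n;
}

// Banded semi-global DP over the window starting at s: D[i][j] = edit
// distance between q[1..i] and t[s..s+j); band j = i + d, d in [-k, k].
static bool verify_diff(const std::vector<int>& q, const std::vector<int>& t,
                        int s, int k, int& best_d, int& best_e) {
  const int m = (int) q.size(), L = (int) t.size();
  const int W = 2 * k + 1;
  std::vector<int> prev(W), cur(W);
  for (int di = 0; di < W; ++di) {
    int d = di - k;
    prev[di] = (d < 0 || s + d > L) ? BIG : d;
  }
  for (int i = 1; i <= m; ++i) {
    for (int di = 0; di < W; ++di) {
      int d = di - k;
      int j = i + d;
      if (j < 0 || s + j > L) { cur[di] = BIG; continue; }
      int best = BIG;
      if (j >= 1 && prev[di] < BIG)  // diagonal: (i-1, j-1) is band (i-1, d)
        best = prev[di] + (eq(q[i - 1], t[s + j - 1]) ? 0 : 1);
      if (di + 1 < W && prev[di + 1] < BIG)  // consume query char only
        best = std::min(best, prev[di + 1] + 1);
      if (di - 1 >= 0 && cur[di - 1] < BIG)  // consume text char only
        best = std::min(best, cur[di - 1] + 1);
      cur[di] = best;
    }
    std::swap(prev, cur);
  }
  best_d = BIG; best_e = -1;
  for (int di = 0; di < W; ++di) {  // ascending d: smallest end wins ties
    int d = di - k, j = m + d;
    if (j < 1 || s + j > L) continue;
    if (prev[di] < best_d) { best_d = prev[di]; best_e = s + j; }
  }
  return best_d <= k;
}

struct GramIndex {
  int G = 0;
  std::unordered_map<uint32_t, std::vector<int>> pos;
};

static void build_index(const std::vector<int>& t, int G, GramIndex& ix) {
  ix.G = G;
  const int L = (int) t.size();
  if (L < G) return;
  const uint32_t mask = (G >= 16) ? 0xffffffffu : ((1u << (2 * G)) - 1u);
  uint32_t key = 0;
  int run = 0;
  for (int i = 0; i < L; ++i) {
    if (t[i] < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint32_t) t[i]) & mask;
    if (++run >= G) ix.pos[key].push_back(i - G + 1);
  }
}

static void map_one(const std::vector<int>& q, const std::vector<int>& t,
                    const GramIndex* ix, int k, bool diff_mode,
                    std::vector<int>& starts, std::vector<int>& ends,
                    std::vector<int>& diffs) {
  const int m = (int) q.size(), L = (int) t.size();
  int min_w = diff_mode ? (m - k) : m;
  if (min_w < 1) min_w = 1;
  const int s_max = L - min_w;
  if (s_max < 0) return;

  auto verify = [&](int s) {
    if (diff_mode) {
      int bd, be;
      if (verify_diff(q, t, s, k, bd, be)) {
        starts.push_back(s); ends.push_back(be); diffs.push_back(bd);
      }
    } else if (s + m <= L) {
      int n = count_mm(q, t, s, k);
      if (n <= k) {
        starts.push_back(s); ends.push_back(s + m); diffs.push_back(n);
      }
    }
  };

  if (!ix || ix->G < 4 || ix->G > m / (k + 1)) {
    for (int s = 0; s <= s_max; ++s) verify(s);
    return;
  }

  const int G = ix->G, np = k + 1;
  std::unordered_set<int> cand;
  for (int p = 0; p < np; ++p) {
    int off = (int) ((long long) p * m / np);
    if (off + G > m) continue;
    uint32_t key = 0;
    bool ok = true;
    for (int j = 0; j < G; ++j) {
      if (q[off + j] < 0) { ok = false; break; }
      key = (key << 2) | (uint32_t) q[off + j];
    }
    if (!ok) continue;
    auto it = ix->pos.find(key);
    if (it == ix->pos.end()) continue;
    const int lo = diff_mode ? -k : 0, hi = diff_mode ? k : 0;
    for (int tp : it->second) {
      for (int sh = lo; sh <= hi; ++sh) {
        int s = tp - off + sh;
        if (s >= 0 && s <= s_max) cand.insert(s);
      }
    }
  }
  std::vector<int> cs(cand.begin(), cand.end());
  std::sort(cs.begin(), cs.end());
  for (int s : cs) verify(s);
}

// [[Rcpp::export]]
DataFrame cpp_map_batch(CharacterVector queries, std::string text, int k,
                        bool diff_mode) {
  std::vector<int> t = encode(text);
  const int L = (int) t.size();
  const int nq = queries.size();
  std::vector<std::vector<int>> qs(nq);
  int min_m = 1 << 30;
  for (int i = 0; i < nq; ++i) {
    qs[i] = encode(as<std::string>(queries[i]));
    min_m = std::min(min_m, (int) qs[i].size());
  }
  int G = (nq == 0) ? 0 : min_m / (k + 1);
  if (G > 15) G = 15;
  const bool use_index = (L >= 5000) && (G >= 4);
  GramIndex ix;
  if (use_index) build_index(t, G, ix);
  const GramIndex* ixp = use_index ? &ix : nullptr;

  std::vector<int> oq, os, oe, od, ostr;
  for (int i = 0; i < nq; ++i) {
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
    for (int strand = 0; strand < 2; ++strand) {
      std::vector<int> q = strand ? revcomp_enc(qs[i]) : qs[i];
      std::vector<int> hs, he, hd;
      map_one(q, t, ixp, k, diff_mode, hs, he, hd);
      for (size_t h = 0; h < hs.size(); ++h) {
        oq.push_back(i + 1);
        os.push_back(hs[h]);
        oe.push_back(he[h]);
        od.push_back(hd[h]);
        ostr.push_back(strand);
      }
    }
  }
  return DataFrame::create(_["qidx"] = oq, _["start"] = os, _["end"] = oe,
                           _["n_diff"] = od, _["minus"] = ostr);
}
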