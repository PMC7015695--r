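// Small compute kernels for the read-level pipelines: ungapped overlap
// merging of read pairs, directional UMI clustering, weighted column-majority
// consensus, CIGAR bookkeeping, and adapter location.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <algorithm>
#include <cstring>
#include <numeric>
using namespace Rcpp;

// Merge R1 with the reverse-complemented R2 by the maximal-scoring ungapped
// overlap (suffix of r1 vs prefix of r2rc).  Overlap score = L - 2*mismatches;
// a candidate is valid when L >= min_overlap and mismatches <= max_mm_frac*L.
// Consensus at disagreeing overlap positions takes the higher-quality base
// (ties keep the R1 base).  q2r must be reversed to match r2rc orientation.
//' @noRd
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector r1, CharacterVector r2rc,
                     CharacterVector q1, CharacterVector q2r,
                     int min_overlap, double max_mm_frac) {
  const int nr = r1.size();
  CharacterVector seq(nr), qual(nr), reason(nr);
  IntegerVector overlap(nr);
  LogicalVector ok(nr);
  for (int r = 0; r < nr; ++r) {
    std::string a = as<std::string>(r1[r]), b = as<std::string>(r2rc[r]);
    std::string qa = as<std::string>(q1[r]), qb = as<std::string>(q2r[r]);
    const int n1 = (int)a.size(), n2 = (int)b.size();
    const int lmax = std::min(n1, n2);
    int best_score = INT_MIN, best_L = -1, best_mm = 0;
    for (int L = lmax; L >= min_overlap; --L) {
      int mm = 0;
      const int off = n1 - L;
      const int allowed = (int)(max_mm_frac * L);
      for (int t = 0; t < L; ++t) {
        if (a[off + t] != b[t] && ++mm > allowed) break;
      }
      if (mm > allowed) continue;
      int sc = L - 2 * mm;
      if (sc > best_score) { best_score = sc; best_L = L; best_mm = mm; }
    }
    if (best_L < 0) {
      ok[r] = false; reason[r] = "no-overlap"; overlap[r] = 0;
      seq[r] = NA_STRING; qual[r] = NA_STRING;
      continue;
    }
    const int off = n1 - best_L;
    std::string ms = a.substr(0, off), mq = qa.substr(0, off);
    for (int t = 0; t < best_L; ++t) {
      char ca = a[off + t], cb = b[t];
      char pa = qa[off + t], pb = qb[t];
      if (ca == cb) { ms += ca; mq += std::max(pa, pb); }
      else if (pb > pa) { ms += cb; mq += pb; }
      else { ms += ca; mq += pa; }
    }
    ms += b.substr(best_L); mq += qb.substr(best_L);
    seq[r] = ms; qual[r] = mq; overlap[r] = best_L; ok[r] = true; reason[r] = NA_STRING;
    (void)best_mm;
  }
  return List::create(_["seq"] = seq, _["qual"] = qual, _["overlap"] = overlap,
                      _["ok"] = ok, _["reason"] = reason);
}

static inline int hamming(const std::string& a, const std::string& b) {
  if (a.size() != b.size()) return INT_MAX;
  int d = 0;
  for (size_t t = 0; t < a.size(); ++t) if (a[t] != b[t]) ++d;
  return d;
}

// UMIs of <= 8 characters pack into a uint64 so Hamming distance 1 reduces to
// "exactly one differing byte"
static inline uint64_t pack8(const std::string& s) {
  uint64_t v = 0;
  std::memcpy(&v, s.data(), s.size());
  return v;
}

static inline bool one_byte_differs(uint64_t x, uint64_t y) {
  uint64_t d = x ^ y;
  if (d == 0) return false;
  const int byte = __builtin_ctzll(d) >> 3; // lowest differing byte
  return (d & ~(0xFFULL << (byte * 8))) == 0;
}

// Directional UMI network clustering (distinct UMIs + read counts):
// edge u -> v when hamming(u, v) == 1 and count(u) >= 2*count(v) - 1.
// Nodes are seeded in (count desc, UMI asc) order; clusters grow by BFS over
// directed edges, visiting candidates in the same deterministic order.
// Returns 1-based cluster ids aligned with the input.
//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_umi_cluster(CharacterVector umis, IntegerVector counts) {
  const int k = umis.size();
  std::vector<std::string> u(k);
  for (int t = 0; t < k; ++t) u[t] = as<std::string>(umis[t]);
  std::vector<int> ord(k);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (counts[a] != counts[b]) return counts[a] > counts[b];
    return u[a] < u[b];
  });
  // adjacency (undirected at distance 1; direction applied during BFS)
  std::vector<std::vector<int>> adj(k);
  bool packable = true;
  for (int t = 0; t < k; ++t)
    if (u[t].size() > 8 || u[t].size() != u[0].size()) { packable = false; break; }
  if (packable) {
    std::vector<uint64_t> pk(k);
    for (int t = 0; t < k; ++t) pk[t] = pack8(u[t]);
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (one_byte_differs(pk[a], pk[b])) { adj[a].push_back(b); adj[b].push_back(a); }
  } else {
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (hamming(u[a], u[b]) == 1) { adj[a].push_back(b); adj[b].push_back(a); }
  }
  std::vector<int> rank(k);
  for (int t = 0; t < k; ++t) rank[ord[t]] = t;
  for (int a = 0; a < k; ++a)
    std::sort(adj[a].begin(), adj[a].end(), [&](int x, int y) { return rank[x] < rank[y]; });

  IntegerVector cluster(k, NA_INTEGER);
  int cid = 0;
  for (int t = 0; t < k; ++t) {
    int seed = ord[t];
    if (cluster[seed] != NA_INTEGER) continue;
    ++cid;
    std::vector<int> queue{seed};
    cluster[seed] = cid;
    size_t qi = 0;
    while (qi < queue.size()) {
      int a = queue[qi++];
      for (int b : adj[a]) {
        if (cluster[b] != NA_INTEGER) continue;
        if (counts[a] >= 2 * counts[b] - 1) { cluster[b] = cid; queue.push_back(b); }
      }
    }
  }
  return cluster;
}

// Weighted per-column majority consensus.  Reads of the (weighted) modal
// length vote; base ties resolve in A < C < G < T order; columns with no
// A/C/G/T vote emit N.
//' @noRd
// [[Rcpp::export]]
String cpp_consensus(CharacterVector seqs, IntegerVector weights) {
  const int nr = seqs.size();
  if (nr == 0) return NA_STRING;
  std::vector<std::string> s(nr);
  for (int t = 0; t < nr; ++t) s[t] = as<std::string>(seqs[t]);
  // weighted modal length (ties -> shorter)
  std::vector<std::pair<size_t,int>> lens;
  for (int t = 0; t < nr; ++t) {
    bool found = false;
    for (auto& pr : lens) if (pr.first == s[t].size()) { pr.second += weights[t]; found = true; break; }
    if (!found) lens.push_back({s[t].size(), weights[t]});
  }
  size_t L = 0; int bw = -1;
  for (auto& pr : lens)
    if (pr.second > bw || (pr.second == bw && pr.first < L)) { L = pr.first; bw = pr.second; }
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string cons(L, 'N');
  std::vector<int> cnt(4);
  for (size_t col = 0; col < L; ++col) {
    cnt.assign(4, 0);
    for (int t = 0; t < nr; ++t) {
      if (s[t].size() != L) continue;
      switch (s[t][col]) {
        case 'A': cnt[0] += weights[t]; break;
        case 'C': cnt[1] += weights[t]; break;
        case 'G': cnt[2] += weights[t]; break;
        case 'T': cnt[3] += weights[t]; break;
      }
    }
    int bi = -1, bc = 0;
    for (int x = 0; x < 4; ++x) if (cnt[x] > bc) { bc = cnt[x]; bi = x; }
    if (bi >= 0) cons[col] = bases[bi];
  }
  return String(cons);
}

// Per-alignment CIGAR bookkeeping: terminal soft clips, aligned (M) read
// length, gap totals, and the largest insertion with its read offset.
//' @noRd
// [[Rcpp::export]]
List cpp_cigar_stats(CharacterVector cigars) {
  const int nr = cigars.size();
  IntegerVector clip_left(nr), clip_right(nr), aligned(nr), ins_total(nr),
      del_total(nr), max_ins(nr), max_ins_pos(nr);
  for (int r = 0; r < nr; ++r) {
    if (cigars[r] == NA_STRING) {
      clip_left[r] = clip_right[r] = aligned[r] = ins_total[r] = del_total[r] =
          max_ins[r] = NA_INTEGER; max_ins_pos[r] = NA_INTEGER;
      continue;
    }
    std::string c = as<std::string>(cigars[r]);
    int readpos = 0, cl = 0, cr = 0, al = 0, it = 0, dt = 0, mi = 0, mip = -1;
    size_t t = 0; bool first = true;
    while (t < c.size()) {
      int len = 0;
      while (t < c.size() && isdigit(c[t])) len = len * 10 + (c[t++] - '0');
      char op = c[t++];
      switch (op) {
        case 'S':
          if (first) cl = len; else cr = len;
          readpos += len; break;
        case 'M': case '=': case 'X': al += len; readpos += len; break;
        case 'I':
          it += len;
          if (len > mi) { mi = len; mip = readpos; }
          readpos += len; break;
        case 'D': dt += len; break;
      }
      first = false;
    }
    clip_left[r] = cl; clip_right[r] = cr; aligned[r] = al;
    ins_total[r] = it; del_total[r] = dt; max_ins[r] = mi; max_ins_pos[r] = mip;
  }
  return List::create(_["clip_left"] = clip_left, _["clip_right"] = clip_right,
                      _["aligned"] = aligned, _["ins_total"] = ins_total,
                      _["del_total"] = del_total, _["max_ins"] = max_ins,
                      _["max_ins_pos"] = max_ins_pos);
}

// Does the alignment contain an indel inside the closed reference window
// [wlo, whi]?  Deleted reference bases count by their base index; insertions
// count by their anchor offset (the between-base position before the next
// reference base).
//' @noRd
// [[Rcpp::export]]
LogicalVector cpp_indel_in_window(CharacterVector cigars, IntegerVector ref_starts,
                                  int wlo, int whi) {
  const int nr = cigars.size();
  LogicalVector out(nr);
  for (int r = 0; r < nr; ++r) {
    if (cigars[r] == NA_STRING) { out[r] = NA_LOGICAL; continue; }
    std::string c = as<std::string>(cigars[r]);
    int refpos = ref_starts[r];
    bool hit = false;
    size_t t = 0;
    while (t < c.size() && !hit) {
      int len = 0;
      while (t < c.size() && isdigit(c[t])) len = len * 10 + (c[t++] - '0');
      char op = c[t++];
      switch (op) {
        case 'M': case '=': case 'X': refpos += len; break;
        case 'D':
          if (refpos <= whi && refpos + len - 1 >= wlo) hit = true;
          refpos += len; break;
        case 'I':
          if (refpos >= wlo && refpos <= whi) hit = true;
          break;
        default: break; // S consumes read only
      }
    }
    out[r] = hit;
  }
  return out;
}

// Locate an adapter in each read with at most max_mm mismatches; the expected
// offset is tried first, then a left-to-right scan.  Returns 0-based offsets,
// -1 when absent.
//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_find_adapter(CharacterVector seqs, std::string adapter,
                               int max_mm, int expected_pos) {
  const int nr = seqs.size();
  const int la = (int)adapter.size();
  IntegerVector out(nr);
  for (int r = 0; r < nr; ++r) {
    std::string s = as<std::string>(seqs[r]);
    const int n = (int)s.size();
    int found = -1;
    auto try_at = [&](int pos) {
      if (pos < 0 || pos + la > n) return false;
      int mm = 0;
      for (int t = 0; t < la; ++t)
        if (s[pos + t] != adapter[t] && ++mm > max_mm) return false;
      return true;
    };
    if (try_at(expected_pos)) found = expected_pos;
    else {
      for (int pos = 0; pos + la <= n; ++pos)
        if (pos != expected_pos && try_at(pos)) { found = pos; break; }
    }
    out[r] = found;
  }
  return out;
}
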