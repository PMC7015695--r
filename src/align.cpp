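// Affine-gap local (Smith-Waterman/Gotoh) alignment core.
//
// Scoring model: match +ma, mismatch -mi, a gap of length L costs go + L*ge
// (the first gapped base pays go+ge).  Coordinates in the results are
// 0-based, half-open on both read and reference.  CIGAR uses M/I/D with
// terminal S for the unaligned read ends (local alignment).
//
// Large problems are handled by exact-seed banding: exact k-mer matches
// between read and reference vote for diagonals; the DP is restricted to a
// band around the voted diagonals.  Reads with no seeds, small problems, or
// over-wide bands fall back to the full DP, so the banded path is a pure
// performance device (verified against the full DP in the test suite).

#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <string>
#include <vector>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

static const int NEG_INF = INT_MIN / 4;

struct AlnParams {
  int ma, mi, go, ge; // match score, mismatch penalty, gap open, gap extend (penalties positive)
};

struct AlnResult {
  int score = 0;
  int ref_start = 0, ref_end = 0;   // 0-based half-open on reference
  int read_start = 0, read_end = 0; // 0-based half-open on read
  int nmatch = 0, nmismatch = 0;
  std::string cigar;
};

// direction byte: bits 0-1 = H move (0 stop, 1 diag, 2 from E/deletion, 3 from F/insertion)
// bit 2 = E extended from E, bit 3 = F extended from F
static thread_local std::vector<uint8_t> g_dir;

// Banded Smith-Waterman with traceback. Band on matrix diagonals d = j - i,
// i in 1..n (read), j in 1..m (ref); cells with d outside [dlo, dhi] are not
// computed.  For a full DP pass dlo = -n, dhi = m.
static AlnResult sw_align(const std::string& read, const std::string& ref,
                          const AlnParams& p, int dlo, int dhi) {
  const int n = (int)read.size(), m = (int)ref.size();
  AlnResult res;
  if (n == 0 || m == 0) { res.cigar = n > 0 ? std::to_string(n) + "S" : ""; return res; }

  const size_t ncell = (size_t)(n + 1) * (size_t)(m + 1);
  if (g_dir.size() < ncell) g_dir.resize(ncell);

  std::vector<int> H(m + 1, 0), F(m + 1, NEG_INF);
  const int oe = p.go + p.ge;

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char rc = read[i - 1];
    int jlo = std::max(1, i + dlo), jhi = std::min(m, i + dhi);
    if (jlo > jhi) continue;
    int E = NEG_INF;
    // H[jlo-1] still holds the previous row's value (band moves right by <=1/row)
    int diag = H[jlo - 1];
    uint8_t* drow = g_dir.data() + (size_t)i * (m + 1);
    for (int j = jlo; j <= jhi; ++j) {
      const int d = j - i;
      uint8_t dir = 0;
      // E: gap in read (D op), needs the left cell inside the band
      if (d > dlo) {
        int e_open = H[j - 1] - oe, e_ext = E - p.ge;
        if (e_ext > e_open) { E = e_ext; dir |= 4; } else { E = e_open; }
      } else E = NEG_INF;
      // F: gap in ref (I op), needs the upper cell inside the band
      int Fj;
      if (d < dhi) {
        int f_open = H[j] - oe, f_ext = F[j] - p.ge;
        if (f_ext > f_open) { Fj = f_ext; dir |= 8; } else { Fj = f_open; }
      } else Fj = NEG_INF;
      F[j] = Fj;
      const int sub = (rc == ref[j - 1]) ? p.ma : -p.mi;
      const int hd = diag + sub;
      // priority on ties: diag > E (deletion) > F (insertion) > stop
      int h = 0; uint8_t mv = 0;
      if (hd > h) { h = hd; mv = 1; }
      if (E > h) { h = E; mv = 2; }
      if (Fj > h) { h = Fj; mv = 3; }
      dir |= mv;
      drow[j] = dir;
      diag = H[j];
      H[j] = h;
      if (h > best || (h == best && best > 0 && (j < bj || (j == bj && i < bi)))) {
        best = h; bi = i; bj = j;
      }
    }
  }

  res.score = best;
  if (best <= 0) { res.cigar = std::to_string(n) + "S"; return res; }

  // traceback
  std::vector<std::pair<char,int>> ops; // reversed
  int i = bi, j = bj;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (true) {
    if (i == 0 || j == 0) break; // DP boundary: alignment start
    if (state == 0) {
      uint8_t d = g_dir[(size_t)i * (m + 1) + j];
      uint8_t mv = d & 3;
      if (mv == 0) break;
      if (mv == 1) {
        if (!ops.empty() && ops.back().first == 'M') ops.back().second++;
        else ops.push_back({'M', 1});
        if (read[i - 1] == ref[j - 1]) res.nmatch++; else res.nmismatch++;
        --i; --j;
      } else if (mv == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // in E: emit D, consume ref
      uint8_t d = g_dir[(size_t)i * (m + 1) + j];
      if (!ops.empty() && ops.back().first == 'D') ops.back().second++;
      else ops.push_back({'D', 1});
      --j;
      if (!(d & 4)) state = 0;
    } else { // in F: emit I, consume read
      uint8_t d = g_dir[(size_t)i * (m + 1) + j];
      if (!ops.empty() && ops.back().first == 'I') ops.back().second++;
      else ops.push_back({'I', 1});
      --i;
      if (!(d & 8)) state = 0;
    }
  }
  res.read_start = i; res.read_end = bi;
  res.ref_start = j;  res.ref_end = bj;

  std::string cig;
  if (res.read_start > 0) cig += std::to_string(res.read_start) + "S";
  for (auto it = ops.rbegin(); it != ops.rend(); ++it)
    cig += std::to_string(it->second) + it->first;
  if (n - res.read_end > 0) cig += std::to_string(n - res.read_end) + "S";
  res.cigar = cig;
  return res;
}

// score-only full Smith-Waterman (rolling arrays)
static int sw_score(const std::string& read, const std::string& ref, const AlnParams& p) {
  const int n = (int)read.size(), m = (int)ref.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> H(m + 1, 0), F(m + 1, NEG_INF);
  const int oe = p.go + p.ge;
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    const char rc = read[i - 1];
    int E = NEG_INF, diag = 0;
    for (int j = 1; j <= m; ++j) {
      E = std::max(H[j - 1] - oe, E - p.ge);
      F[j] = std::max(H[j] - oe, F[j] - p.ge);
      int h = diag + ((rc == ref[j - 1]) ? p.ma : -p.mi);
      if (E > h) h = E;
      if (F[j] > h) h = F[j];
      if (h < 0) h = 0;
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

static inline int base_code(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3; }
  return -1;
}

// k-mer index of the reference: hash -> positions
struct RefIndex {
  int k;
  std::unordered_map<uint32_t, std::vector<int>> pos;
};

static RefIndex build_index(const std::string& ref, int k) {
  RefIndex idx; idx.k = k;
  const int m = (int)ref.size();
  if (m < k) return idx;
  uint32_t h = 0, mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  int valid = 0;
  for (int j = 0; j < m; ++j) {
    int c = base_code(ref[j]);
    if (c < 0) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint32_t)c) & mask;
    if (++valid >= k) idx.pos[h].push_back(j - k + 1);
  }
  return idx;
}

// seed diagonals (matrix convention d = j_ref - i_read, 0-based offsets)
static bool seed_diag_range(const std::string& read, const RefIndex& idx,
                            int& dmin, int& dmax) {
  const int k = idx.k, n = (int)read.size();
  if (n < k || idx.pos.empty()) return false;
  uint32_t h = 0, mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  int valid = 0; bool any = false;
  dmin = INT_MAX; dmax = INT_MIN;
  for (int i = 0; i < n; ++i) {
    int c = base_code(read[i]);
    if (c < 0) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint32_t)c) & mask;
    if (++valid >= k) {
      auto it = idx.pos.find(h);
      if (it != idx.pos.end()) {
        int i0 = i - k + 1;
        for (int j0 : it->second) {
          int d = j0 - i0;
          if (d < dmin) dmin = d;
          if (d > dmax) dmax = d;
          any = true;
        }
      }
    }
  }
  return any;
}

//' @noRd
// [[Rcpp::export]]
List cpp_align_batch(CharacterVector reads, std::string ref,
                     int match, int mismatch, int gap_open, int gap_extend,
                     int k = 15, int pad = 40, double max_full_cells = 1e5,
                     int band_limit = 160, bool force_full = false) {
  AlnParams p{match, mismatch, gap_open, gap_extend};
  const int nr = reads.size();
  RefIndex idx;
  bool have_idx = false;
  IntegerVector score(nr), ref_start(nr), ref_end(nr), read_start(nr), read_end(nr),
      nmatch(nr), nmismatch(nr);
  CharacterVector cigar(nr);
  const int m = (int)ref.size();
  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    const int n = (int)rd.size();
    int dlo = -n, dhi = m;
    if (!force_full && (double)n * (double)m > max_full_cells && n >= k) {
      if (!have_idx) { idx = build_index(ref, k); have_idx = true; }
      int dmin, dmax;
      if (seed_diag_range(rd, idx, dmin, dmax) && (dmax - dmin) <= band_limit) {
        dlo = dmin - pad; dhi = dmax + pad;
      }
    }
    AlnResult a = sw_align(rd, ref, p, dlo, dhi);
    score[r] = a.score; ref_start[r] = a.ref_start; ref_end[r] = a.ref_end;
    read_start[r] = a.read_start; read_end[r] = a.read_end;
    nmatch[r] = a.nmatch; nmismatch[r] = a.nmismatch; cigar[r] = a.cigar;
  }
  return List::create(_["score"] = score, _["ref_start"] = ref_start,
                      _["ref_end"] = ref_end, _["read_start"] = read_start,
                      _["read_end"] = read_end, _["nmatch"] = nmatch,
                      _["nmismatch"] = nmismatch, _["cigar"] = cigar);
}

//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_score_batch(CharacterVector reads, std::string ref,
                              int match, int mismatch, int gap_open, int gap_extend) {
  AlnParams p{match, mismatch, gap_open, gap_extend};
  const int nr = reads.size();
  IntegerVector out(nr);
  for (int r = 0; r < nr; ++r)
    out[r] = sw_score(as<std::string>(reads[r]), ref, p);
  return out;
}
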