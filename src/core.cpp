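// Low-level engine: affine-gap Smith-Waterman with traceback, seeded
// hit scanning over large subjects, k-mer recurrence profiles for tandem
// periodicity, batch short-read mapping, and small sequence utilities.
//
// Conventions: gap of length L costs gap_open + L * gap_extend (penalties
// passed as positive integers); all coordinates returned 1-based inclusive.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

struct AlnResult {
  int score = 0;
  int a_start = 0, a_end = 0, b_start = 0, b_end = 0; // 1-based
  int matches = 0, mismatches = 0, gap_opens = 0, gaps = 0, columns = 0;
  std::string a_aln, b_aln;
};

// Gotoh local alignment. a = query, b = subject. Penalties positive.
static AlnResult sw_align(const std::string &a, const std::string &b,
                          int match, int mismatch, int gap_open, int gap_extend,
                          bool traceback_seqs) {
  const int m = (int)a.size(), n = (int)b.size();
  AlnResult res;
  if (m == 0 || n == 0) return res;
  const int NEG = -1000000000;
  const int go = gap_open + gap_extend; // cost of opening a length-1 gap
  const int ge = gap_extend;

  // rolling-row DP (previous + current row for each state) with a full
  // 1-byte traceback matrix: keeps the working set cache-resident even
  // for large windows, and avoids per-call allocation in scan loops
  static std::vector<int> Mrows, Xrows, Yrows;
  static std::vector<uint8_t> tb;
  const size_t need = (size_t)(m + 1) * (n + 1);
  if (tb.size() < need) tb.resize(need);
  if (Mrows.size() < 2 * (size_t)(n + 1)) {
    Mrows.resize(2 * (size_t)(n + 1));
    Xrows.resize(2 * (size_t)(n + 1));
    Yrows.resize(2 * (size_t)(n + 1));
  }
  int *Mp = Mrows.data(), *Mc = Mrows.data() + (n + 1);
  int *Xp = Xrows.data(), *Xc = Xrows.data() + (n + 1);
  int *Yp = Yrows.data(), *Yc = Yrows.data() + (n + 1);
  for (int j = 0; j <= n; ++j) { Mp[j] = 0; Xp[j] = NEG; Yp[j] = NEG; }
  // traceback byte: 2 bits per state
  // M: 0 = stop, 1 = from M, 2 = from Ix, 3 = from Iy (diagonal move)
  // Ix: bit 0x10 -> from M (open) else from Ix; Iy: 0x20 likewise

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const size_t row = (size_t)i * (n + 1);
    const char ai = a[(size_t)i - 1];
    Mc[0] = 0; Xc[0] = NEG; Yc[0] = NEG;
    for (int j = 1; j <= n; ++j) {
      // Ix: consume a[i], gap in b
      int open_x = Mp[j] - go, ext_x = Xp[j] - ge;
      int ix = open_x >= ext_x ? open_x : ext_x;
      if (ix < NEG) ix = NEG;
      uint8_t t = 0;
      if (open_x >= ext_x) t |= 0x10;
      Xc[j] = ix;
      // Iy: consume b[j], gap in a
      int open_y = Mc[j - 1] - go, ext_y = Yc[j - 1] - ge;
      int iy = open_y >= ext_y ? open_y : ext_y;
      if (iy < NEG) iy = NEG;
      if (open_y >= ext_y) t |= 0x20;
      Yc[j] = iy;
      // M
      const char bj_ = b[(size_t)j - 1];
      int s = (ai == bj_ && ai != 'N' && ai != 'n') ? match : -mismatch;
      int dm = Mp[j - 1], dx = Xp[j - 1], dy = Yp[j - 1];
      int dbest = dm; uint8_t dtag = 1;
      if (dx > dbest) { dbest = dx; dtag = 2; }
      if (dy > dbest) { dbest = dy; dtag = 3; }
      int mm = dbest + s;
      if (mm <= 0) { mm = 0; dtag = 0; }
      Mc[j] = mm;
      tb[row + j] = t | dtag;
      if (mm > best) { best = mm; bi = i; bj = j; }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  res.score = best;
  if (best <= 0) return res;

  // traceback from (bi, bj) in state M
  int i = bi, j = bj, state = 0; // 0 = M, 1 = Ix, 2 = Iy
  std::string aa, bb;
  bool in_gap_run = false;
  while (i > 0 && j > 0) {
    uint8_t t = tb[(size_t)i * (n + 1) + j];
    if (state == 0) {
      uint8_t dtag = t & 0x03;
      if (dtag == 0) break;
      // diagonal consume
      char ca = a[(size_t)i - 1], cb = b[(size_t)j - 1];
      if (traceback_seqs) { aa.push_back(ca); bb.push_back(cb); }
      if (ca == cb && ca != 'N' && ca != 'n') res.matches++; else res.mismatches++;
      res.columns++;
      in_gap_run = false;
      i--; j--;
      if (dtag == 1) state = 0; else if (dtag == 2) state = 1; else state = 2;
      // a dtag of 0 at the next M cell (local start) terminates the walk
    } else if (state == 1) { // Ix: a[i] vs gap
      if (traceback_seqs) { aa.push_back(a[(size_t)i - 1]); bb.push_back('-'); }
      res.gaps++; res.columns++;
      if (!in_gap_run) { res.gap_opens++; in_gap_run = true; }
      bool from_open = (t & 0x10) != 0;
      i--;
      state = from_open ? 0 : 1;
      if (state == 0) in_gap_run = false;
    } else { // Iy: gap vs b[j]
      if (traceback_seqs) { aa.push_back('-'); bb.push_back(b[(size_t)j - 1]); }
      res.gaps++; res.columns++;
      if (!in_gap_run) { res.gap_opens++; in_gap_run = true; }
      bool from_open = (t & 0x20) != 0;
      j--;
      state = from_open ? 0 : 2;
      if (state == 0) in_gap_run = false;
    }
  }
  res.a_start = i + 1; res.a_end = bi;
  res.b_start = j + 1; res.b_end = bj;
  if (traceback_seqs) {
    std::reverse(aa.begin(), aa.end());
    std::reverse(bb.begin(), bb.end());
    res.a_aln = aa; res.b_aln = bb;
  }
  return res;
}

// Banded variant: path offsets o = j - i restricted to
// [center - halfband, center + halfband]. Used by the window scan, where
// the expected copy diagonal is known from the seeds; out-of-band cells
// act as hard stops (NEG), so the traceback can never leave the band.
static AlnResult sw_align_banded(const std::string &a, const std::string &b,
                                 int center, int halfband,
                                 int match, int mismatch, int gap_open,
                                 int gap_extend) {
  const int m = (int)a.size(), n = (int)b.size();
  AlnResult res;
  if (m == 0 || n == 0) return res;
  const int NEG = -1000000000;
  const int go = gap_open + gap_extend;
  const int ge = gap_extend;

  static std::vector<int> Mrows, Xrows, Yrows;
  static std::vector<uint8_t> tb;
  const size_t need = (size_t)(m + 1) * (n + 1);
  if (tb.size() < need) tb.resize(need);
  if (Mrows.size() < 2 * (size_t)(n + 1)) {
    Mrows.resize(2 * (size_t)(n + 1));
    Xrows.resize(2 * (size_t)(n + 1));
    Yrows.resize(2 * (size_t)(n + 1));
  }
  int *Mp = Mrows.data(), *Mc = Mrows.data() + (n + 1);
  int *Xp = Xrows.data(), *Xc = Xrows.data() + (n + 1);
  int *Yp = Yrows.data(), *Yc = Yrows.data() + (n + 1);
  for (int j = 0; j <= n; ++j) { Mp[j] = 0; Xp[j] = NEG; Yp[j] = NEG; }

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const size_t row = (size_t)i * (n + 1);
    const char ai = a[(size_t)i - 1];
    int jlo = i + center - halfband, jhi = i + center + halfband;
    if (jlo < 1) jlo = 1;
    if (jhi > n) jhi = n;
    if (jlo > jhi) { std::swap(Mp, Mc); std::swap(Xp, Xc);
                     std::swap(Yp, Yc); continue; }
    Mc[jlo - 1] = NEG; Xc[jlo - 1] = NEG; Yc[jlo - 1] = NEG;
    if (jlo == 1) Mc[0] = 0;
    for (int j = jlo; j <= jhi; ++j) {
      int open_x = Mp[j] - go, ext_x = Xp[j] - ge;
      int ix = open_x >= ext_x ? open_x : ext_x;
      if (ix < NEG) ix = NEG;
      uint8_t t = 0;
      if (open_x >= ext_x) t |= 0x10;
      Xc[j] = ix;
      int open_y = Mc[j - 1] - go, ext_y = Yc[j - 1] - ge;
      int iy = open_y >= ext_y ? open_y : ext_y;
      if (iy < NEG) iy = NEG;
      if (open_y >= ext_y) t |= 0x20;
      Yc[j] = iy;
      const char bj_ = b[(size_t)j - 1];
      int s = (ai == bj_ && ai != 'N' && ai != 'n') ? match : -mismatch;
      int dm = Mp[j - 1], dx = Xp[j - 1], dy = Yp[j - 1];
      int dbest = dm; uint8_t dtag = 1;
      if (dx > dbest) { dbest = dx; dtag = 2; }
      if (dy > dbest) { dbest = dy; dtag = 3; }
      int mm = dbest + s;
      if (mm <= 0) { mm = 0; dtag = 0; }
      Mc[j] = mm;
      tb[row + j] = t | dtag;
      if (mm > best) { best = mm; bi = i; bj = j; }
    }
    if (jhi + 1 <= n) { Mc[jhi + 1] = NEG; Xc[jhi + 1] = NEG;
                        Yc[jhi + 1] = NEG; }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  res.score = best;
  if (best <= 0) return res;

  int i = bi, j = bj, state = 0;
  while (i > 0 && j > 0) {
    uint8_t t = tb[(size_t)i * (n + 1) + j];
    if (state == 0) {
      uint8_t dtag = t & 0x03;
      if (dtag == 0) break;
      char ca = a[(size_t)i - 1], cb = b[(size_t)j - 1];
      if (ca == cb && ca != 'N' && ca != 'n') res.matches++;
      else res.mismatches++;
      res.columns++;
      i--; j--;
      if (dtag == 1) state = 0; else if (dtag == 2) state = 1; else state = 2;
    } else if (state == 1) {
      res.gaps++; res.columns++;
      if ((t & 0x10) != 0) { res.gap_opens++; state = 0; } else state = 1;
      i--;
    } else {
      res.gaps++; res.columns++;
      if ((t & 0x20) != 0) { res.gap_opens++; state = 0; } else state = 2;
      j--;
    }
  }
  res.a_start = i + 1; res.a_end = bi;
  res.b_start = j + 1; res.b_end = bj;
  return res;
}

static List aln_to_list(const AlnResult &r, bool with_seqs) {
  List out = List::create(
    _["score"] = r.score,
    _["q_start"] = r.a_start, _["q_end"] = r.a_end,
    _["s_start"] = r.b_start, _["s_end"] = r.b_end,
    _["matches"] = r.matches, _["mismatches"] = r.mismatches,
    _["gap_opens"] = r.gap_opens, _["gaps"] = r.gaps,
    _["columns"] = r.columns);
  if (with_seqs) {
    out["q_aln"] = r.a_aln;
    out["s_aln"] = r.b_aln;
  }
  return out;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b, int match, int mismatch,
                  int gap_open, int gap_extend, bool traceback = false) {
  AlnResult r = sw_align(a, b, match, mismatch, gap_open, gap_extend, traceback);
  return aln_to_list(r, traceback);
}

// Seeded scan: find regions of `subject` sharing k-mers with `query`,
// then tile windows (stride = query length, width = 2*qlen + margin) and
// run a local alignment in each. Returns raw window hits; thresholding and
// overlap collapsing happen in R.
// [[Rcpp::export(name = ".scan_windows_cpp")]]
DataFrame scan_windows_cpp(std::string query, std::string subject, int k,
                           int match, int mismatch, int gap_open, int gap_extend,
                           int min_score) {
  const int m = (int)query.size(), n = (int)subject.size();
  std::vector<int> qs_v, qe_v, ss_v, se_v, sc_v, mat_v, mis_v, gpo_v, col_v;
  if (m < k || n < k) {
    return DataFrame::create(_["q_start"] = qs_v, _["q_end"] = qe_v,
                             _["s_start"] = ss_v, _["s_end"] = se_v,
                             _["score"] = sc_v, _["matches"] = mat_v,
                             _["mismatches"] = mis_v, _["gap_opens"] = gpo_v,
                             _["columns"] = col_v);
  }
  // query k-mers with their first query position (for seed diagonals)
  std::unordered_map<uint64_t, int> qk;
  qk.reserve((size_t)m * 2);
  {
    uint64_t key = 0; int valid = 0;
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    for (int i = 0; i < m; ++i) {
      int c = base2bits(query[(size_t)i]);
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++valid >= k) qk.emplace(key, i - k + 1);
    }
  }
  // seeds on the subject: (position, diagonal = spos - qpos)
  std::vector<std::pair<int, int>> seeds; // (spos, diag)
  {
    uint64_t key = 0; int valid = 0;
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    for (int i = 0; i < n; ++i) {
      int c = base2bits(subject[(size_t)i]);
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (valid + 1 >= k) {
        auto it = qk.find(key);
        if (it != qk.end())
          seeds.emplace_back(i - k + 1, i - k + 1 - it->second);
      }
      ++valid;
    }
  }
  if (seeds.empty()) {
    return DataFrame::create(_["q_start"] = qs_v, _["q_end"] = qe_v,
                             _["s_start"] = ss_v, _["s_end"] = se_v,
                             _["score"] = sc_v, _["matches"] = mat_v,
                             _["mismatches"] = mis_v, _["gap_opens"] = gpo_v,
                             _["columns"] = col_v);
  }
  // merge seeds into regions (gap <= qlen); regions backed by a single
  // chance k-mer never trigger alignment, and the requirement grows with
  // query length (a copy at the 70% identity floor still shares ~0.7^k
  // of its k-mers)
  const int gap_tol = m;
  const int min_seeds = std::max(2, m / 250);
  const int slack = std::max(20, m / 20);
  const int diag_gap = std::max(30, m / 2);
  std::vector<std::pair<size_t, size_t>> regions; // index ranges in seeds
  size_t r0 = 0;
  for (size_t idx = 1; idx <= seeds.size(); ++idx) {
    if (idx == seeds.size() ||
        seeds[idx].first - (seeds[idx - 1].first + k) > gap_tol) {
      regions.emplace_back(r0, idx);
      r0 = idx;
    }
  }
  std::vector<int> diags;
  for (auto &rg : regions) {
    if (rg.second - rg.first < (size_t)min_seeds) continue;
    // cluster the region's seed diagonals: one cluster per monomer copy
    diags.clear();
    for (size_t i = rg.first; i < rg.second; ++i)
      diags.push_back(seeds[i].second);
    std::sort(diags.begin(), diags.end());
    size_t c0 = 0;
    for (size_t i = 1; i <= diags.size(); ++i) {
      if (i == diags.size() || diags[i] - diags[i - 1] > diag_gap) {
        size_t cn = i - c0;
        if (cn >= 2) {
          int s0 = diags[c0 + cn / 2]; // median diagonal = copy start
          int w0 = std::max(0, s0 - slack);
          int wend = std::min(n, s0 + m + slack);
          if (wend - w0 >= k) {
            AlnResult r = sw_align_banded(
              query, subject.substr((size_t)w0, (size_t)(wend - w0)),
              s0 - w0, 2 * slack, match, mismatch, gap_open, gap_extend);
            if (r.score >= min_score && r.score > 0) {
              qs_v.push_back(r.a_start); qe_v.push_back(r.a_end);
              ss_v.push_back(r.b_start + w0); se_v.push_back(r.b_end + w0);
              sc_v.push_back(r.score); mat_v.push_back(r.matches);
              mis_v.push_back(r.mismatches); gpo_v.push_back(r.gap_opens);
              col_v.push_back(r.columns);
            }
          }
        }
        c0 = i;
      }
    }
  }
  return DataFrame::create(_["q_start"] = qs_v, _["q_end"] = qe_v,
                           _["s_start"] = ss_v, _["s_end"] = se_v,
                           _["score"] = sc_v, _["matches"] = mat_v,
                           _["mismatches"] = mis_v, _["gap_opens"] = gpo_v,
                           _["columns"] = col_v);
}

// Distance from each position to the previous occurrence of the k-mer
// starting there (0 when first occurrence or k-mer spans an invalid base).
// [[Rcpp::export(name = ".kmer_dist_profile_cpp")]]
IntegerVector kmer_dist_profile_cpp(std::string seq, int k) {
  const int n = (int)seq.size();
  IntegerVector out(std::max(0, n - k + 1), 0);
  if (n < k) return out;
  std::unordered_map<uint64_t, int> last;
  last.reserve((size_t)n);
  uint64_t key = 0; int valid = 0;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int i = 0; i < n; ++i) {
    int c = base2bits(seq[(size_t)i]);
    if (c < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++valid >= k) {
      int pos = i - k + 1; // 0-based k-mer start
      auto it = last.find(key);
      if (it != last.end()) out[pos] = pos - it->second;
      last[key] = pos;
    }
  }
  return out;
}

// Batch best-hit mapping of reads against a small set of tandemized
// references (both orientations supplied by caller as separate entries).
// Returns one row per mapped read: read index, reference index, score and
// subject interval on the tandemized reference.
// [[Rcpp::export(name = ".map_reads_cpp")]]
DataFrame map_reads_cpp(CharacterVector reads, CharacterVector refs, int k,
                        int match, int mismatch, int gap_open, int gap_extend,
                        int min_score, int window_margin) {
  const int nref = refs.size();
  std::vector<std::string> refstr(nref);
  for (int r = 0; r < nref; ++r) refstr[r] = as<std::string>(refs[r]);
  // index: kmer -> (ref, first position)
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int r = 0; r < nref; ++r) {
    const std::string &s = refstr[r];
    std::unordered_set<uint64_t> seen;
    uint64_t key = 0; int valid = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int c = base2bits(s[(size_t)i]);
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++valid >= k && seen.insert(key).second)
        index[key].emplace_back(r, i - k + 1);
    }
  }
  std::vector<int> read_i, ref_i, sc_v, ss_v, se_v, qs_v, qe_v;
  const int nreads = reads.size();
  std::vector<int> cand_pos_min(nref), cand_pos_max(nref), cand_count(nref);
  for (int ri = 0; ri < nreads; ++ri) {
    std::string rd = as<std::string>(reads[ri]);
    std::fill(cand_count.begin(), cand_count.end(), 0);
    uint64_t key = 0; int valid = 0;
    for (int i = 0; i < (int)rd.size(); ++i) {
      int c = base2bits(rd[(size_t)i]);
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++valid >= k) {
        auto it = index.find(key);
        if (it == index.end()) continue;
        for (auto &pr : it->second) {
          int r = pr.first, p = pr.second;
          if (cand_count[r] == 0) { cand_pos_min[r] = p; cand_pos_max[r] = p; }
          else {
            if (p < cand_pos_min[r]) cand_pos_min[r] = p;
            if (p > cand_pos_max[r]) cand_pos_max[r] = p;
          }
          cand_count[r]++;
        }
      }
    }
    int best_score = 0, best_ref = -1;
    AlnResult best_aln; int best_off = 0;
    for (int r = 0; r < nref; ++r) {
      if (cand_count[r] < 2) continue;
      const std::string &s = refstr[r];
      int w0 = std::max(0, cand_pos_min[r] - window_margin);
      int w1 = std::min((int)s.size(), cand_pos_max[r] + k + window_margin);
      if (w1 - w0 < k) continue;
      AlnResult a = sw_align(rd, s.substr((size_t)w0, (size_t)(w1 - w0)),
                             match, mismatch, gap_open, gap_extend, false);
      if (a.score > best_score) {
        best_score = a.score; best_ref = r; best_aln = a; best_off = w0;
      }
    }
    if (best_ref >= 0 && best_score >= min_score) {
      read_i.push_back(ri + 1);
      ref_i.push_back(best_ref + 1);
      sc_v.push_back(best_score);
      qs_v.push_back(best_aln.a_start); qe_v.push_back(best_aln.a_end);
      ss_v.push_back(best_aln.b_start + best_off);
      se_v.push_back(best_aln.b_end + best_off);
    }
  }
  return DataFrame::create(_["read"] = read_i, _["ref"] = ref_i,
                           _["score"] = sc_v,
                           _["q_start"] = qs_v, _["q_end"] = qe_v,
                           _["s_start"] = ss_v, _["s_end"] = se_v);
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j) {
      char c = s[s.size() - 1 - j], o;
      switch (c) {
      case 'A': o = 'T'; break; case 'a': o = 't'; break;
      case 'C': o = 'G'; break; case 'c': o = 'g'; break;
      case 'G': o = 'C'; break; case 'g': o = 'c'; break;
      case 'T': o = 'A'; break; case 't': o = 'a'; break;
      default: o = 'N';
      }
      r[j] = o;
    }
    out[i] = r;
  }
  out.attr("names") = x.attr("names");
  return out;
}

// 1-based start positions where `primer` matches `tmpl` with at most
// max_mm mismatches (no indels; N never matches).
// [[Rcpp::export(name = ".primer_match_cpp")]]
IntegerVector primer_match_cpp(std::string tmpl, std::string primer, int max_mm) {
  const int n = (int)tmpl.size(), m = (int)primer.size();
  std::vector<int> hits;
  for (int i = 0; i + m <= n; ++i) {
    int mm = 0;
    for (int j = 0; j < m; ++j) {
      char a = tmpl[(size_t)(i + j)], b = primer[(size_t)j];
      if (a != b || a == 'N' || a == 'n') { if (++mm > max_mm) break; }
    }
    if (mm <= max_mm) hits.push_back(i + 1);
  }
  return wrap(hits);
}

// Rotation r (0-based) of `unit` minimizing Hamming distance to `ref`
// over the shorter length.
// [[Rcpp::export(name = ".best_rotation_cpp")]]
int best_rotation_cpp(std::string unit, std::string ref) {
  const int p = (int)unit.size();
  const int L = std::min(p, (int)ref.size());
  int best_r = 0, best_d = L + 1;
  for (int r = 0; r < p; ++r) {
    int d = 0;
    for (int j = 0; j < L; ++j) {
      if (unit[(size_t)((j + r) % p)] != ref[(size_t)j]) {
        if (++d >= best_d) break;
      }
    }
    if (d < best_d) { best_d = d; best_r = r; }
  }
  return best_r;
}
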