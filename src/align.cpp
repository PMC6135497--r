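#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>

using namespace Rcpp;

// DNA alphabet handling: only A,C,G,T participate in matches; any other
// IUPAC code (ambiguity, N) is scored as a mismatch and never counted as a
// compared site.
static inline int baseCode(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

// ---------------------------------------------------------------------------
// Overlap (free end-gap) Needleman-Wunsch with linear gap penalty.
//
// Tie-breaks are fixed so results are deterministic:
//   * within a cell: diagonal (match/mismatch), then gap-in-a, then gap-in-b;
//   * for the end point: best score over last row/column, ties resolved
//     towards the bottom-right corner (larger i+j, then larger i).
// Compared sites are columns where both characters are unambiguous bases;
// end gaps and ambiguity columns are excluded (pairwise deletion).
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".nw_overlap_cpp")]]
List nw_overlap_cpp(std::string a, std::string b,
                    double match, double mismatch, double gap) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");

  std::vector<double> H((size_t)(n + 1) * (m + 1));
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1)); // 1=diag, 2=left(gap in a), 3=up(gap in b)
  auto at = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  for (int j = 0; j <= m; ++j) { H[at(0, j)] = 0.0; tb[at(0, j)] = 2; }
  for (int i = 0; i <= n; ++i) { H[at(i, 0)] = 0.0; tb[at(i, 0)] = 3; }

  for (int i = 1; i <= n; ++i) {
    const int ca = baseCode(a[i - 1]);
    for (int j = 1; j <= m; ++j) {
      const int cb = baseCode(b[j - 1]);
      const double s = (ca >= 0 && ca == cb) ? match : mismatch;
      const double d = H[at(i - 1, j - 1)] + s;
      const double l = H[at(i, j - 1)] + gap; // gap in a
      const double u = H[at(i - 1, j)] + gap; // gap in b
      double best = d; uint8_t t = 1;
      if (l > best) { best = l; t = 2; }
      if (u > best) { best = u; t = 3; }
      H[at(i, j)] = best; tb[at(i, j)] = t;
    }
  }

  // end point: free end gaps -> max over last row and last column
  int ei = n, ej = m; double bestScore = H[at(n, m)];
  for (int j = 0; j <= m; ++j) {
    double v = H[at(n, j)];
    if (v > bestScore || (v == bestScore && (n + j > ei + ej || (n + j == ei + ej && n > ei)))) {
      bestScore = v; ei = n; ej = j;
    }
  }
  for (int i = 0; i <= n; ++i) {
    double v = H[at(i, m)];
    if (v > bestScore || (v == bestScore && (i + m > ei + ej || (i + m == ei + ej && i > ei)))) {
      bestScore = v; ei = i; ej = m;
    }
  }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  // trailing free end gaps
  for (int i = n; i > ei; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
  for (int j = m; j > ej; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }
  int i = ei, j = ej;
  while (i > 0 && j > 0) {
    const uint8_t t = tb[at(i, j)];
    if (t == 1)      { ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j; }
    else if (t == 2) { ra.push_back('-');      rb.push_back(b[j - 1]); --j; }
    else             { ra.push_back(a[i - 1]); rb.push_back('-');      --i; }
  }
  while (i > 0) { ra.push_back(a[i - 1]); rb.push_back('-'); --i; }
  while (j > 0) { ra.push_back('-'); rb.push_back(b[j - 1]); --j; }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  int compared = 0, diffs = 0;
  for (size_t k = 0; k < ra.size(); ++k) {
    const int x = baseCode(ra[k]), y = baseCode(rb[k]);
    if (x >= 0 && y >= 0) { ++compared; if (x != y) ++diffs; }
  }

  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = bestScore,
                      _["n_compared_sites"] = compared,
                      _["n_differences"] = diffs);
}

// ---------------------------------------------------------------------------
// Smith-Waterman local alignment with affine gaps (Gotoh).
// A gap of length L costs |gap_open| + L * |gap_extend| (BLASTN convention;
// penalties are passed as negative numbers). Traceback tie-break within a
// cell: diagonal, then up (gap in subject), then left (gap in read). The
// maximal cell is the first encountered in row-major order.
// ---------------------------------------------------------------------------
struct SWResult {
  int raw_score = 0, matches = 0, aligned_cols = 0;
  int read_start = 0, read_end = 0, sub_start = 0, sub_end = 0;
  bool found = false;
};

static SWResult sw_affine(const std::string& a, const std::string& b,
                          int match, int mismatch, int gap_open, int gap_extend,
                          bool traceback) {
  const int n = (int)a.size(), m = (int)b.size();
  SWResult res;
  if (n == 0 || m == 0) return res;
  const int open_first = gap_open + gap_extend; // cost of the first gap column
  const int NEG = -1000000000;

  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0), Eprev(m + 1, NEG), Ecur(m + 1, NEG),
      Fprev(m + 1, NEG), Fcur(m + 1, NEG);
  // packed traceback: bits 0-1 H origin (0 stop, 1 diag, 2 up/F, 3 left/E),
  // bit 2: E extends E, bit 3: F extends F
  std::vector<uint8_t> tb;
  if (traceback) tb.assign((size_t)(n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  int bi = 0, bj = 0, bscore = 0;
  for (int i = 1; i <= n; ++i) {
    const int ca = baseCode(a[i - 1]);
    Hcur[0] = 0; Ecur[0] = NEG; Fcur[0] = NEG;
    uint8_t* tbrow = traceback ? &tb[at(i, 0)] : nullptr;
    for (int j = 1; j <= m; ++j) {
      const int cb = baseCode(b[j - 1]);
      const int s = (ca >= 0 && ca == cb) ? match : mismatch;

      int e_open = Hcur[j - 1] + open_first, e_ext = Ecur[j - 1] + gap_extend;
      const int e = e_open >= e_ext ? e_open : e_ext;          // gap in read (left)
      int f_open = Hprev[j] + open_first, f_ext = Fprev[j] + gap_extend;
      const int f = f_open >= f_ext ? f_open : f_ext;          // gap in subject (up)
      const int d = Hprev[j - 1] + s;

      // strict '>' updates give the tie-break priority: diagonal, up, left
      int h = 0; uint8_t t = 0;
      if (d > h) { h = d; t = 1; }
      if (f > h) { h = f; t = 2; }
      if (e > h) { h = e; t = 3; }

      Hcur[j] = h; Ecur[j] = e; Fcur[j] = f;
      if (traceback) {
        uint8_t code = t;
        if (e_ext > e_open) code |= 4;
        if (f_ext > f_open) code |= 8;
        tbrow[j] = code;
      }
      if (h > bscore) { bscore = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }

  res.raw_score = bscore;
  if (bscore <= 0) return res;
  res.found = true;
  if (!traceback) { res.read_end = bi; res.sub_end = bj; return res; }

  enum { H_ST, E_ST, F_ST };
  int i = bi, j = bj, state = H_ST;
  int matches = 0, cols = 0;
  while (i > 0 && j > 0) {
    const uint8_t code = tb[at(i, j)];
    if (state == H_ST) {
      const uint8_t t = code & 3;
      if (t == 0) break;
      if (t == 1) {
        ++cols;
        const int x = baseCode(a[i - 1]), y = baseCode(b[j - 1]);
        if (x >= 0 && x == y) ++matches;
        --i; --j;
      } else if (t == 2) state = F_ST;
      else state = E_ST;
    } else if (state == E_ST) { // gap in read, consume subject
      ++cols;
      state = (code & 4) ? E_ST : H_ST;
      --j;
    } else {                    // gap in subject, consume read
      ++cols;
      state = (code & 8) ? F_ST : H_ST;
      --i;
    }
  }
  res.matches = matches; res.aligned_cols = cols;
  res.read_start = i; res.read_end = bi;   // 0-based half-open on the read
  res.sub_start = j;  res.sub_end = bj;    // 0-based half-open on the subject
  return res;
}

// [[Rcpp::export(name = ".sw_affine_cpp")]]
List sw_affine_cpp(std::string read, std::string subject,
                   int match, int mismatch, int gap_open, int gap_extend) {
  if (read.empty() || subject.empty()) stop("sequences must be non-empty");
  SWResult r = sw_affine(read, subject, match, mismatch, gap_open, gap_extend, true);
  return List::create(_["raw_score"] = r.raw_score, _["matches"] = r.matches,
                      _["aligned_cols"] = r.aligned_cols,
                      _["read_start"] = r.read_start, _["read_end"] = r.read_end,
                      _["sub_start"] = r.sub_start, _["sub_end"] = r.sub_end);
}

// k-mer index: 2-bit encoding, k-mers containing ambiguity codes skipped.
static void candidateSubjects(const std::string& read, int k,
                              const std::unordered_map<uint64_t, std::vector<int>>& index,
                              std::vector<char>& seen, std::vector<int>& cand) {
  const int n = (int)read.size();
  uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    const int c = baseCode(read[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run < k) continue;
    auto it = index.find(key);
    if (it == index.end()) continue;
    for (int s : it->second) {
      if (!seen[s]) { seen[s] = 1; cand.push_back(s); }
    }
  }
}

// ---------------------------------------------------------------------------
// Batch local-alignment search of reads against subjects. With prefilter,
// only subjects sharing at least one exact k-mer with the read are aligned.
// Returns one row per (read, subject) local alignment with positive score.
// Indices in the result are 1-based; spans are 0-based half-open.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".sw_search_cpp")]]
DataFrame sw_search_cpp(CharacterVector reads, CharacterVector subjects,
                        int match, int mismatch, int gap_open, int gap_extend,
                        int kmer, bool prefilter) {
  const int nsub = subjects.size(), nread = reads.size();
  std::vector<std::string> subj(nsub);
  for (int s = 0; s < nsub; ++s) subj[s] = as<std::string>(subjects[s]);

  std::unordered_map<uint64_t, std::vector<int>> index;
  if (prefilter) {
    for (int s = 0; s < nsub; ++s) {
      const std::string& seq = subj[s];
      uint64_t key = 0, mask = (kmer < 32) ? ((1ULL << (2 * kmer)) - 1) : ~0ULL;
      int run = 0;
      for (size_t i = 0; i < seq.size(); ++i) {
        const int c = baseCode(seq[i]);
        if (c < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & mask;
        if (++run < kmer) continue;
        std::vector<int>& v = index[key];
        if (v.empty() || v.back() != s) v.push_back(s);
      }
    }
  }

  std::vector<int> out_read, out_sub, out_raw, out_matches, out_cols,
      out_rs, out_re, out_ss, out_se;
  std::vector<char> seen(nsub, 0);
  std::vector<int> cand;

  for (int r = 0; r < nread; ++r) {
    const std::string read = as<std::string>(reads[r]);
    cand.clear();
    if (prefilter) {
      candidateSubjects(read, kmer, index, seen, cand);
      for (int s : cand) seen[s] = 0;
    } else {
      for (int s = 0; s < nsub; ++s) cand.push_back(s);
    }
    for (int s : cand) {
      SWResult a = sw_affine(read, subj[s], match, mismatch, gap_open, gap_extend, true);
      if (!a.found) continue;
      out_read.push_back(r + 1); out_sub.push_back(s + 1);
      out_raw.push_back(a.raw_score); out_matches.push_back(a.matches);
      out_cols.push_back(a.aligned_cols);
      out_rs.push_back(a.read_start); out_re.push_back(a.read_end);
      out_ss.push_back(a.sub_start); out_se.push_back(a.sub_end);
    }
    if ((r & 63) == 0) Rcpp::checkUserInterrupt();
  }

  return DataFrame::create(_["read"] = out_read, _["subject"] = out_sub,
                           _["raw_score"] = out_raw, _["matches"] = out_matches,
                           _["aligned_cols"] = out_cols,
                           _["read_start"] = out_rs, _["read_end"] = out_re,
                           _["sub_start"] = out_ss, _["sub_end"] = out_se);
}
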