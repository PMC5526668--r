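#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Both scanners report *maximal* mismatch-bounded windows along diagonals of
// the self-comparison matrix: for a diagonal (offset) d, the line compares
// s[i] with s[i + d]. A window [i, i+L) is maximal when neither end can be
// extended without exceeding the mismatch budget. Gap/length filtering and
// overlap merging happen at the R level, shared by both routes.

static void emit(std::vector<int> &out, int i, int d, int len, int mm,
                 int min_len) {
  if (len >= min_len) {
    out.push_back(i);
    out.push_back(i + d);
    out.push_back(len);
    out.push_back(mm);
  }
}

// Enumerate maximal windows on one diagonal from its mismatch positions.
// With K mismatches on a line of length len and budget m, the maximal
// windows are (M[j-1]+1 .. M[j+m]-1) for j = 0..K-m (sentinels M[-1] = -1,
// M[K] = len); if K <= m the whole line is the single maximal window.
static void diagonal_windows(const char *s, int n, int d, int max_mm,
                             int min_len, std::vector<int> &out) {
  int len = n - d;
  if (len < min_len) return;
  std::vector<int> mis;
  for (int i = 0; i < len; ++i)
    if (s[i] != s[i + d]) mis.push_back(i);
  int K = (int)mis.size();
  if (K <= max_mm) {
    emit(out, 0, d, len, K, min_len);
    return;
  }
  for (int j = 0; j + max_mm <= K; ++j) {
    int l = (j == 0) ? 0 : mis[j - 1] + 1;
    int r = (j + max_mm == K) ? len : mis[j + max_mm]; // exclusive end
    emit(out, l, d, r - l, max_mm, min_len);
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_repeat_scan_seeded(std::string seq, int min_len, int max_mm,
                                     int kmer, int max_kmer_occ) {
  const char *s = seq.c_str();
  int n = (int)seq.size();
  std::vector<int> out;
  if (n >= 2 * kmer) {
    // hash exact k-mers (2 bits per base) to collect candidate diagonals
    std::unordered_map<uint64_t, std::vector<int> > pos;
    uint64_t key = 0, mask = (kmer >= 32) ? ~0ULL : ((1ULL << (2 * kmer)) - 1);
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int code;
      switch (s[i]) {
      case 'A': code = 0; break;
      case 'C': code = 1; break;
      case 'G': code = 2; break;
      case 'T': code = 3; break;
      default: code = -1;
      }
      if (code < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)code) & mask;
      if (++run >= kmer) pos[key].push_back(i - kmer + 1);
    }
    std::unordered_set<int> diags;
    for (std::unordered_map<uint64_t, std::vector<int> >::iterator it = pos.begin();
         it != pos.end(); ++it) {
      std::vector<int> &v = it->second;
      if ((int)v.size() < 2 || (int)v.size() > max_kmer_occ) continue;
      for (size_t a = 0; a + 1 < v.size(); ++a)
        for (size_t b = a + 1; b < v.size(); ++b)
          diags.insert(v[b] - v[a]);
    }
    for (std::unordered_set<int>::iterator it = diags.begin();
         it != diags.end(); ++it)
      diagonal_windows(s, n, *it, max_mm, min_len, out);
  }
  IntegerMatrix m((int)out.size() / 4, 4);
  for (int i = 0; i < m.nrow(); ++i)
    for (int j = 0; j < 4; ++j) m(i, j) = out[4 * i + j];
  colnames(m) = CharacterVector::create("start1", "start2", "length", "hamming");
  return m;
}

// Exhaustive reference scan: every diagonal, start-anchored greedy forward
// extension from every position, keeping only left-maximal windows. This is
// an independent enumeration of the same maximal-window set, used as the
// brute-force oracle for the seeded scanner.
// [[Rcpp::export]]
IntegerMatrix cpp_repeat_scan_exhaustive(std::string seq, int min_len,
                                         int max_mm) {
  const char *s = seq.c_str();
  int n = (int)seq.size();
  std::vector<int> out;
  for (int d = 1; d < n; ++d) {
    int len = n - d;
    if (len < min_len) break;
    for (int i = 0; i < len; ++i) {
      // greedy forward from i with mismatch budget
      int mm = 0, j = i;
      while (j < len) {
        if (s[j] != s[j + d]) {
          if (mm == max_mm) break;
          ++mm;
        }
        ++j;
      }
      int L = j - i;
      if (L < min_len) continue;
      // left-maximal: at the line start, or extending left would exceed budget
      bool leftmax = (i == 0) || (s[i - 1] != s[i - 1 + d] && mm == max_mm);
      if (!leftmax) continue;
      emit(out, i, d, L, mm, min_len);
    }
  }
  IntegerMatrix m((int)out.size() / 4, 4);
  for (int i = 0; i < m.nrow(); ++i)
    for (int j = 0; j < 4; ++j) m(i, j) = out[4 * i + j];
  colnames(m) = CharacterVector::create("start1", "start2", "length", "hamming");
  return m;
}
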