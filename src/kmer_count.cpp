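#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit encoding; -1 marks ambiguity codes, which invalidate every window
// they fall into.
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

// Sparse k-mer counter over overlapping windows (step 1), forward strand,
// per contig. Windows containing a non-ACGT character are skipped; no
// window spans a contig junction. Codes are returned as doubles, exact for
// k <= 26 (2k <= 52 mantissa bits).
// [[Rcpp::export(name = ".count_kmers_cpp")]]
List count_kmers_cpp(CharacterVector contigs, int k) {
  if (k < 1 || k > 26)
    stop("k must be between 1 and 26");
  std::unordered_map<uint64_t, double> tab;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  double total = 0.0;
  for (R_xlen_t ci = 0; ci < contigs.size(); ++ci) {
    const char *s = CHAR(STRING_ELT(contigs, ci));
    R_xlen_t n = LENGTH(STRING_ELT(contigs, ci));
    uint64_t code = 0;
    int run = 0;  // length of current ambiguity-free run
    for (R_xlen_t i = 0; i < n; ++i) {
      int b = base_code(s[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run >= k) { tab[code] += 1.0; total += 1.0; }
    }
  }
  std::vector<std::pair<uint64_t, double> > items(tab.begin(), tab.end());
  std::sort(items.begin(), items.end());
  R_xlen_t m = (R_xlen_t)items.size();
  NumericVector codes(m), counts(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    codes[i] = (double)items[i].first;
    counts[i] = items[i].second;
  }
  return List::create(_["codes"] = codes, _["counts"] = counts,
                      _["total_windows"] = total);
}

// Counts of A, C, G, T and other characters across contigs.
// [[Rcpp::export(name = ".base_counts_cpp")]]
NumericVector base_counts_cpp(CharacterVector contigs) {
  double acgt[4] = {0, 0, 0, 0};
  double other = 0;
  for (R_xlen_t ci = 0; ci < contigs.size(); ++ci) {
    const char *s = CHAR(STRING_ELT(contigs, ci));
    R_xlen_t n = LENGTH(STRING_ELT(contigs, ci));
    for (R_xlen_t i = 0; i < n; ++i) {
      int b = base_code(s[i]);
      if (b < 0) other += 1.0; else acgt[b] += 1.0;
    }
  }
  NumericVector out = NumericVector::create(
    _["A"] = acgt[0], _["C"] = acgt[1], _["G"] = acgt[2], _["T"] = acgt[3],
    _["other"] = other);
  return out;
}

// Decode numeric 2-bit codes back to k-mer strings.
// [[Rcpp::export(name = ".decode_kmers_cpp")]]
CharacterVector decode_kmers_cpp(NumericVector codes, int k) {
  static const char letters[4] = {'A', 'C', 'G', 'T'};
  R_xlen_t m = codes.size();
  CharacterVector out(m);
  std::vector<char> buf(k + 1, '\0');
  for (R_xlen_t i = 0; i < m; ++i) {
    uint64_t code = (uint64_t)codes[i];
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = letters[code & 3ULL];
      code >>= 2;
    }
    out[i] = std::string(buf.data(), k);
  }
  return out;
}
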