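#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// IUPAC nucleotide bitmasks: A=1, C=2, G=4, T=8.
static inline int iupac_mask(char c) {
  switch (c) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;  case 'T': return 8;
    case 'U': return 8;
    case 'R': return 1|4; case 'Y': return 2|8; case 'S': return 2|4; case 'W': return 1|8;
    case 'K': return 4|8; case 'M': return 1|2;
    case 'B': return 2|4|8; case 'D': return 1|4|8; case 'H': return 1|2|8; case 'V': return 1|2|4;
    case 'N': return 15;
    default:  return 0;  // never matches
  }
}

//' Best approximate occurrence of a (possibly degenerate) pattern in a subject
//'
//' Semi-global edit-distance search: the whole pattern is aligned against any
//' substring of the subject (free leading and trailing subject bases). A
//' degenerate IUPAC position in the pattern matches any base of its code set
//' at zero cost; substitutions, insertions and deletions each cost 1.
//'
//' @param pattern pattern string (IUPAC DNA, uppercase)
//' @param subject subject string (uppercase DNA)
//' @return integer vector (distance, start, end): 1-based inclusive subject
//'   coordinates of the best-scoring occurrence. Ties are broken towards the
//'   smallest end coordinate, then the longest occurrence. For an empty
//'   subject, distance is the pattern length and start/end are 0.
//' @keywords internal
// [[Rcpp::export(name = ".cpp_edit_search")]]
IntegerVector cpp_edit_search(std::string pattern, std::string subject) {
  const int m = pattern.size(), n = subject.size();
  if (m == 0) stop("empty pattern");
  if (n == 0) return IntegerVector::create(m, 0, 0);

  std::vector<int> pmask(m);
  for (int i = 0; i < m; ++i) pmask[i] = iupac_mask(pattern[i]);
  std::vector<int> smask(n);
  for (int j = 0; j < n; ++j) smask[j] = iupac_mask(subject[j]);

  // D[i][j]: best edit distance of pattern[0..i) vs a subject substring ending at j.
  // O[i][j]: start column (0-based, exclusive prefix length) of that substring.
  std::vector<int> prev(n + 1), cur(n + 1), oprev(n + 1), ocur(n + 1);
  for (int j = 0; j <= n; ++j) { prev[j] = 0; oprev[j] = j; }
  for (int i = 1; i <= m; ++i) {
    cur[0] = i; ocur[0] = 0;
    for (int j = 1; j <= n; ++j) {
      int sub = prev[j - 1] + ((pmask[i - 1] & smask[j - 1]) ? 0 : 1);
      int del = prev[j] + 1;   // pattern base unmatched (deletion in subject)
      int ins = cur[j - 1] + 1; // extra subject base (insertion)
      int best = sub, org = oprev[j - 1];
      if (del < best) { best = del; org = oprev[j]; }
      if (ins < best) { best = ins; org = ocur[j - 1]; }
      // prefer earlier start on ties (longer occurrence)
      if (del == best && oprev[j] < org) org = oprev[j];
      if (ins == best && ocur[j - 1] < org) org = ocur[j - 1];
      cur[j] = best; ocur[j] = org;
    }
    std::swap(prev, cur); std::swap(oprev, ocur);
  }
  int bd = prev[1], bend = 1, borg = oprev[1];
  for (int j = 1; j <= n; ++j) {
    if (prev[j] < bd) { bd = prev[j]; bend = j; borg = oprev[j]; }
  }
  if (prev[0] < bd) { bd = prev[0]; bend = 0; borg = 0; }
  return IntegerVector::create(bd, borg + 1, bend);
}
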