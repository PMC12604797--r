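#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Unit-cost semi-global alignment of a member read against a cluster
// representative: the member is aligned end-to-end, leading and trailing
// representative bases are free. Used for greedy-cluster identity and for
// consensus voting in representative coordinates.
//
// Returns: spos/epos (1-based first/last representative position consumed),
// aligned (member in representative coordinates, '-' at deletions),
// ins_pos / ins_str (insertion runs attaching BEFORE representative position
// ins_pos), matches, columns (alignment columns incl. insertions).
// [[Rcpp::export(name = ".cpp_align_to_rep")]]
List cpp_align_to_rep(std::string member, std::string rep) {
  const int m = member.size(), L = rep.size();
  if (m == 0 || L == 0) stop("empty sequence in alignment");
  // D: (m+1) x (L+1); tb: 0 diag, 1 up (insertion), 2 left (deletion)
  std::vector<int> D((m + 1) * (L + 1));
  std::vector<unsigned char> tb((m + 1) * (L + 1));
  const int W = L + 1;
  for (int j = 0; j <= L; ++j) { D[j] = 0; tb[j] = 2; }
  for (int i = 1; i <= m; ++i) { D[i * W] = i; tb[i * W] = 1; }
  for (int i = 1; i <= m; ++i) {
    const char mc = member[i - 1];
    for (int j = 1; j <= L; ++j) {
      int diag = D[(i - 1) * W + j - 1] + (mc == rep[j - 1] ? 0 : 1);
      int up = D[(i - 1) * W + j] + 1;
      int left = D[i * W + j - 1] + 1;
      int best = diag; unsigned char t = 0;
      if (up < best) { best = up; t = 1; }
      if (left < best) { best = left; t = 2; }
      D[i * W + j] = best; tb[i * W + j] = t;
    }
  }
  int jend = L;
  for (int j = 0; j <= L; ++j) if (D[m * W + j] < D[m * W + jend]) jend = j;
  // traceback
  std::vector<char> col(L + 1, 0);     // member char per consumed rep pos
  std::vector<std::string> ins(L + 2); // insertions before rep pos j (1-based)
  int i = m, j = jend;
  int matches = 0, columns = 0;
  while (i > 0) {
    unsigned char t = tb[i * W + j];
    if (t == 0) {
      col[j] = member[i - 1];
      if (member[i - 1] == rep[j - 1]) ++matches;
      ++columns; --i; --j;
    } else if (t == 1) {            // member base with no rep base
      ins[j + 1].insert(0, 1, member[i - 1]);
      ++columns; --i;
    } else {                        // rep base skipped inside the span
      col[j] = '-';
      ++columns; --j;
    }
  }
  int spos = j + 1;                 // first consumed rep position
  std::string aligned;
  if (jend >= spos) {
    aligned.reserve(jend - spos + 1);
    for (int k = spos; k <= jend; ++k) aligned.push_back(col[k] ? col[k] : '-');
  }
  std::vector<int> ipos;
  std::vector<std::string> istr;
  for (int k = 1; k <= L + 1; ++k) {
    if (!ins[k].empty()) { ipos.push_back(k); istr.push_back(ins[k]); }
  }
  return List::create(_["spos"] = spos, _["epos"] = jend,
                      _["aligned"] = aligned,
                      _["ins_pos"] = wrap(ipos), _["ins_str"] = wrap(istr),
                      _["matches"] = matches, _["columns"] = columns);
}

// Alignment identity (matches / alignment columns) of member vs rep under
// the same semi-global model, without traceback output.
// [[Rcpp::export(name = ".cpp_rep_identity")]]
double cpp_rep_identity(std::string member, std::string rep) {
  List r = cpp_align_to_rep(member, rep);
  int matches = r["matches"], columns = r["columns"];
  return columns > 0 ? (double)matches / columns : 0.0;
}
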