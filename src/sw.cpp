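#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps and full traceback.
//
// Gap convention: a gap of length L costs gap_open + (L-1) * gap_extend
// (the opening column costs gap_open, each further column gap_extend).
//
// q, t: 0-based indices into the substitution matrix rows/cols.
// Returns the optimal score and the coordinates / identity of one optimal
// alignment (ties resolved towards the smallest end coordinates, then by
// preferring diagonal > query-gap > target-gap moves during traceback,
// which makes the reported alignment deterministic).

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(IntegerVector q, IntegerVector t, IntegerMatrix score_mat,
              int gap_open, int gap_extend) {
  const int m = q.size(), n = t.size();
  const int NEG = -1000000000;

  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0);
  std::vector<int> Eprev(n + 1, NEG), Ecur(n + 1, NEG);
  std::vector<int> Fcol(n + 1, NEG);
  // pointer matrices, (m+1) x (n+1), row-major
  std::vector<unsigned char> ptrH((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> ptrE((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> ptrF((size_t)(m + 1) * (n + 1), 0);

  int best = 0, bi = 0, bj = 0;

  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0;
    Ecur[0] = NEG;
    for (int j = 1; j <= n; ++j) {
      size_t at = (size_t)i * (n + 1) + j;
      // E: gap in query (move along target)
      int e_open = Hcur[j - 1] - gap_open;
      int e_ext = Ecur[j - 1] - gap_extend;
      Ecur[j] = (e_open >= e_ext) ? e_open : e_ext;
      ptrE[at] = (e_open >= e_ext) ? 0 : 1;
      // F: gap in target (move along query)
      int f_open = Hprev[j] - gap_open;
      int f_ext = Fcol[j] - gap_extend;
      Fcol[j] = (f_open >= f_ext) ? f_open : f_ext;
      ptrF[at] = (f_open >= f_ext) ? 0 : 1;
      // H
      int diag = Hprev[j - 1] + score_mat(q[i - 1], t[j - 1]);
      int h = 0;
      unsigned char p = 0;
      if (diag > h) { h = diag; p = 1; }
      if (Ecur[j] > h) { h = Ecur[j]; p = 2; }
      if (Fcol[j] > h) { h = Fcol[j]; p = 3; }
      Hcur[j] = h;
      ptrH[at] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }

  if (best == 0) {
    return List::create(_["score"] = 0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["t_start"] = NA_INTEGER,
                        _["t_end"] = NA_INTEGER, _["identities"] = 0,
                        _["aln_length"] = 0);
  }

  // traceback from (bi, bj)
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E, 2 = F
  int identities = 0, cols = 0;
  while (true) {
    size_t at = (size_t)i * (n + 1) + j;
    if (state == 0) {
      unsigned char p = ptrH[at];
      if (p == 0) break;            // score 0: local alignment starts here
      if (p == 1) {
        ++cols;
        if (q[i - 1] == t[j - 1]) ++identities;
        --i; --j;
      } else if (p == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {        // in E: consumed target char j
      unsigned char p = ptrE[at];
      ++cols;
      --j;
      state = (p == 0) ? 0 : 1;
    } else {                        // in F: consumed query char i
      unsigned char p = ptrF[at];
      ++cols;
      --i;
      state = (p == 0) ? 0 : 2;
    }
  }

  return List::create(_["score"] = best, _["q_start"] = i + 1,
                      _["q_end"] = bi, _["t_start"] = j + 1,
                      _["t_end"] = bj, _["identities"] = identities,
                      _["aln_length"] = cols);
}
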