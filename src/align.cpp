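#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Global pairwise alignment with affine gaps (Needleman-Wunsch / Gotoh).
//
// Gap convention: a gap run of length L costs gap_open + gap_extend*(L-1),
// i.e. the first gapped residue carries the full opening cost (a length-1
// gap costs gap_open).  Traceback is deterministic with move precedence
// diagonal > vertical (residue of `a` over a gap) > horizontal.
//
// `ai`, `bi` are 0-based indices into the substitution matrix `sub`.
// [[Rcpp::export(name = ".nw_affine")]]
List nw_affine(IntegerVector ai, IntegerVector bi, NumericMatrix sub,
               double gap_open, double gap_extend) {
  const int n = ai.size(), m = bi.size();
  const double NEG = -std::numeric_limits<double>::infinity();

  // States: 0 = M (diagonal), 1 = Ia (vertical, gap in b), 2 = Ib (horizontal).
  std::vector<double> M((n + 1) * (m + 1), NEG), Ia((n + 1) * (m + 1), NEG),
      Ib((n + 1) * (m + 1), NEG);
  // Predecessor state for each cell/state (0/1/2), 255 = none.
  std::vector<unsigned char> pM((n + 1) * (m + 1), 255),
      pIa((n + 1) * (m + 1), 255), pIb((n + 1) * (m + 1), 255);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    Ia[at(i, 0)] = -(gap_open + gap_extend * (i - 1));
    pIa[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Ib[at(0, j)] = -(gap_open + gap_extend * (j - 1));
    pIb[at(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = sub(ai[i - 1], bi[j - 1]);
      // M: predecessors at (i-1, j-1); precedence M > Ia > Ib on ties.
      {
        double best = M[at(i - 1, j - 1)];
        unsigned char st = 0;
        if (Ia[at(i - 1, j - 1)] > best) { best = Ia[at(i - 1, j - 1)]; st = 1; }
        if (Ib[at(i - 1, j - 1)] > best) { best = Ib[at(i - 1, j - 1)]; st = 2; }
        if (best > NEG) { M[at(i, j)] = best + s; pM[at(i, j)] = st; }
      }
      // Ia (vertical): consume a[i-1] over a gap; from (i-1, j).
      {
        double best = NEG;
        unsigned char st = 255;
        double vM = (M[at(i - 1, j)] > NEG) ? M[at(i - 1, j)] - gap_open : NEG;
        double vA = (Ia[at(i - 1, j)] > NEG) ? Ia[at(i - 1, j)] - gap_extend : NEG;
        double vB = (Ib[at(i - 1, j)] > NEG) ? Ib[at(i - 1, j)] - gap_open : NEG;
        if (vM > best) { best = vM; st = 0; }
        if (vA > best) { best = vA; st = 1; }
        if (vB > best) { best = vB; st = 2; }
        if (st != 255) { Ia[at(i, j)] = best; pIa[at(i, j)] = st; }
      }
      // Ib (horizontal): consume b[j-1] over a gap; from (i, j-1).
      {
        double best = NEG;
        unsigned char st = 255;
        double vM = (M[at(i, j - 1)] > NEG) ? M[at(i, j - 1)] - gap_open : NEG;
        double vA = (Ia[at(i, j - 1)] > NEG) ? Ia[at(i, j - 1)] - gap_open : NEG;
        double vB = (Ib[at(i, j - 1)] > NEG) ? Ib[at(i, j - 1)] - gap_extend : NEG;
        if (vM > best) { best = vM; st = 0; }
        if (vA > best) { best = vA; st = 1; }
        if (vB > best) { best = vB; st = 2; }
        if (st != 255) { Ib[at(i, j)] = best; pIb[at(i, j)] = st; }
      }
    }
  }

  // Final state: precedence M > Ia > Ib on ties.
  double score = M[at(n, m)];
  int state = 0;
  if (Ia[at(n, m)] > score) { score = Ia[at(n, m)]; state = 1; }
  if (Ib[at(n, m)] > score) { score = Ib[at(n, m)]; state = 2; }
  if (n == 0 && m == 0) { score = 0.0; state = 0; }

  // Traceback: emit 0-based operation codes (0 diag, 1 vertical, 2 horizontal)
  // reversed at the end.
  std::vector<unsigned char> ops;
  ops.reserve(n + m);
  int i = n, j = m, st = state;
  while (i > 0 || j > 0) {
    if (st == 0) {
      ops.push_back(0);
      st = pM[at(i, j)];
      --i; --j;
    } else if (st == 1) {
      ops.push_back(1);
      st = pIa[at(i, j)];
      --i;
    } else {
      ops.push_back(2);
      st = pIb[at(i, j)];
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  IntegerVector opv(ops.begin(), ops.end());
  return List::create(_["score"] = score, _["ops"] = opv);
}
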