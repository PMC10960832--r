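#include <Rcpp.h>
#include <limits>
#include <string>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps (Gotoh).
// Gap of length L costs gap_open + L * gap_extend (needle-style; both
// passed as negative scores). 'N' matches nothing and scores as a
// mismatch. Ties are broken deterministically: substitutions preferred
// over gaps, then leftmost gap placement (diagonal-preferred traceback).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

enum State { SM = 0, SD = 1, SI = 2 }; // match/mismatch, del (gap in read), ins

// [[Rcpp::export(name = ".nw_affine")]]
List nw_affine(std::string read, std::string ref,
               double match, double mismatch,
               double gap_open, double gap_extend) {
  const int n = read.size(), m = ref.size();
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), D((n + 1) * W, NEG_INF),
      I((n + 1) * W, NEG_INF);
  std::vector<signed char> tbM((n + 1) * W, -1), tbD((n + 1) * W, -1),
      tbI((n + 1) * W, -1);

  M[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    D[j] = gap_open + j * gap_extend;
    tbD[j] = SD;
  }
  tbD[1] = SM;
  for (int i = 1; i <= n; ++i) {
    I[i * W] = gap_open + i * gap_extend;
    tbI[i * W] = (i == 1) ? SM : SI;
  }

  for (int i = 1; i <= n; ++i) {
    const char rb = read[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int ij = i * W + j, up = (i - 1) * W + j, lf = i * W + j - 1,
                dg = (i - 1) * W + j - 1;
      const char qb = ref[j - 1];
      const double s = (rb == qb && rb != 'N') ? match : mismatch;
      // M: diagonal from best of the three, preference M > D > I
      {
        double best = M[dg]; signed char from = SM;
        if (D[dg] > best) { best = D[dg]; from = SD; }
        if (I[dg] > best) { best = I[dg]; from = SI; }
        if (best > NEG_INF) { M[ij] = best + s; tbM[ij] = from; }
      }
      // D: consume ref base with gap in read
      {
        double best = M[lf] + gap_open + gap_extend; signed char from = SM;
        if (D[lf] + gap_extend > best) { best = D[lf] + gap_extend; from = SD; }
        if (I[lf] + gap_open + gap_extend > best) {
          best = I[lf] + gap_open + gap_extend; from = SI;
        }
        D[ij] = best; tbD[ij] = from;
      }
      // I: consume read base with gap in ref
      {
        double best = M[up] + gap_open + gap_extend; signed char from = SM;
        if (D[up] + gap_open + gap_extend > best) {
          best = D[up] + gap_open + gap_extend; from = SD;
        }
        if (I[up] + gap_extend > best) { best = I[up] + gap_extend; from = SI; }
        I[ij] = best; tbI[ij] = from;
      }
    }
  }

  const int end = n * W + m;
  double score = M[end]; int state = SM;
  if (D[end] > score) { score = D[end]; state = SD; }
  if (I[end] > score) { score = I[end]; state = SI; }

  // traceback: record one op per alignment column, reversed
  std::string ops;          // '=', 'X', 'D', 'I'
  std::string col_bases;    // read base for X/I columns, '-' otherwise
  std::vector<int> col_ref; // 0-based ref offset consumed (D/=/X) or anchor (I)
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int ij = i * W + j;
    if (state == SM) {
      const char rb = read[i - 1], qb = ref[j - 1];
      const bool is_match = (rb == qb && rb != 'N');
      ops.push_back(is_match ? '=' : 'X');
      col_bases.push_back(rb);
      col_ref.push_back(j - 1);
      state = tbM[ij]; --i; --j;
    } else if (state == SD) {
      ops.push_back('D');
      col_bases.push_back('-');
      col_ref.push_back(j - 1);
      state = tbD[ij]; --j;
    } else {
      ops.push_back('I');
      col_bases.push_back(read[i - 1]);
      col_ref.push_back(j); // anchored to the ref offset it precedes
      state = tbI[ij]; --i;
    }
  }
  std::reverse(ops.begin(), ops.end());
  std::reverse(col_bases.begin(), col_bases.end());
  std::reverse(col_ref.begin(), col_ref.end());

  // aggregate into events sorted by coordinate
  std::vector<std::string> ev_type, ev_bases;
  std::vector<int> ev_start, ev_end;
  int n_match = 0;
  const int L = ops.size();
  for (int k = 0; k < L; ++k) {
    if (ops[k] == '=') { ++n_match; continue; }
    if (ops[k] == 'X') {
      ev_type.push_back("substitution");
      ev_start.push_back(col_ref[k]);
      ev_end.push_back(col_ref[k] + 1);
      ev_bases.push_back(std::string(1, col_bases[k]));
    } else if (ops[k] == 'D') {
      int k2 = k;
      while (k2 + 1 < L && ops[k2 + 1] == 'D') ++k2;
      ev_type.push_back("deletion");
      ev_start.push_back(col_ref[k]);
      ev_end.push_back(col_ref[k2] + 1); // half-open [start, end)
      ev_bases.push_back("");
      k = k2;
    } else { // 'I'
      int k2 = k;
      std::string ins;
      ins.push_back(col_bases[k]);
      while (k2 + 1 < L && ops[k2 + 1] == 'I') {
        ++k2;
        ins.push_back(col_bases[k2]);
      }
      ev_type.push_back("insertion");
      ev_start.push_back(col_ref[k]);
      ev_end.push_back(col_ref[k]);
      ev_bases.push_back(ins);
      k = k2;
    }
  }

  return List::create(
      _["score"] = score, _["n_match"] = n_match, _["aln_len"] = L,
      _["cigar_ops"] = ops,
      _["events"] = DataFrame::create(
          _["type"] = ev_type, _["ref_start"] = ev_start,
          _["ref_end"] = ev_end, _["bases"] = ev_bases,
          _["stringsAsFactors"] = false));
}
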