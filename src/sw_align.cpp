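#include <Rcpp.h>
using namespace Rcpp;

// Exact affine-gap local alignment (Gotoh) with traceback of one optimal
// segment. Sequences arrive as 0-based indices into the scoring matrix.
// A gap of length L costs gap_open + L * gap_extend.
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, IntegerMatrix S,
                  int gap_open, int gap_extend) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0) {
    return List::create(_["score"] = 0, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0);
  }
  const int NEG = -1000000000;
  const int go = gap_open + gap_extend;   // cost of the first gapped residue
  std::vector<int> Hrow((n + 1)), Hprev((n + 1)), Erow(n + 1), Eprev(n + 1),
      Frow(n + 1), Fprev(n + 1);
  // pointer codes: H: 0 stop, 1 diag, 2 from E, 3 from F
  //                E: 0 opened from H, 1 extended; F likewise
  std::vector<unsigned char> ptrH((m + 1) * (n + 1), 0),
      ptrE((m + 1) * (n + 1), 0), ptrF((m + 1) * (n + 1), 0);
  for (int j = 0; j <= n; ++j) { Hprev[j] = 0; Eprev[j] = NEG; Fprev[j] = NEG; }
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Hrow[0] = 0; Erow[0] = NEG; Frow[0] = NEG;
    const int ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      const size_t idx = (size_t)i * (n + 1) + j;
      // E: gap in A (consumes b_j)
      int e_open = Hrow[j - 1] - go;
      int e_ext = Erow[j - 1] - gap_extend;
      if (e_open >= e_ext) { Erow[j] = e_open; ptrE[idx] = 0; }
      else { Erow[j] = e_ext; ptrE[idx] = 1; }
      // F: gap in B (consumes a_i)
      int f_open = Hprev[j] - go;
      int f_ext = Fprev[j] - gap_extend;
      if (f_open >= f_ext) { Frow[j] = f_open; ptrF[idx] = 0; }
      else { Frow[j] = f_ext; ptrF[idx] = 1; }
      int diag = Hprev[j - 1] + S(ai, b[j - 1]);
      int h = 0; unsigned char p = 0;
      if (diag > h) { h = diag; p = 1; }
      if (Erow[j] > h) { h = Erow[j]; p = 2; }
      if (Frow[j] > h) { h = Frow[j]; p = 3; }
      Hrow[j] = h; ptrH[idx] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hrow, Hprev); std::swap(Erow, Eprev); std::swap(Frow, Fprev);
  }
  // traceback
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E, 2 = F
  int a_end = bi, b_end = bj;
  while (i > 0 && j > 0) {
    const size_t idx = (size_t)i * (n + 1) + j;
    if (state == 0) {
      unsigned char p = ptrH[idx];
      if (p == 0) break;
      if (p == 1) { --i; --j; }
      else if (p == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      unsigned char p = ptrE[idx];
      --j;
      state = (p == 0) ? 0 : 1;
    } else {
      unsigned char p = ptrF[idx];
      --i;
      state = (p == 0) ? 0 : 2;
    }
  }
  int a_start = (best > 0) ? i + 1 : 0;
  int b_start = (best > 0) ? j + 1 : 0;
  if (best == 0) { a_end = 0; b_end = 0; }
  return List::create(_["score"] = best, _["a_start"] = a_start,
                      _["a_end"] = a_end, _["b_start"] = b_start,
                      _["b_end"] = b_end);
}
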