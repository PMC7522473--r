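#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh). Gap of length k costs open + k*ext.
// q, s are 1-based indices into the rows/cols of 'submat'.
// Returns the optimal score plus traceback-derived column statistics.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector q, IntegerVector s, NumericMatrix submat,
                  double gap_open, double gap_extend) {
  const int m = q.size(), n = s.size();
  const double NEG = -1e30;
  std::vector<double> H((m + 1) * (n + 1), 0.0);
  std::vector<double> E((m + 1) * (n + 1), NEG);
  std::vector<double> F((m + 1) * (n + 1), NEG);
  // traceback codes: dH 0=stop 1=diag 2=from E (gap in query) 3=from F
  std::vector<unsigned char> dH((m + 1) * (n + 1), 0);
  std::vector<unsigned char> dE((m + 1) * (n + 1), 0); // 1 = opened from H
  std::vector<unsigned char> dF((m + 1) * (n + 1), 0);

  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int ij = at(i, j);
      double e_open = H[at(i, j - 1)] - gap_open - gap_extend;
      double e_ext  = E[at(i, j - 1)] - gap_extend;
      if (e_open >= e_ext) { E[ij] = e_open; dE[ij] = 1; }
      else                 { E[ij] = e_ext;  dE[ij] = 0; }

      double f_open = H[at(i - 1, j)] - gap_open - gap_extend;
      double f_ext  = F[at(i - 1, j)] - gap_extend;
      if (f_open >= f_ext) { F[ij] = f_open; dF[ij] = 1; }
      else                 { F[ij] = f_ext;  dF[ij] = 0; }

      double diag = H[at(i - 1, j - 1)] + submat(q[i - 1] - 1, s[j - 1] - 1);
      double h = 0.0; unsigned char d = 0;
      if (diag > h) { h = diag; d = 1; }
      if (E[ij] > h) { h = E[ij]; d = 2; }
      if (F[ij] > h) { h = F[ij]; d = 3; }
      H[ij] = h; dH[ij] = d;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback
  int n_ident = 0, n_pos = 0, align_len = 0;
  int qend = bi, send = bj, qstart = bi + 1, sstart = bj + 1;
  int i = bi, j = bj, state = 0; // 0=H, 1=E, 2=F
  while (i > 0 && j > 0) {
    const int ij = at(i, j);
    if (state == 0) {
      unsigned char d = dH[ij];
      if (d == 0) break;
      if (d == 1) {
        ++align_len;
        double sc = submat(q[i - 1] - 1, s[j - 1] - 1);
        if (q[i - 1] == s[j - 1]) ++n_ident;
        if (sc > 0) ++n_pos;
        qstart = i; sstart = j;
        --i; --j;
      } else if (d == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // gap in query, consumes s[j]
      ++align_len;
      unsigned char d = dE[ij];
      sstart = j;
      --j;
      state = d ? 0 : 1;
    } else { // gap in subject, consumes q[i]
      ++align_len;
      unsigned char d = dF[ij];
      qstart = i;
      --i;
      state = d ? 0 : 2;
    }
  }
  if (best <= 0.0) { qstart = 0; qend = 0; sstart = 0; send = 0; }

  return List::create(
    _["score"] = best,
    _["qstart"] = qstart, _["qend"] = qend,
    _["sstart"] = sstart, _["send"] = send,
    _["n_ident"] = n_ident, _["n_pos"] = n_pos,
    _["align_len"] = align_len);
}
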