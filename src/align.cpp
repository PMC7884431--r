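#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gotoh local alignment (affine gaps) over integer-coded sequences.
// Gap of length L costs gap_open + gap_ext * L, matching the convention of
// Biostrings::pairwiseAlignment, which the test suite uses as an
// independent oracle for the score.
//
// Score matrices H/E/F are kept as rolling rows; the full matrix is only a
// byte array of traceback codes, so memory stays at (m+1)*(n+1) bytes.
// Traceback preference: diagonal > vertical > horizontal; the end cell is
// the first maximum in row-major order. Returns score, match count,
// alignment columns, and the aligned spans on both sequences (1-based,
// inclusive; 0/-1 when the best score is not positive).
// [[Rcpp::export(name = ".rfl_align_c")]]
List rfl_align_c(IntegerVector a, IntegerVector b, NumericMatrix submat,
                 double gap_open, double gap_ext) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0)
    return List::create(_["score"] = 0.0, _["matches"] = 0,
                        _["cols"] = 0, _["a_start"] = 0, _["a_end"] = -1,
                        _["b_start"] = 0, _["b_end"] = -1);
  const float NEG = -1e30f;
  const float go = (float)(gap_open + gap_ext);
  const float ge = (float)gap_ext;
  std::vector<float> Hup(n + 1, 0.0f), Hcur(n + 1, 0.0f);
  std::vector<float> Fup(n + 1, NEG);
  std::vector<unsigned char> TB((size_t)(m + 1) * (n + 1), 0);
  const int nsub = submat.nrow();
  // row-major float copy of the scoring matrix (scores are small integers,
  // so float arithmetic is exact)
  std::vector<float> sm((size_t)nsub * submat.ncol());
  for (int r = 0; r < nsub; ++r)
    for (int c = 0; c < submat.ncol(); ++c)
      sm[(size_t)r * submat.ncol() + c] = (float)submat(r, c);
  float best = 0.0f;
  int bi = 0, bj = 0;
  const int *bp = b.begin();
  for (int i = 1; i <= m; ++i) {
    float Eleft = NEG;
    Hcur[0] = 0.0f;
    const float *srow = &sm[(size_t)(a[i - 1] - 1) * submat.ncol()];
    unsigned char *tbrow = &TB[(size_t)i * (n + 1)];
    float *Hu = Hup.data(), *Hc = Hcur.data(), *Fu = Fup.data();
    for (int j = 1; j <= n; ++j) {
      float e_open = Hc[j - 1] - go;
      float e_ext = Eleft - ge;
      float e = e_open >= e_ext ? e_open : e_ext;
      float f_open = Hu[j] - go;
      float f_ext = Fu[j] - ge;
      float f = f_open >= f_ext ? f_open : f_ext;
      float d = Hu[j - 1] + srow[bp[j - 1] - 1];
      float h = 0.0f;
      unsigned char tb = 0;
      if (d >= h) { h = d; tb = 1; }
      if (f > h) { h = f; tb = 2; }
      if (e > h) { h = e; tb = 3; }
      if (h <= 0.0f) { h = 0.0f; tb = 0; }
      if (f_ext > f_open) tb |= 4;   // F arrived by extension
      if (e_ext > e_open) tb |= 8;   // E arrived by extension
      Hc[j] = h; Eleft = e; Fu[j] = f;
      tbrow[j] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hup, Hcur);
  }
  int matches = 0, cols = 0;
  int a_end = bi, b_end = bj, a_start = bi + 1, b_start = bj + 1;
  if (best > 0.0) {
    int i = bi, j = bj;
    int state = 0; // 0 = in H, 2 = vertical run (F), 3 = horizontal run (E)
    while (i > 0 && j > 0) {
      unsigned char tb = TB[(size_t)i * (n + 1) + j];
      if (state == 0) {
        unsigned char dir = tb & 3;
        if (dir == 0) break;
        if (dir == 1) {
          ++cols;
          if (a[i - 1] == b[j - 1]) ++matches;
          a_start = i; b_start = j;
          --i; --j;
        } else if (dir == 2) state = 2;
        else state = 3;
      } else if (state == 2) {       // gap in b, consume a[i]
        ++cols;
        a_start = i;
        bool ext = (tb & 4) != 0;
        --i;
        if (!ext) state = 0;
      } else {                       // gap in a, consume b[j]
        ++cols;
        b_start = j;
        bool ext = (tb & 8) != 0;
        --j;
        if (!ext) state = 0;
      }
    }
  } else {
    a_start = 0; a_end = -1; b_start = 0; b_end = -1;
  }
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["cols"] = cols, _["a_start"] = a_start,
                      _["a_end"] = a_end, _["b_start"] = b_start,
                      _["b_end"] = b_end);
}
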