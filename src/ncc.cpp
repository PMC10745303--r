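#include <Rcpp.h>
using namespace Rcpp;

// Zero-normalized cross-correlation of a template against every placement
// inside a search image. Scores are invariant to affine intensity changes
// (gain and offset) of either input. Returns a
// (nrow(img)-nrow(tpl)+1) x (ncol(img)-ncol(tpl)+1) score matrix in [-1, 1];
// placements with (near-)constant image content score 0.
// [[Rcpp::export]]
NumericMatrix ncc_search(const NumericMatrix& img, const NumericMatrix& tpl) {
  const int hi = img.nrow(), wi = img.ncol();
  const int ht = tpl.nrow(), wt = tpl.ncol();
  const int nr = hi - ht + 1, nc = wi - wt + 1;
  if (nr < 1 || nc < 1) stop("search window smaller than template");
  const double nt = static_cast<double>(ht) * wt;

  double tmean = 0.0;
  for (int j = 0; j < wt; ++j)
    for (int i = 0; i < ht; ++i) tmean += tpl(i, j);
  tmean /= nt;

  std::vector<double> tz(static_cast<size_t>(ht) * wt);
  double tss = 0.0;
  for (int j = 0; j < wt; ++j)
    for (int i = 0; i < ht; ++i) {
      double v = tpl(i, j) - tmean;
      tz[static_cast<size_t>(j) * ht + i] = v;
      tss += v * v;
    }

  NumericMatrix out(nr, nc);
  if (tss <= 1e-12) return out;  // degenerate template: all scores 0

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double s = 0.0, s2 = 0.0, cross = 0.0;
      for (int j = 0; j < wt; ++j) {
        const double* col = &img(0, c + j);
        const double* tcol = &tz[static_cast<size_t>(j) * ht];
        for (int i = 0; i < ht; ++i) {
          double v = col[r + i];
          s += v;
          s2 += v * v;
          cross += v * tcol[i];
        }
      }
      double wss = s2 - s * s / nt;
      double denom = wss * tss;
      out(r, c) = denom > 1e-12 ? cross / std::sqrt(denom) : 0.0;
    }
  }
  return out;
}
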