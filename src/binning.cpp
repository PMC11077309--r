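#include <Rcpp.h>
using namespace Rcpp;

// Accumulate the periodic bilinear-binning contributions of a subset of
// points onto a G x G grid. idx/w are n x 4 (cell index, weight) pairs
// produced by the R-side binning; rows are 1-based point indices.
// [[Rcpp::export(name = ".bin_group_cpp")]]
NumericMatrix bin_group_cpp(IntegerMatrix idx, NumericMatrix w,
                            IntegerVector rows, int G) {
  NumericMatrix H(G, G);
  double *h = H.begin();
  const int nr = rows.size();
  for (int k = 0; k < nr; ++k) {
    const int i = rows[k] - 1;
    for (int j = 0; j < 4; ++j) {
      h[idx(i, j) - 1] += w(i, j);
    }
  }
  return H;
}
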