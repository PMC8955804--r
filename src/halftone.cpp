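#include <Rcpp.h>
using namespace Rcpp;

// Floyd-Steinberg error diffusion, plain raster scan (top-to-bottom,
// left-to-right). Quantization error is pushed 7/16 right, 3/16 below-left,
// 5/16 below, 1/16 below-right; targets outside the image are dropped.
// Accumulated values are not clamped before thresholding; threshold is 0.5
// with ties firing a dot.
// [[Rcpp::export]]
IntegerMatrix fs_diffuse(NumericMatrix x) {
  int h = x.nrow(), w = x.ncol();
  NumericMatrix acc(clone(x));
  IntegerMatrix out(h, w);
  for (int r = 0; r < h; ++r) {
    for (int c = 0; c < w; ++c) {
      double v = acc(r, c);
      int bit = (v >= 0.5) ? 1 : 0;
      out(r, c) = bit;
      double e = v - bit;
      if (c + 1 < w) acc(r, c + 1) += e * 7.0 / 16.0;
      if (r + 1 < h) {
        if (c - 1 >= 0) acc(r + 1, c - 1) += e * 3.0 / 16.0;
        acc(r + 1, c) += e * 5.0 / 16.0;
        if (c + 1 < w) acc(r + 1, c + 1) += e * 1.0 / 16.0;
      }
    }
  }
  return out;
}
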