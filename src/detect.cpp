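#include <Rcpp.h>
using namespace Rcpp;

// Streaming raster-order threshold detector.
//
// Emulates the on-sensor pipeline: pixels arrive in raster order (row-major,
// rows top to bottom, columns left to right) and each one is compared once
// against the threshold as it streams past; a supra-threshold, non-hot pixel
// overwrites the stored position. When the last pixel has been seen the
// stored position is the result; (0,0) means no pixel exceeded T.
//
// Exactly one comparison per pixel is performed and counted, regardless of
// the frame content, mirroring the constant-work hard-real-time contract.
//
// frame and mask are height x width (row, col) matrices; returns
// c(row, col, comparisons) with 1-based coordinates.
// [[Rcpp::export]]
IntegerVector cpp_stream_detect(const IntegerMatrix& frame,
                                const LogicalMatrix& mask,
                                const int threshold) {
  const int nrow = frame.nrow();
  const int ncol = frame.ncol();
  int hit_row = 0, hit_col = 0;
  long long comparisons = 0;
  for (int i = 0; i < nrow; ++i) {
    for (int j = 0; j < ncol; ++j) {
      ++comparisons;
      if (frame(i, j) > threshold && !mask(i, j)) {
        hit_row = i + 1;
        hit_col = j + 1;
      }
    }
  }
  return IntegerVector::create(hit_row, hit_col, (int)comparisons);
}
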