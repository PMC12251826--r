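#include <Rcpp.h>

using namespace Rcpp;

// Accumulate column-matrix gradients back onto the (stacked) input maps
// of a batched valid convolution: the adjoint of the im2col gather.
//
// dcols: (npix * bs) x kkc gradient of the column matrix (sample-major
//        row blocks), idx: npix x kkc im2col index matrix (1-based, per
//        sample), d: length of one sample's input map, bs: batch size.
// Returns the stacked input gradient of length d * bs.
// [[Rcpp::export]]
NumericVector col2im_acc_cpp(NumericMatrix dcols, IntegerMatrix idx,
                             int d, int bs) {
  const int npix = idx.nrow(), kkc = idx.ncol();
  if (dcols.nrow() != npix * bs || dcols.ncol() != kkc)
    stop("dcols shape does not match idx/bs");
  NumericVector dx((R_xlen_t)d * bs);
  for (int cc = 0; cc < kkc; ++cc) {
    const int *ic = &idx(0, cc);
    const double *gc = &dcols(0, cc);
    for (int s = 0; s < bs; ++s) {
      double *o = &dx[(R_xlen_t)s * d];
      const double *g = gc + (R_xlen_t)s * npix;
      for (int p = 0; p < npix; ++p) o[ic[p] - 1] += g[p];
    }
  }
  return dx;
}
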