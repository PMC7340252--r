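#ifndef CRYOPICK_IMAGEOPS_H
#define CRYOPICK_IMAGEOPS_H

#include <RcppArmadillo.h>

// rows = y, cols = x throughout (matches R matrix layout image[y+1, x+1])
arma::mat rotate_reflect(const arma::mat& img, double angle_deg);
arma::mat bilinear_resize(const arma::mat& img, int out_h, int out_w);
arma::vec standardize_flat(const arma::mat& img);

#endif
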