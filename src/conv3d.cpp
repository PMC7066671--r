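// Hot loops for the twin 3D-CNN: 3x3x3 "same" convolution via padded
// shift-and-gemm, 2x max pooling and global spatial max pooling, each with
// its backward pass.
// Layout conventions (shared with the R side):
//   * a batch of grids is a (C * D^3) x B matrix, channel-first within a
//     voxel, voxel index v = ix + D*iy + D*D*iz (0-based, x fastest);
//   * conv weights are (F) x (C * 27) with column index c + C*o where
//     o = (dx+1) + 3*(dy+1) + 9*(dz+1) enumerates the kernel offsets.
// The input is zero-padded by one voxel per face into a (D+2)^3 volume;
// each kernel offset then corresponds to a single contiguous column shift
// of the flattened padded volume, so the whole convolution runs as 27
// dense GEMMs on contiguous subviews.  Outputs in the padding shell pick
// up wrap-around garbage and are simply discarded when un-padding.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// Copy one sample (C x D^3, flattened) into the interior of a zeroed
// padded (C x (D+2)^3) volume.  Rows along x are contiguous blocks of
// C*D doubles.
void pad_sample(const double* x, int C, int D, mat& Xp) {
  const int P = D + 2;
  Xp.zeros();
  for (int iz = 0; iz < D; ++iz)
    for (int iy = 0; iy < D; ++iy) {
      const int src = C * D * (iy + D * iz);
      const int dst = 1 + P * (iy + 1) + P * P * (iz + 1);
      std::memcpy(Xp.colptr(dst), x + src, C * D * sizeof(double));
    }
}

void unpad_sample(const mat& Yp, int F, int D, double* y) {
  const int P = D + 2;
  for (int iz = 0; iz < D; ++iz)
    for (int iy = 0; iy < D; ++iy) {
      const int dst = F * D * (iy + D * iz);
      const int src = 1 + P * (iy + 1) + P * P * (iz + 1);
      std::memcpy(y + dst, Yp.colptr(src), F * D * sizeof(double));
    }
}

} // namespace

// [[Rcpp::export]]
arma::mat conv3d_fwd(const arma::mat& X, const arma::mat& W,
                     const arma::vec& b, int C, int D) {
  const int S = D * D * D;
  const int P = D + 2;
  const int PS = P * P * P;
  const int B = X.n_cols;
  const int F = W.n_rows;
  mat Y(F * S, B);
  mat Xp(C, PS), Yp(F, PS);
  for (int s = 0; s < B; ++s) {
    pad_sample(X.colptr(s), C, D, Xp);
    Yp.zeros();
    for (int o = 0; o < 27; ++o) {
      const int off = (o % 3 - 1) + P * ((o / 3) % 3 - 1) + P * P * (o / 9 - 1);
      const mat Wo = W.cols(C * o, C * o + C - 1);
      const int a = std::max(0, -off);
      const int n = PS - std::abs(off);
      Yp.cols(a, a + n - 1) += Wo * Xp.cols(a + off, a + off + n - 1);
    }
    unpad_sample(Yp, F, D, Y.colptr(s));
  }
  // broadcast bias over voxels
  for (int s = 0; s < B; ++s) {
    double* yp = Y.colptr(s);
    for (int v = 0; v < S; ++v)
      for (int f = 0; f < F; ++f) yp[f + F * v] += b(f);
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv3d_bwd(const arma::mat& X, const arma::mat& W,
                      const arma::mat& dY, int C, int D,
                      bool want_dx = true) {
  const int S = D * D * D;
  const int P = D + 2;
  const int PS = P * P * P;
  const int B = X.n_cols;
  const int F = W.n_rows;
  mat dW(F, C * 27, fill::zeros);
  vec db(F, fill::zeros);
  mat dX(want_dx ? C * S : 0, want_dx ? B : 0);
  mat Xp(C, PS), dYp(F, PS), dXp(want_dx ? C : 0, want_dx ? PS : 0);
  for (int s = 0; s < B; ++s) {
    pad_sample(X.colptr(s), C, D, Xp);
    pad_sample(dY.colptr(s), F, D, dYp);
    if (want_dx) dXp.zeros();
    for (int o = 0; o < 27; ++o) {
      const int off = (o % 3 - 1) + P * ((o / 3) % 3 - 1) + P * P * (o / 9 - 1);
      const int a = std::max(0, -off);
      const int n = PS - std::abs(off);
      dW.cols(C * o, C * o + C - 1) +=
        dYp.cols(a, a + n - 1) * Xp.cols(a + off, a + off + n - 1).t();
      if (want_dx) {
        const mat Wo = W.cols(C * o, C * o + C - 1);
        dXp.cols(a + off, a + off + n - 1) += Wo.t() * dYp.cols(a, a + n - 1);
      }
    }
    if (want_dx) unpad_sample(dXp, C, D, dX.colptr(s));
    const mat dys(const_cast<double*>(dY.colptr(s)), F, S, false, true);
    db += sum(dys, 1);
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dX);
}

// [[Rcpp::export]]
Rcpp::List maxpool2_fwd(const arma::mat& X, int C, int D) {
  const int H = D / 2;
  const int SO = H * H * H;
  const int B = X.n_cols;
  mat Y(C * SO, B);
  Rcpp::IntegerMatrix idx(C * SO, B); // 1-based argmax rows into X columns
  const int D2 = D * D;
  for (int s = 0; s < B; ++s) {
    const double* xp = X.colptr(s);
    double* yp = Y.colptr(s);
    for (int kz = 0; kz < H; ++kz)
      for (int ky = 0; ky < H; ++ky)
        for (int kx = 0; kx < H; ++kx) {
          const int vo = kx + H * ky + H * H * kz;
          for (int c = 0; c < C; ++c) {
            double best = -datum::inf;
            int besti = -1;
            for (int oz = 0; oz < 2; ++oz)
              for (int oy = 0; oy < 2; ++oy)
                for (int ox = 0; ox < 2; ++ox) {
                  const int v = (2 * kx + ox) + D * (2 * ky + oy) +
                                D2 * (2 * kz + oz);
                  const int r = c + C * v;
                  if (xp[r] > best) { best = xp[r]; besti = r; }
                }
            yp[c + C * vo] = best;
            idx(c + C * vo, s) = besti + 1;
          }
        }
  }
  return Rcpp::List::create(Rcpp::Named("y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::mat maxpool_bwd(const Rcpp::IntegerMatrix& idx, const arma::mat& dY,
                      int n_in) {
  const int B = dY.n_cols, n = dY.n_rows;
  mat dX(n_in, B, fill::zeros);
  for (int s = 0; s < B; ++s) {
    double* dp = dX.colptr(s);
    const double* gp = dY.colptr(s);
    for (int r = 0; r < n; ++r) dp[idx(r, s) - 1] += gp[r];
  }
  return dX;
}

// [[Rcpp::export]]
Rcpp::List gpool_fwd(const arma::mat& X, int C, int S) {
  const int B = X.n_cols;
  mat Y(C, B);
  Rcpp::IntegerMatrix idx(C, B);
  for (int s = 0; s < B; ++s) {
    const double* xp = X.colptr(s);
    for (int c = 0; c < C; ++c) {
      double best = -datum::inf;
      int besti = -1;
      for (int v = 0; v < S; ++v) {
        const int r = c + C * v;
        if (xp[r] > best) { best = xp[r]; besti = r; }
      }
      Y(c, s) = best;
      idx(c, s) = besti + 1;
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = Y, Rcpp::Named("idx") = idx);
}
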