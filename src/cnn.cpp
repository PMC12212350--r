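// Convolutional autoencoder for per-spot image grids.
//
// Encoder: conv(k x k, "same") -> ReLU -> avgpool(2,2)  x2
// Decoder: two stride-2 transposed convolutions (implemented as zero-insertion
//          upsampling followed by a valid convolution), ReLU after each.
// Trained with Adam on the summed squared reconstruction error.
//
// Convolutions run as im2col + sgemm; float32 throughout. Weight
// initialization and mini-batch order are supplied from R so training is
// deterministic given the R-side seed.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct ConvGeom {
  int H, W, k, pad, oH, oW;
  ConvGeom(int H_, int W_, int k_, int pad_)
    : H(H_), W(W_), k(k_), pad(pad_),
      oH(H_ + 2 * pad_ - k_ + 1), oW(W_ + 2 * pad_ - k_ + 1) {}
  int npix() const { return H * W; }
  int opix() const { return oH * oW; }
};

// In: (bs*npix) x Cin feature maps (row-major pixel index r*W+c inside each
// sample block) -> Out: (bs*opix) x (Cin*k*k) patch matrix.
void im2col(const fmat& In, fmat& Out, int bs, const ConvGeom& g, int Cin) {
  const int npix = g.npix(), opix = g.opix(), kk2 = g.k * g.k;
  Out.zeros(static_cast<uword>(bs) * opix, static_cast<uword>(Cin) * kk2);
  for (int ci = 0; ci < Cin; ++ci) {
    const float* src_col = In.colptr(ci);
    for (int ky = 0; ky < g.k; ++ky) {
      for (int kx = 0; kx < g.k; ++kx) {
        float* dst_col = Out.colptr(static_cast<uword>(ci) * kk2 + ky * g.k + kx);
        const int oc0 = std::max(0, g.pad - kx);
        const int oc1 = std::min(g.oW, g.W + g.pad - kx);
        if (oc0 >= oc1) continue;
        for (int s = 0; s < bs; ++s) {
          const float* src = src_col + static_cast<size_t>(s) * npix;
          float* dst = dst_col + static_cast<size_t>(s) * opix;
          for (int orow = 0; orow < g.oH; ++orow) {
            const int ir = orow + ky - g.pad;
            if (ir < 0 || ir >= g.H) continue;
            std::memcpy(dst + orow * g.oW + oc0,
                        src + ir * g.W + (oc0 + kx - g.pad),
                        sizeof(float) * (oc1 - oc0));
          }
        }
      }
    }
  }
}

// Adjoint of im2col: scatter-add patch gradients back onto feature maps.
void col2im(const fmat& dOut, fmat& dIn, int bs, const ConvGeom& g, int Cin) {
  const int npix = g.npix(), opix = g.opix(), kk2 = g.k * g.k;
  dIn.zeros(static_cast<uword>(bs) * npix, Cin);
  for (int ci = 0; ci < Cin; ++ci) {
    float* dst_col = dIn.colptr(ci);
    for (int ky = 0; ky < g.k; ++ky) {
      for (int kx = 0; kx < g.k; ++kx) {
        const float* src_col = dOut.colptr(static_cast<uword>(ci) * kk2 + ky * g.k + kx);
        const int oc0 = std::max(0, g.pad - kx);
        const int oc1 = std::min(g.oW, g.W + g.pad - kx);
        if (oc0 >= oc1) continue;
        for (int s = 0; s < bs; ++s) {
          const float* src = src_col + static_cast<size_t>(s) * opix;
          float* dst = dst_col + static_cast<size_t>(s) * npix;
          for (int orow = 0; orow < g.oH; ++orow) {
            const int ir = orow + ky - g.pad;
            if (ir < 0 || ir >= g.H) continue;
            float* d0 = dst + ir * g.W + (oc0 + kx - g.pad);
            const float* s0 = src + orow * g.oW + oc0;
            for (int t = 0; t < oc1 - oc0; ++t) d0[t] += s0[t];
          }
        }
      }
    }
  }
}

// 2x2 stride-2 average pooling: (bs*H*W) x C -> (bs*(H/2)*(W/2)) x C.
void avgpool(const fmat& In, fmat& Out, int bs, int H, int W, int C) {
  const int qH = H / 2, qW = W / 2, npix = H * W, qpix = qH * qW;
  Out.set_size(static_cast<uword>(bs) * qpix, C);
  for (int c = 0; c < C; ++c) {
    const float* src_col = In.colptr(c);
    float* dst_col = Out.colptr(c);
    for (int s = 0; s < bs; ++s) {
      const float* src = src_col + static_cast<size_t>(s) * npix;
      float* dst = dst_col + static_cast<size_t>(s) * qpix;
      for (int qr = 0; qr < qH; ++qr)
        for (int qc = 0; qc < qW; ++qc) {
          const float* p = src + 2 * qr * W + 2 * qc;
          dst[qr * qW + qc] = 0.25f * (p[0] + p[1] + p[W] + p[W + 1]);
        }
    }
  }
}

void avgpool_back(const fmat& dOut, fmat& dIn, int bs, int H, int W, int C) {
  const int qH = H / 2, qW = W / 2, npix = H * W, qpix = qH * qW;
  dIn.set_size(static_cast<uword>(bs) * npix, C);
  for (int c = 0; c < C; ++c) {
    const float* src_col = dOut.colptr(c);
    float* dst_col = dIn.colptr(c);
    for (int s = 0; s < bs; ++s) {
      const float* src = src_col + static_cast<size_t>(s) * qpix;
      float* dst = dst_col + static_cast<size_t>(s) * npix;
      for (int qr = 0; qr < qH; ++qr)
        for (int qc = 0; qc < qW; ++qc) {
          const float v = 0.25f * src[qr * qW + qc];
          float* p = dst + 2 * qr * W + 2 * qc;
          p[0] = v; p[1] = v; p[W] = v; p[W + 1] = v;
        }
    }
  }
}

// Transposed convolution, stride 2, kernel k, padding (k-1)/2, output
// padding 1, so the spatial size exactly doubles. Implemented in gemm form:
// Cols = In * K with K of shape Cin x (Cout*k*k), then each input pixel
// (r, c) scatters its k x k taps onto output positions
// (2r + 2 - ky, 2c + 2 - kx). tconv_scatter is the forward scatter-add;
// tconv_gather is its adjoint (gathers output gradients back into Cols
// layout).
struct TconvGeom {
  int iH, iW, k, oH, oW;
  TconvGeom(int iH_, int iW_, int k_)
    : iH(iH_), iW(iW_), k(k_), oH(2 * iH_), oW(2 * iW_) {}
  int ipix() const { return iH * iW; }
  int opix() const { return oH * oW; }
};

void tconv_scatter(const fmat& Cols, fmat& Out, int bs, const TconvGeom& g,
                   int Cout) {
  const int ipix = g.ipix(), opix = g.opix(), kk2 = g.k * g.k;
  const int off = 2;  // (k-1)/2 padding with output padding 1, k = 5
  Out.zeros(static_cast<uword>(bs) * opix, Cout);
  for (int co = 0; co < Cout; ++co) {
    float* out_col = Out.colptr(co);
    for (int ky = 0; ky < g.k; ++ky) {
      for (int kx = 0; kx < g.k; ++kx) {
        const float* col = Cols.colptr(static_cast<uword>(co) * kk2 + ky * g.k + kx);
        for (int s = 0; s < bs; ++s) {
          const float* src = col + static_cast<size_t>(s) * ipix;
          float* dst = out_col + static_cast<size_t>(s) * opix;
          for (int r = 0; r < g.iH; ++r) {
            const int orow = 2 * r + off - ky;
            if (orow < 0 || orow >= g.oH) continue;
            for (int c = 0; c < g.iW; ++c) {
              const int ocol = 2 * c + off - kx;
              if (ocol < 0 || ocol >= g.oW) continue;
              dst[orow * g.oW + ocol] += src[r * g.iW + c];
            }
          }
        }
      }
    }
  }
}

void tconv_gather(const fmat& dOut, fmat& dCols, int bs, const TconvGeom& g,
                  int Cout) {
  const int ipix = g.ipix(), opix = g.opix(), kk2 = g.k * g.k;
  const int off = 2;
  dCols.zeros(static_cast<uword>(bs) * ipix, static_cast<uword>(Cout) * kk2);
  for (int co = 0; co < Cout; ++co) {
    const float* out_col = dOut.colptr(co);
    for (int ky = 0; ky < g.k; ++ky) {
      for (int kx = 0; kx < g.k; ++kx) {
        float* col = dCols.colptr(static_cast<uword>(co) * kk2 + ky * g.k + kx);
        for (int s = 0; s < bs; ++s) {
          float* dst = col + static_cast<size_t>(s) * ipix;
          const float* src = out_col + static_cast<size_t>(s) * opix;
          for (int r = 0; r < g.iH; ++r) {
            const int orow = 2 * r + off - ky;
            if (orow < 0 || orow >= g.oH) continue;
            for (int c = 0; c < g.iW; ++c) {
              const int ocol = 2 * c + off - kx;
              if (ocol < 0 || ocol >= g.oW) continue;
              dst[r * g.iW + c] = src[orow * g.oW + ocol];
            }
          }
        }
      }
    }
  }
}

inline void relu_(fmat& X) { X.for_each([](float& v) { if (v < 0.f) v = 0.f; }); }

inline void relu_back_(fmat& dX, const fmat& Z) {
  const uword n = dX.n_elem;
  const float* z = Z.memptr();
  float* d = dX.memptr();
  for (uword i = 0; i < n; ++i) if (z[i] <= 0.f) d[i] = 0.f;
}

struct AdamState {
  fmat m, v;
  void init(const fmat& w) { m.zeros(size(w)); v.zeros(size(w)); }
  void step(fmat& w, const fmat& g, float lr, int t) {
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    m = b1 * m + (1.f - b1) * g;
    v = b2 * v + (1.f - b2) * square(g);
    const float c1 = 1.f - std::pow(b1, static_cast<float>(t));
    const float c2 = 1.f - std::pow(b2, static_cast<float>(t));
    w -= lr * (m / c1) / (sqrt(v / c2) + eps);
  }
};

struct Net {
  int side, c1, c2, k;
  ConvGeom g1, g2;
  TconvGeom td1, td2;
  fmat K1, K2, Kd1, Kd2;
  frowvec b1, b2, bd1, bd2;

  // forward intermediates (batch)
  fmat X1col, Z1, Z1p, X2col, Z2, B2, Cols1, H1, Cols2, H;

  Net(int side_, int c1_, int c2_, int k_)
    : side(side_), c1(c1_), c2(c2_), k(k_),
      g1(side_, side_, k_, (k_ - 1) / 2),
      g2(side_ / 2, side_ / 2, k_, (k_ - 1) / 2),
      td1(side_ / 4, side_ / 4, k_),
      td2(side_ / 2, side_ / 2, k_) {}

  void forward(const fmat& B, int bs) {
    im2col(B, X1col, bs, g1, 1);
    Z1 = X1col * K1;
    Z1.each_row() += b1;
    relu_(Z1);
    avgpool(Z1, Z1p, bs, side, side, c1);
    im2col(Z1p, X2col, bs, g2, c1);
    Z2 = X2col * K2;
    Z2.each_row() += b2;
    relu_(Z2);
    avgpool(Z2, B2, bs, side / 2, side / 2, c2);
    Cols1 = B2 * Kd1;                 // (bs*ipix) x (c1*k^2)
    tconv_scatter(Cols1, H1, bs, td1, c1);
    H1.each_row() += bd1;
    relu_(H1);
    Cols2 = H1 * Kd2;                 // (bs*ipix) x k^2
    tconv_scatter(Cols2, H, bs, td2, 1);
    H.each_row() += bd2;
    relu_(H);
  }
};

fmat as_fmat(const Rcpp::NumericMatrix& m) {
  fmat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i)
      out(i, j) = static_cast<float>(m(i, j));
  return out;
}

frowvec as_frowvec(const Rcpp::NumericVector& v) {
  frowvec out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = static_cast<float>(v[i]);
  return out;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(const Rcpp::NumericMatrix& x, int side, int c1, int c2,
                         int k, double lr, int n_iter,
                         const Rcpp::IntegerMatrix& batch_idx,
                         const Rcpp::List& init) {
  const int ns = x.nrow(), P = x.ncol();
  if (P != side * side) Rcpp::stop("grid size mismatch");
  fmat X = as_fmat(x);   // ns x P, one flattened grid per row

  Net net(side, c1, c2, k);
  net.K1 = as_fmat(init["K1"]);   net.b1 = as_frowvec(init["b1"]);
  net.K2 = as_fmat(init["K2"]);   net.b2 = as_frowvec(init["b2"]);
  net.Kd1 = as_fmat(init["Kd1"]); net.bd1 = as_frowvec(init["bd1"]);
  net.Kd2 = as_fmat(init["Kd2"]); net.bd2 = as_frowvec(init["bd2"]);

  AdamState aK1, ab1, aK2, ab2, aKd1, abd1, aKd2, abd2;
  aK1.init(net.K1); aK2.init(net.K2); aKd1.init(net.Kd1); aKd2.init(net.Kd2);
  fmat b1m(net.b1), b2m(net.b2), bd1m(net.bd1), bd2m(net.bd2);
  ab1.init(b1m); ab2.init(b2m); abd1.init(bd1m); abd2.init(bd2m);

  const int bs = batch_idx.ncol();
  fmat Bstack(static_cast<uword>(bs) * P, 1);
  std::vector<double> loss(n_iter);
  // gradient buffers hoisted out of the loop so large blocks are reused
  fmat dH, dPd2, dH1, dPd1, dB2, dZ2, dP2, dZ1p, dZ1, dP1;
  fmat dKd2, dKd1, dK2, dK1, dCols2, dCols1, dX2col;
  frowvec dbd2, dbd1, db2, db1;

  for (int t = 0; t < n_iter; ++t) {
    // stack batch rows into the (bs*P) x 1 pixel layout used by the net
    for (int s = 0; s < bs; ++s) {
      const int r = batch_idx(t, s) - 1;
      float* dst = Bstack.memptr() + static_cast<size_t>(s) * P;
      for (int p = 0; p < P; ++p) dst[p] = X.at(r, p);
    }

    net.forward(Bstack, bs);

    dH = 2.f * (net.H - Bstack);
    loss[t] = accu(square(net.H - Bstack)) / bs;

    dPd2 = dH; relu_back_(dPd2, net.H);
    dbd2 = sum(dPd2, 0);
    tconv_gather(dPd2, dCols2, bs, net.td2, 1);
    dKd2 = net.H1.t() * dCols2;
    dH1 = dCols2 * net.Kd2.t();

    dPd1 = dH1; relu_back_(dPd1, net.H1);
    dbd1 = sum(dPd1, 0);
    tconv_gather(dPd1, dCols1, bs, net.td1, c1);
    dKd1 = net.B2.t() * dCols1;
    dB2 = dCols1 * net.Kd1.t();

    avgpool_back(dB2, dZ2, bs, side / 2, side / 2, c2);
    dP2 = dZ2; relu_back_(dP2, net.Z2);
    dK2 = net.X2col.t() * dP2;
    db2 = sum(dP2, 0);
    dX2col = dP2 * net.K2.t();
    col2im(dX2col, dZ1p, bs, net.g2, c1);

    avgpool_back(dZ1p, dZ1, bs, side, side, c1);
    dP1 = dZ1; relu_back_(dP1, net.Z1);
    dK1 = net.X1col.t() * dP1;
    db1 = sum(dP1, 0);

    const int step = t + 1;
    aK1.step(net.K1, dK1, lr, step);
    aK2.step(net.K2, dK2, lr, step);
    aKd1.step(net.Kd1, dKd1, lr, step);
    aKd2.step(net.Kd2, dKd2, lr, step);
    b1m = net.b1; ab1.step(b1m, fmat(db1), lr, step); net.b1 = b1m.row(0);
    b2m = net.b2; ab2.step(b2m, fmat(db2), lr, step); net.b2 = b2m.row(0);
    bd1m = net.bd1; abd1.step(bd1m, fmat(dbd1), lr, step); net.bd1 = bd1m.row(0);
    bd2m = net.bd2; abd2.step(bd2m, fmat(dbd2), lr, step); net.bd2 = bd2m.row(0);
  }

  // final full forward pass in chunks: reconstructions + bottleneck features
  mat recon(ns, P);
  const int fdim = c2 * (side / 4) * (side / 4);
  mat bottleneck(ns, fdim);
  fmat Cstack;
  for (int start = 0; start < ns; start += bs) {
    const int m = std::min(bs, ns - start);
    Cstack.set_size(static_cast<uword>(m) * P, 1);
    for (int s = 0; s < m; ++s)
      for (int p = 0; p < P; ++p)
        Cstack(static_cast<uword>(s) * P + p, 0) = X(start + s, p);
    net.forward(Cstack, m);
    for (int s = 0; s < m; ++s) {
      for (int p = 0; p < P; ++p)
        recon(start + s, p) = net.H(static_cast<uword>(s) * P + p, 0);
      const int qpix = (side / 4) * (side / 4);
      for (int c = 0; c < c2; ++c)
        for (int p = 0; p < qpix; ++p)
          bottleneck(start + s, static_cast<size_t>(c) * qpix + p) =
            net.B2(static_cast<uword>(s) * qpix + p, c);
    }
  }

  Rcpp::List weights = Rcpp::List::create(
    Rcpp::Named("K1") = conv_to<mat>::from(net.K1),
    Rcpp::Named("b1") = conv_to<rowvec>::from(net.b1),
    Rcpp::Named("K2") = conv_to<mat>::from(net.K2),
    Rcpp::Named("b2") = conv_to<rowvec>::from(net.b2),
    Rcpp::Named("Kd1") = conv_to<mat>::from(net.Kd1),
    Rcpp::Named("bd1") = conv_to<rowvec>::from(net.bd1),
    Rcpp::Named("Kd2") = conv_to<mat>::from(net.Kd2),
    Rcpp::Named("bd2") = conv_to<rowvec>::from(net.bd2));

  return Rcpp::List::create(
    Rcpp::Named("recon") = recon,
    Rcpp::Named("bottleneck") = bottleneck,
    Rcpp::Named("loss") = loss,
    Rcpp::Named("weights") = weights);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cnn_forward_cpp(const Rcpp::NumericMatrix& x, int side,
                                    int c1, int c2, int k,
                                    const Rcpp::List& weights) {
  const int ns = x.nrow(), P = x.ncol();
  if (P != side * side) Rcpp::stop("grid size mismatch");
  fmat X = as_fmat(x);
  Net net(side, c1, c2, k);
  net.K1 = as_fmat(weights["K1"]);   net.b1 = as_frowvec(weights["b1"]);
  net.K2 = as_fmat(weights["K2"]);   net.b2 = as_frowvec(weights["b2"]);
  net.Kd1 = as_fmat(weights["Kd1"]); net.bd1 = as_frowvec(weights["bd1"]);
  net.Kd2 = as_fmat(weights["Kd2"]); net.bd2 = as_frowvec(weights["bd2"]);

  Rcpp::NumericMatrix recon(ns, P);
  const int chunk = 128;
  fmat Cstack;
  for (int start = 0; start < ns; start += chunk) {
    const int m = std::min(chunk, ns - start);
    Cstack.set_size(static_cast<uword>(m) * P, 1);
    for (int s = 0; s < m; ++s)
      for (int p = 0; p < P; ++p)
        Cstack(static_cast<uword>(s) * P + p, 0) = X(start + s, p);
    net.forward(Cstack, m);
    for (int s = 0; s < m; ++s)
      for (int p = 0; p < P; ++p)
        recon(start + s, p) = net.H(static_cast<uword>(s) * P + p, 0);
  }
  return recon;
}
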