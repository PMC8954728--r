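// Dual-branch convolutional network for signature-image affinity regression.
//
// Each branch is three (3x3 valid convolution + ReLU -> 2x2 max-pool) blocks
// followed by a flatten; the two flatten vectors are concatenated and fed to
// dropout -> dense(ReLU) -> dropout -> dense(linear).  Training minimises the
// mean squared error.  All heavy arithmetic goes through BLAS GEMM on
// single-precision matrices via an im2col layout; gradients are accumulated
// over small sample chunks so memory stays bounded at any batch size.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

namespace {

constexpr int CHUNK = 32;  // samples processed per inner pass

struct ConvDims {
  int H, W, Cin, Cout;   // input height/width/channels, output channels
  int Ho, Wo;            // post-convolution (valid, 3x3)
  int Hp, Wp;            // post 2x2/2 max-pool (floor)
  ConvDims(int h, int w, int cin, int cout)
      : H(h), W(w), Cin(cin), Cout(cout),
        Ho(h - 2), Wo(w - 2), Hp((h - 2) / 2), Wp((w - 2) / 2) {}
};

// Scratch space for one conv layer over one chunk of samples.
struct ConvScratch {
  std::vector<fmat> col;    // (Ho*Wo) x (9*Cin), per sample
  std::vector<fmat> z;      // (Ho*Wo) x Cout pre-activation, per sample
  std::vector<umat> amax;   // (Hp*Wp) x Cout argmax linear index, per sample
  std::vector<fcube> out;   // Hp x Wp x Cout pooled output, per sample
  void resize(const ConvDims& d) {
    col.assign(CHUNK, fmat(d.Ho * d.Wo, 9 * d.Cin));
    z.assign(CHUNK, fmat(d.Ho * d.Wo, d.Cout));
    amax.assign(CHUNK, umat(d.Hp * d.Wp, d.Cout));
    out.assign(CHUNK, fcube(d.Hp, d.Wp, d.Cout));
  }
};

// column j = c*9 + dx*3 + dy holds the (dy,dx)-shifted window of channel c,
// rows in column-major pixel order (index = x*Ho + y).
void im2col3(const fcube& X, const ConvDims& d, fmat& col) {
  for (int c = 0; c < d.Cin; ++c)
    for (int dx = 0; dx < 3; ++dx)
      for (int dy = 0; dy < 3; ++dy)
        col.col(c * 9 + dx * 3 + dy) =
            vectorise(X.slice(c).submat(dy, dx, dy + d.Ho - 1, dx + d.Wo - 1));
}

void col2im3(const fmat& dcol, const ConvDims& d, fcube& dX) {
  dX.zeros();
  for (int c = 0; c < d.Cin; ++c)
    for (int dx = 0; dx < 3; ++dx)
      for (int dy = 0; dy < 3; ++dy)
        dX.slice(c).submat(dy, dx, dy + d.Ho - 1, dx + d.Wo - 1) +=
            reshape(dcol.col(c * 9 + dx * 3 + dy), d.Ho, d.Wo);
}

// conv -> ReLU -> max-pool for one sample; fills scratch slot i.
void conv_block_fwd(const fcube& X, const fmat& W, const frowvec& b,
                    const ConvDims& d, ConvScratch& s, int i) {
  im2col3(X, d, s.col[i]);
  s.z[i] = s.col[i] * W;
  s.z[i].each_row() += b;
  // ReLU is folded into the pool: pooled value = max(0, window max of z);
  // amax records the window max of z so the backward ReLU mask stays exact
  for (int c = 0; c < d.Cout; ++c) {
    const float* zc = s.z[i].colptr(c);
    float* oc = s.out[i].slice_memptr(c);
    uword* ac = s.amax[i].colptr(c);
    for (int px = 0; px < d.Wp; ++px) {
      const float* col0 = zc + 2 * px * d.Ho;
      const float* col1 = col0 + d.Ho;
      for (int py = 0; py < d.Hp; ++py) {
        const int y0 = 2 * py;
        float best = col0[y0];
        int bo = 2 * px * d.Ho + y0;
        if (col0[y0 + 1] > best) { best = col0[y0 + 1]; bo = 2 * px * d.Ho + y0 + 1; }
        if (col1[y0] > best) { best = col1[y0]; bo = (2 * px + 1) * d.Ho + y0; }
        if (col1[y0 + 1] > best) { best = col1[y0 + 1]; bo = (2 * px + 1) * d.Ho + y0 + 1; }
        oc[px * d.Hp + py] = best > 0.0f ? best : 0.0f;
        ac[px * d.Hp + py] = (uword)bo;
      }
    }
  }
}

// backward through pool+ReLU+conv; accumulates dW/db, optionally emits dX.
void conv_block_bwd(const fcube& dOut, const ConvDims& d, const ConvScratch& s,
                    int i, const fmat& W, fmat& dW, frowvec& db,
                    fcube* dX) {
  fmat dZ(d.Ho * d.Wo, d.Cout, fill::zeros);
  for (int c = 0; c < d.Cout; ++c) {
    // pool windows are disjoint: plain scatter of the pooled gradient onto
    // the argmax cell, masked by the ReLU derivative at that cell
    const float* dp = dOut.slice_memptr(c);
    const float* zc = s.z[i].colptr(c);
    const uword* ac = s.amax[i].colptr(c);
    float* dzc = dZ.colptr(c);
    const int np = d.Hp * d.Wp;
    for (int p = 0; p < np; ++p)
      if (zc[ac[p]] > 0.0f) dzc[ac[p]] = dp[p];
  }
  dW += s.col[i].t() * dZ;
  db += sum(dZ, 0);
  if (dX) {
    const fmat dcol = dZ * W.t();
    col2im3(dcol, d, *dX);
  }
}

struct Params {
  fmat mW1, mW2, mW3, pW1, pW2, pW3, Wd, Wo_;
  frowvec mb1, mb2, mb3, pb1, pb2, pb3, bd;
  float bo;
  static Params from_list(const Rcpp::List& p) {
    Params q;
    q.mW1 = conv_to<fmat>::from(Rcpp::as<mat>(p["mW1"]));
    q.mW2 = conv_to<fmat>::from(Rcpp::as<mat>(p["mW2"]));
    q.mW3 = conv_to<fmat>::from(Rcpp::as<mat>(p["mW3"]));
    q.pW1 = conv_to<fmat>::from(Rcpp::as<mat>(p["pW1"]));
    q.pW2 = conv_to<fmat>::from(Rcpp::as<mat>(p["pW2"]));
    q.pW3 = conv_to<fmat>::from(Rcpp::as<mat>(p["pW3"]));
    q.Wd  = conv_to<fmat>::from(Rcpp::as<mat>(p["Wd"]));
    q.Wo_ = conv_to<fmat>::from(Rcpp::as<mat>(p["Wo"]));
    q.mb1 = conv_to<frowvec>::from(Rcpp::as<rowvec>(p["mb1"]));
    q.mb2 = conv_to<frowvec>::from(Rcpp::as<rowvec>(p["mb2"]));
    q.mb3 = conv_to<frowvec>::from(Rcpp::as<rowvec>(p["mb3"]));
    q.pb1 = conv_to<frowvec>::from(Rcpp::as<rowvec>(p["pb1"]));
    q.pb2 = conv_to<frowvec>::from(Rcpp::as<rowvec>(p["pb2"]));
    q.pb3 = conv_to<frowvec>::from(Rcpp::as<rowvec>(p["pb3"]));
    q.bd  = conv_to<frowvec>::from(Rcpp::as<rowvec>(p["bd"]));
    q.bo  = (float)Rcpp::as<double>(p["bo"]);
    return q;
  }
};

struct Dims {
  ConvDims m1, m2, m3, p1, p2, p3;
  int mol_flat, prot_flat, concat, hidden;
  Dims(int mside, int pside, int f1, int f2, int f3, int hid)
      : m1(mside, mside, 1, f1),
        m2(m1.Hp, m1.Wp, f1, f2),
        m3(m2.Hp, m2.Wp, f2, f3),
        p1(pside, pside, 1, f1),
        p2(p1.Hp, p1.Wp, f1, f2),
        p3(p2.Hp, p2.Wp, f2, f3),
        mol_flat(m3.Hp * m3.Wp * f3),
        prot_flat(p3.Hp * p3.Wp * f3),
        concat(mol_flat + prot_flat),
        hidden(hid) {}
};

Dims dims_from(const Params& q, int mside, int pside) {
  const int f1 = q.mW1.n_cols, f2 = q.mW2.n_cols, f3 = q.mW3.n_cols;
  return Dims(mside, pside, f1, f2, f3, q.Wd.n_cols);
}

// run one branch forward for sample chunk slot i; returns flatten vector
frowvec branch_fwd(const fcube& img, const fmat& W1, const frowvec& b1,
                   const fmat& W2, const frowvec& b2, const fmat& W3,
                   const frowvec& b3, const ConvDims& d1, const ConvDims& d2,
                   const ConvDims& d3, ConvScratch& s1, ConvScratch& s2,
                   ConvScratch& s3, int i) {
  conv_block_fwd(img, W1, b1, d1, s1, i);
  conv_block_fwd(s1.out[i], W2, b2, d2, s2, i);
  conv_block_fwd(s2.out[i], W3, b3, d3, s3, i);
  return conv_to<frowvec>::from(vectorise(s3.out[i]).t());
}

}  // namespace

// Forward + backward over one batch.  xmol: mside x mside x n, xprot: pside x
// pside x n, y: n.  mask1 (n x concat) and mask2 (n x hidden) are 0/1 inverted
// dropout masks already divided by the keep probability (pass all-ones for
// evaluation-mode gradients).  Returns total squared error, predictions and
// gradients of the mean squared error over the batch.
// [[Rcpp::export]]
Rcpp::List cnn_forward_backward(Rcpp::List params,
                                arma::cube xmol, arma::cube xprot,
                                arma::vec y,
                                arma::mat mask1, arma::mat mask2) {
  const Params q = Params::from_list(params);
  const int n = xmol.n_slices;
  const int mside = xmol.n_rows, pside = xprot.n_rows;
  const Dims D = dims_from(q, mside, pside);
  if ((int)q.Wd.n_rows != D.concat)
    Rcpp::stop("dense weight rows (%d) do not match concat width (%d)",
               (int)q.Wd.n_rows, D.concat);

  const fmat M1 = conv_to<fmat>::from(mask1), M2 = conv_to<fmat>::from(mask2);
  const fvec yf = conv_to<fvec>::from(y);

  ConvScratch sm1, sm2, sm3, sp1, sp2, sp3;
  sm1.resize(D.m1); sm2.resize(D.m2); sm3.resize(D.m3);
  sp1.resize(D.p1); sp2.resize(D.p2); sp3.resize(D.p3);

  fmat dmW1(size(q.mW1), fill::zeros), dmW2(size(q.mW2), fill::zeros),
       dmW3(size(q.mW3), fill::zeros), dpW1(size(q.pW1), fill::zeros),
       dpW2(size(q.pW2), fill::zeros), dpW3(size(q.pW3), fill::zeros),
       dWd(size(q.Wd), fill::zeros), dWo(size(q.Wo_), fill::zeros);
  frowvec dmb1(q.mb1.n_elem, fill::zeros), dmb2(q.mb2.n_elem, fill::zeros),
          dmb3(q.mb3.n_elem, fill::zeros), dpb1(q.pb1.n_elem, fill::zeros),
          dpb2(q.pb2.n_elem, fill::zeros), dpb3(q.pb3.n_elem, fill::zeros),
          dbd(q.bd.n_elem, fill::zeros);
  float dbo = 0.0f, sse = 0.0f;
  vec yhat(n);

  for (int start = 0; start < n; start += CHUNK) {
    const int cs = std::min(CHUNK, n - start);
    fmat F(cs, D.concat);
    for (int i = 0; i < cs; ++i) {
      fcube xm = conv_to<fcube>::from(
          cube(xmol.slice_memptr(start + i), mside, mside, 1));
      fcube xp = conv_to<fcube>::from(
          cube(xprot.slice_memptr(start + i), pside, pside, 1));
      F.submat(i, 0, i, D.mol_flat - 1) =
          branch_fwd(xm, q.mW1, q.mb1, q.mW2, q.mb2, q.mW3, q.mb3,
                     D.m1, D.m2, D.m3, sm1, sm2, sm3, i);
      F.submat(i, D.mol_flat, i, D.concat - 1) =
          branch_fwd(xp, q.pW1, q.pb1, q.pW2, q.pb2, q.pW3, q.pb3,
                     D.p1, D.p2, D.p3, sp1, sp2, sp3, i);
    }
    // head: dropout -> dense ReLU -> dropout -> dense linear
    const fmat Fd = F % M1.rows(start, start + cs - 1);
    fmat Zh = Fd * q.Wd;
    Zh.each_row() += q.bd;
    const fmat H = clamp(Zh, 0.0f, std::numeric_limits<float>::max());
    const fmat Hd = H % M2.rows(start, start + cs - 1);
    fvec out = Hd * q.Wo_ + q.bo;

    const fvec resid = out - yf.subvec(start, start + cs - 1);
    sse += dot(resid, resid);
    for (int i = 0; i < cs; ++i) yhat(start + i) = out(i);

    // backward head; dL/dout = 2 * resid / n  (MSE over the full batch)
    const fvec dout = (2.0f / (float)n) * resid;
    dWo += Hd.t() * dout;
    dbo += accu(dout);
    fmat dHd = dout * q.Wo_.t();
    fmat dZh = (dHd % M2.rows(start, start + cs - 1)) %
               conv_to<fmat>::from(Zh > 0.0f);
    dWd += Fd.t() * dZh;
    dbd += sum(dZh, 0);
    fmat dF = (dZh * q.Wd.t()) % M1.rows(start, start + cs - 1);

    // backward branches per sample
    fcube dm3(D.m3.Hp, D.m3.Wp, D.m3.Cout), dp3(D.p3.Hp, D.p3.Wp, D.p3.Cout);
    fcube dm2(D.m2.Hp, D.m2.Wp, D.m2.Cout), dp2(D.p2.Hp, D.p2.Wp, D.p2.Cout);
    fcube dm2in(D.m3.H, D.m3.W, D.m3.Cin), dp2in(D.p3.H, D.p3.W, D.p3.Cin);
    fcube dm1in(D.m2.H, D.m2.W, D.m2.Cin), dp1in(D.p2.H, D.p2.W, D.p2.Cin);
    for (int i = 0; i < cs; ++i) {
      for (int j = 0; j < D.mol_flat; ++j) dm3(j) = dF(i, j);
      for (int j = 0; j < D.prot_flat; ++j) dp3(j) = dF(i, D.mol_flat + j);
      conv_block_bwd(dm3, D.m3, sm3, i, q.mW3, dmW3, dmb3, &dm2in);
      conv_block_bwd(dm2in, D.m2, sm2, i, q.mW2, dmW2, dmb2, &dm1in);
      conv_block_bwd(dm1in, D.m1, sm1, i, q.mW1, dmW1, dmb1, nullptr);
      conv_block_bwd(dp3, D.p3, sp3, i, q.pW3, dpW3, dpb3, &dp2in);
      conv_block_bwd(dp2in, D.p2, sp2, i, q.pW2, dpW2, dpb2, &dp1in);
      conv_block_bwd(dp1in, D.p1, sp1, i, q.pW1, dpW1, dpb1, nullptr);
    }
  }

  auto m = [](const fmat& x) { return conv_to<mat>::from(x); };
  auto r = [](const frowvec& x) { return conv_to<rowvec>::from(x); };
  return Rcpp::List::create(
      Rcpp::Named("loss") = (double)(sse / n),
      Rcpp::Named("yhat") = yhat,
      Rcpp::Named("grads") = Rcpp::List::create(
          Rcpp::Named("mW1") = m(dmW1), Rcpp::Named("mb1") = r(dmb1),
          Rcpp::Named("mW2") = m(dmW2), Rcpp::Named("mb2") = r(dmb2),
          Rcpp::Named("mW3") = m(dmW3), Rcpp::Named("mb3") = r(dmb3),
          Rcpp::Named("pW1") = m(dpW1), Rcpp::Named("pb1") = r(dpb1),
          Rcpp::Named("pW2") = m(dpW2), Rcpp::Named("pb2") = r(dpb2),
          Rcpp::Named("pW3") = m(dpW3), Rcpp::Named("pb3") = r(dpb3),
          Rcpp::Named("Wd") = m(dWd), Rcpp::Named("bd") = r(dbd),
          Rcpp::Named("Wo") = m(dWo), Rcpp::Named("bo") = (double)dbo));
}

// Inference-mode forward pass (dropout layers act as identity).
// [[Rcpp::export]]
arma::vec cnn_predict(Rcpp::List params, arma::cube xmol, arma::cube xprot) {
  const Params q = Params::from_list(params);
  const int n = xmol.n_slices;
  const int mside = xmol.n_rows, pside = xprot.n_rows;
  const Dims D = dims_from(q, mside, pside);
  if ((int)q.Wd.n_rows != D.concat)
    Rcpp::stop("dense weight rows (%d) do not match concat width (%d)",
               (int)q.Wd.n_rows, D.concat);

  ConvScratch sm1, sm2, sm3, sp1, sp2, sp3;
  sm1.resize(D.m1); sm2.resize(D.m2); sm3.resize(D.m3);
  sp1.resize(D.p1); sp2.resize(D.p2); sp3.resize(D.p3);

  vec yhat(n);
  for (int start = 0; start < n; start += CHUNK) {
    const int cs = std::min(CHUNK, n - start);
    fmat F(cs, D.concat);
    for (int i = 0; i < cs; ++i) {
      fcube xm = conv_to<fcube>::from(
          cube(xmol.slice_memptr(start + i), mside, mside, 1));
      fcube xp = conv_to<fcube>::from(
          cube(xprot.slice_memptr(start + i), pside, pside, 1));
      F.submat(i, 0, i, D.mol_flat - 1) =
          branch_fwd(xm, q.mW1, q.mb1, q.mW2, q.mb2, q.mW3, q.mb3,
                     D.m1, D.m2, D.m3, sm1, sm2, sm3, i);
      F.submat(i, D.mol_flat, i, D.concat - 1) =
          branch_fwd(xp, q.pW1, q.pb1, q.pW2, q.pb2, q.pW3, q.pb3,
                     D.p1, D.p2, D.p3, sp1, sp2, sp3, i);
    }
    fmat Zh = F * q.Wd;
    Zh.each_row() += q.bd;
    const fmat H = clamp(Zh, 0.0f, std::numeric_limits<float>::max());
    fvec out = H * q.Wo_ + q.bo;
    for (int i = 0; i < cs; ++i) yhat(start + i) = out(i);
  }
  return yhat;
}

// Flatten widths implied by an architecture, without building weights:
// side -> conv(3x3 valid) -> pool(2x2 floor), three times, times f3 channels.
// [[Rcpp::export]]
Rcpp::IntegerVector cnn_flatten_width(int side, int f3) {
  int s = side;
  for (int i = 0; i < 3; ++i) s = (s - 2) / 2;
  return Rcpp::IntegerVector::create(s, s * f3 * s);
}
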