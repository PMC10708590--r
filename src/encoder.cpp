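// Forward and backward passes of the shared feature extractor:
// a stack of 1-D convolution blocks (valid convolution over time, ReLU)
// followed by two LSTM layers; the last LSTM hidden state is projected
// linearly to the H-dimensional embedding z, from which two affine heads
// produce the known-class and novel-class logits.
//
// Parameters arrive as a named R list of numeric arrays; gradients are
// returned under the same names. All state needed for the backward pass is
// cached by the forward pass, so training steps are forward() + backward()
// with no hidden globals.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

static mat sigmoid(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// Gather timestep t across slices: returns (features x N)
static mat slice_t(const cube& x, arma::uword t) {
  mat out(x.n_rows, x.n_slices);
  for (arma::uword n = 0; n < x.n_slices; ++n) out.col(n) = x.slice(n).col(t);
  return out;
}

struct ConvCache {
  cube input;   // (Cin, Lin, N)
  cube pre;     // (F, Lout, N) pre-ReLU
};

struct LstmCache {
  cube input;   // (in, T, N)
  cube i, f, g, o, c, h;  // (H, T, N)
};

// ---- conv block -----------------------------------------------------------

static cube conv_forward(const cube& x, const cube& W, const vec& b,
                         int stride, ConvCache* cache) {
  const arma::uword F = W.n_rows, Cin = W.n_cols, K = W.n_slices;
  const arma::uword Lin = x.n_cols, N = x.n_slices;
  if (x.n_rows != Cin) stop("conv: channel mismatch");
  if (Lin < K) stop("conv: window shorter than kernel");
  const arma::uword Lout = (Lin - K) / stride + 1;
  // reshape weights to (F, Cin*K): column index c*K + k
  mat W2(F, Cin * K);
  for (arma::uword c = 0; c < Cin; ++c)
    for (arma::uword k = 0; k < K; ++k)
      W2.col(c * K + k) = W.slice(k).col(c);
  cube out(F, Lout, N);
  mat xcol(Cin * K, Lout);
  for (arma::uword n = 0; n < N; ++n) {
    const mat& xs = x.slice(n);
    for (arma::uword t = 0; t < Lout; ++t)
      for (arma::uword c = 0; c < Cin; ++c)
        for (arma::uword k = 0; k < K; ++k)
          xcol(c * K + k, t) = xs(c, t * stride + k);
    mat pre = W2 * xcol;
    pre.each_col() += b;
    out.slice(n) = pre;
  }
  if (cache) { cache->input = x; cache->pre = out; }
  // ReLU
  cube relu = out;
  relu.transform([](double v) { return v > 0 ? v : 0.0; });
  return relu;
}

static cube conv_backward(const ConvCache& cache, const cube& W, int stride,
                          const cube& dout, cube& dW, vec& db) {
  const arma::uword F = W.n_rows, Cin = W.n_cols, K = W.n_slices;
  const arma::uword Lin = cache.input.n_cols, N = cache.input.n_slices;
  const arma::uword Lout = dout.n_cols;
  mat W2(F, Cin * K);
  for (arma::uword c = 0; c < Cin; ++c)
    for (arma::uword k = 0; k < K; ++k)
      W2.col(c * K + k) = W.slice(k).col(c);
  mat dW2(F, Cin * K, arma::fill::zeros);
  db.zeros(F);
  cube dx(Cin, Lin, N, arma::fill::zeros);
  mat xcol(Cin * K, Lout);
  for (arma::uword n = 0; n < N; ++n) {
    // ReLU gate
    mat dpre = dout.slice(n) % arma::conv_to<mat>::from(cache.pre.slice(n) > 0);
    const mat& xs = cache.input.slice(n);
    for (arma::uword t = 0; t < Lout; ++t)
      for (arma::uword c = 0; c < Cin; ++c)
        for (arma::uword k = 0; k < K; ++k)
          xcol(c * K + k, t) = xs(c, t * stride + k);
    dW2 += dpre * xcol.t();
    db += arma::sum(dpre, 1);
    mat dxcol = W2.t() * dpre;   // (Cin*K, Lout)
    mat& dxs = dx.slice(n);
    for (arma::uword t = 0; t < Lout; ++t)
      for (arma::uword c = 0; c < Cin; ++c)
        for (arma::uword k = 0; k < K; ++k)
          dxs(c, t * stride + k) += dxcol(c * K + k, t);
  }
  dW.set_size(F, Cin, K);
  for (arma::uword c = 0; c < Cin; ++c)
    for (arma::uword k = 0; k < K; ++k)
      dW.slice(k).col(c) = dW2.col(c * K + k);
  return dx;
}

// ---- LSTM layer -----------------------------------------------------------
// gate order in W/U/b rows: input, forget, cell, output (4H rows)

static cube lstm_forward(const cube& x, const mat& W, const mat& U,
                         const vec& b, LstmCache* cache) {
  const arma::uword H = U.n_cols, T = x.n_cols, N = x.n_slices;
  cube gi(H, T, N), gf(H, T, N), gg(H, T, N), go(H, T, N),
       cs(H, T, N), hs(H, T, N);
  mat h(H, N, arma::fill::zeros), c(H, N, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t) {
    mat xt = slice_t(x, t);
    mat a = W * xt + U * h;
    a.each_col() += b;
    mat i = sigmoid(a.rows(0, H - 1));
    mat f = sigmoid(a.rows(H, 2 * H - 1));
    mat g = arma::tanh(a.rows(2 * H, 3 * H - 1));
    mat o = sigmoid(a.rows(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % arma::tanh(c);
    for (arma::uword n = 0; n < N; ++n) {
      gi.slice(n).col(t) = i.col(n); gf.slice(n).col(t) = f.col(n);
      gg.slice(n).col(t) = g.col(n); go.slice(n).col(t) = o.col(n);
      cs.slice(n).col(t) = c.col(n); hs.slice(n).col(t) = h.col(n);
    }
  }
  if (cache) {
    cache->input = x;
    cache->i = gi; cache->f = gf; cache->g = gg; cache->o = go;
    cache->c = cs; cache->h = hs;
  }
  return hs;
}

// dh_seq: gradient w.r.t. h at every timestep (H, T, N); returns dx
static cube lstm_backward(const LstmCache& cache, const mat& W, const mat& U,
                          const cube& dh_seq, mat& dW, mat& dU, vec& db) {
  const arma::uword H = U.n_cols, T = cache.input.n_cols,
                    N = cache.input.n_slices, In = cache.input.n_rows;
  dW.zeros(4 * H, In); dU.zeros(4 * H, H); db.zeros(4 * H);
  cube dx(In, T, N, arma::fill::zeros);
  mat dh_next(H, N, arma::fill::zeros), dc_next(H, N, arma::fill::zeros);
  for (arma::uword tt = T; tt-- > 0;) {
    mat dh = slice_t(dh_seq, tt) + dh_next;
    mat i = slice_t(cache.i, tt), f = slice_t(cache.f, tt),
        g = slice_t(cache.g, tt), o = slice_t(cache.o, tt),
        c = slice_t(cache.c, tt);
    mat tanhc = arma::tanh(c);
    mat dc = dc_next + dh % o % (1 - tanhc % tanhc);
    mat c_prev(H, N, arma::fill::zeros), h_prev(H, N, arma::fill::zeros);
    if (tt > 0) { c_prev = slice_t(cache.c, tt - 1); h_prev = slice_t(cache.h, tt - 1); }
    mat da(4 * H, N);
    da.rows(0, H - 1)         = (dc % g) % i % (1 - i);
    da.rows(H, 2 * H - 1)     = (dc % c_prev) % f % (1 - f);
    da.rows(2 * H, 3 * H - 1) = (dc % i) % (1 - g % g);
    da.rows(3 * H, 4 * H - 1) = (dh % tanhc) % o % (1 - o);
    mat xt = slice_t(cache.input, tt);
    dW += da * xt.t();
    dU += da * h_prev.t();
    db += arma::sum(da, 1);
    mat dxt = W.t() * da;
    for (arma::uword n = 0; n < N; ++n) dx.slice(n).col(tt) = dxt.col(n);
    dh_next = U.t() * da;
    dc_next = dc % f;
  }
  return dx;
}

// ---- whole encoder --------------------------------------------------------

struct EncCaches {
  std::vector<ConvCache> conv;
  std::vector<LstmCache> lstm;
  mat hT, z;
};

// persistent cache between forward and backward (single-threaded trainer)
static EncCaches g_cache;

// [[Rcpp::export]]
List enc_forward(List params, arma::cube x, IntegerVector strides,
                 bool keep_cache) {
  int n_conv = strides.size();
  EncCaches local;
  EncCaches& cc = keep_cache ? g_cache : local;
  cc.conv.assign(n_conv, ConvCache());
  cc.lstm.assign(2, LstmCache());
  cube cur = x;
  for (int b = 0; b < n_conv; ++b) {
    cube W = as<cube>(params[std::string("conv") + std::to_string(b + 1) + "_W"]);
    vec bb = as<vec>(params[std::string("conv") + std::to_string(b + 1) + "_b"]);
    cur = conv_forward(cur, W, bb, strides[b], keep_cache ? &cc.conv[b] : &cc.conv[b]);
  }
  for (int l = 0; l < 2; ++l) {
    mat W = as<mat>(params[std::string("lstm") + std::to_string(l + 1) + "_W"]);
    mat U = as<mat>(params[std::string("lstm") + std::to_string(l + 1) + "_U"]);
    vec bb = as<vec>(params[std::string("lstm") + std::to_string(l + 1) + "_b"]);
    cur = lstm_forward(cur, W, U, bb, &cc.lstm[l]);
  }
  // last timestep hidden state
  mat hT = slice_t(cur, cur.n_cols - 1);
  mat Wz = as<mat>(params["proj_W"]); vec bz = as<vec>(params["proj_b"]);
  mat z = Wz * hT; z.each_col() += bz;
  mat Wl = as<mat>(params["headl_W"]); vec bl = as<vec>(params["headl_b"]);
  mat Wu = as<mat>(params["headu_W"]); vec bu = as<vec>(params["headu_b"]);
  mat ll = Wl * z; ll.each_col() += bl;
  mat lu = Wu * z; lu.each_col() += bu;
  cc.hT = hT; cc.z = z;
  return List::create(_["z"] = z.t(), _["logits_l"] = ll.t(),
                      _["logits_u"] = lu.t());
}

// Gradients w.r.t. all parameters given upstream gradients on z and the two
// heads (each N x dim, matching the transposed forward outputs). Must be
// called right after enc_forward(..., keep_cache = TRUE) on the same batch.
// [[Rcpp::export]]
List enc_backward(List params, IntegerVector strides,
                  arma::mat dz_in, arma::mat dlogits_l, arma::mat dlogits_u) {
  EncCaches& cc = g_cache;
  if (cc.z.n_elem == 0) stop("enc_backward: no cached forward pass");
  mat z = cc.z, hT = cc.hT;
  mat dLl = dlogits_l.t();   // (Cl, N)
  mat dLu = dlogits_u.t();
  mat dz = dz_in.t();        // (H, N)
  mat Wl = as<mat>(params["headl_W"]);
  mat Wu = as<mat>(params["headu_W"]);
  mat Wz = as<mat>(params["proj_W"]);
  List grads;
  grads["headl_W"] = dLl * z.t();
  grads["headl_b"] = vec(arma::sum(dLl, 1));
  grads["headu_W"] = dLu * z.t();
  grads["headu_b"] = vec(arma::sum(dLu, 1));
  mat dz_tot = dz + Wl.t() * dLl + Wu.t() * dLu;
  grads["proj_W"] = dz_tot * hT.t();
  grads["proj_b"] = vec(arma::sum(dz_tot, 1));
  mat dhT = Wz.t() * dz_tot;
  // seed gradient only at the last timestep of the top LSTM
  const LstmCache& top = cc.lstm[1];
  cube dh_seq(top.h.n_rows, top.h.n_cols, top.h.n_slices, arma::fill::zeros);
  for (arma::uword n = 0; n < dh_seq.n_slices; ++n)
    dh_seq.slice(n).col(dh_seq.n_cols - 1) = dhT.col(n);
  cube dcur;
  for (int l = 2; l-- > 0;) {
    mat W = as<mat>(params[std::string("lstm") + std::to_string(l + 1) + "_W"]);
    mat U = as<mat>(params[std::string("lstm") + std::to_string(l + 1) + "_U"]);
    mat dW, dU; vec db;
    dcur = lstm_backward(cc.lstm[l], W, U, l == 1 ? dh_seq : dcur, dW, dU, db);
    grads[std::string("lstm") + std::to_string(l + 1) + "_W"] = dW;
    grads[std::string("lstm") + std::to_string(l + 1) + "_U"] = dU;
    grads[std::string("lstm") + std::to_string(l + 1) + "_b"] = db;
  }
  int n_conv = strides.size();
  for (int b = n_conv; b-- > 0;) {
    cube W = as<cube>(params[std::string("conv") + std::to_string(b + 1) + "_W"]);
    cube dW; vec db;
    dcur = conv_backward(cc.conv[b], W, strides[b], dcur, dW, db);
    grads[std::string("conv") + std::to_string(b + 1) + "_W"] = dW;
    grads[std::string("conv") + std::to_string(b + 1) + "_b"] = db;
  }
  return grads;
}
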