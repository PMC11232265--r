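// Whole-network forward/backward used by the training loop (scale-4
// Res2Net block with one conv per group). All activations and patch
// matrices live in a persistent float state object across steps, so the
// only data crossing the R boundary per step are the input batch, the
// reconstruction, the loss gradient and the parameter gradients. The
// layer-by-layer R path in R/network.R implements the same computation
// and serves the exported operations; the two are checked against each
// other in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// from conv_ops.cpp
void net_im2col(arma::fmat& K, const float* x, size_t cstride, size_t row0,
                int H, int W, int C, int kh, int kw, int pad);
void net_col2im(const arma::fmat& G, float* gx, size_t cstride, size_t row0,
                int H, int W, int C, int kh, int kw, int pad);

namespace {

struct Layer {
  int kh, kw, cin, cout, pad;
  bool relu;
  arma::fmat Wm;   // (kh*kw*cin) x cout
  arma::fvec bias;
};

// Node indices of the fixed topology.
// acts: 0 x, 1 a1, 2 a2, 3 u, 4 z3, 5 z4, 6 cc, 7 v, 8 d1, 9 d2, 10 d3, 11 out
const int N_ACT = 12, N_CONV = 11;

struct NetState {
  int H = 0, W = 0, B = 0;
  std::vector<arma::fmat> act;   // (HW*B) x C
  std::vector<arma::fmat> K;     // patch matrices per conv (empty for 1x1)
  std::vector<arma::fmat> g;     // gradient scratch, same shapes as act
  NetState() : act(N_ACT), K(N_CONV), g(N_ACT) {}
};

std::vector<Layer> read_layers(const List& layers) {
  std::vector<Layer> out;
  for (int i = 0; i < layers.size(); ++i) {
    List l = layers[i];
    NumericVector w = l["w"];
    NumericVector b = l["b"];
    IntegerVector wd = w.attr("dim");
    Layer L;
    L.kh = wd[0]; L.kw = wd[1]; L.cin = wd[2]; L.cout = wd[3];
    L.pad = as<int>(l["pad"]);
    L.relu = as<bool>(l["relu"]);
    L.Wm.set_size((arma::uword)(L.kh * L.kw * L.cin), (arma::uword)L.cout);
    std::copy(w.begin(), w.end(), L.Wm.begin());
    L.bias.set_size(L.cout);
    std::copy(b.begin(), b.end(), L.bias.begin());
    out.push_back(std::move(L));
  }
  return out;
}

// Forward one conv from state act[src] into state act[dst]; builds K[li]
// for 3x3 layers (1x1 layers multiply the activation matrix directly).
void conv_node(NetState& st, std::vector<Layer>& L, int li,
               const arma::fmat& src, arma::fmat& dst) {
  Layer& l = L[li];
  const size_t HW = (size_t)st.H * st.W;
  if (l.kh == 1 && l.kw == 1) {
    dst = src * l.Wm;
  } else {
    arma::fmat& K = st.K[li];
    K.set_size(HW * st.B, (arma::uword)(l.kh * l.kw * l.cin));
    for (int b = 0; b < st.B; ++b)
      net_im2col(K, src.colptr(0) + HW * b, src.n_rows, HW * b,
                 st.H, st.W, l.cin, l.kh, l.kw, l.pad);
    dst = K * l.Wm;
  }
  for (int oc = 0; oc < l.cout; ++oc) dst.col(oc) += l.bias[oc];
  if (l.relu) dst.transform([](float v) { return v > 0.0f ? v : 0.0f; });
}

// Backward through conv li: consumes gdst (gradient at its output,
// already ReLU-masked), emits parameter grads and adds the input
// gradient into gsrc (accumulate = true) or overwrites it.
void conv_node_bwd(NetState& st, std::vector<Layer>& L, int li,
                   const arma::fmat& src, const arma::fmat& gdst,
                   arma::fmat* gsrc, bool accumulate,
                   arma::fmat& gW, arma::fvec& gB) {
  Layer& l = L[li];
  const size_t HW = (size_t)st.H * st.W;
  if (l.kh == 1 && l.kw == 1) {
    gW = src.t() * gdst;
  } else {
    gW = st.K[li].t() * gdst;
  }
  gB = arma::sum(gdst, 0).t();
  if (gsrc == nullptr) return;
  if (l.kh == 1 && l.kw == 1) {
    if (accumulate) *gsrc += gdst * l.Wm.t();
    else *gsrc = gdst * l.Wm.t();
  } else {
    arma::fmat Gcol = gdst * l.Wm.t();
    if (!accumulate) gsrc->zeros(gdst.n_rows, l.cin);
    for (int b = 0; b < st.B; ++b)
      net_col2im(Gcol, gsrc->colptr(0) + HW * b, gsrc->n_rows, HW * b,
                 st.H, st.W, l.cin, l.kh, l.kw, l.pad);
  }
}

inline arma::fmat relu_mask(const arma::fmat& g, const arma::fmat& out) {
  arma::fmat m = g;
  const float* o = out.memptr();
  float* p = m.memptr();
  for (size_t t = 0; t < m.n_elem; ++t) if (o[t] <= 0.0f) p[t] = 0.0f;
  return m;
}

} // namespace

// layers: list of 11 layers in topology order
// (enc1, enc2, block_in, g2, g3, g4, block_out, dec1, dec2, dec3, dec4).
// [[Rcpp::export]]
List cpp_net_forward_fast(List layers, NumericVector x, SEXP state) {
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 4 || xd[2] != 1)
    stop("expected an (H, W, 1, B) input batch");
  const int H = xd[0], W = xd[1], B = xd[3];
  const size_t HW = (size_t)H * W;

  Rcpp::XPtr<NetState> stp =
    (state == R_NilValue) ? Rcpp::XPtr<NetState>(new NetState(), true)
                          : Rcpp::XPtr<NetState>(state);
  NetState& st = *stp;
  st.H = H; st.W = W; st.B = B;
  std::vector<Layer> L = read_layers(layers);
  if (L.size() != (size_t)N_CONV) stop("expected 11 layers");

  st.act[0].set_size(HW * B, 1);
  std::copy(x.begin(), x.end(), st.act[0].begin());

  conv_node(st, L, 0, st.act[0], st.act[1]);       // enc1 -> a1 (32)
  conv_node(st, L, 1, st.act[1], st.act[2]);       // enc2 -> a2 (64)
  conv_node(st, L, 2, st.act[2], st.act[3]);       // block_in -> u (64)
  arma::fmat& u = st.act[3];
  arma::fmat& cc = st.act[6];
  cc.set_size(u.n_rows, 64);
  cc.cols(0, 15) = u.cols(0, 15);                  // y1 = x1
  { arma::fmat x2 = u.cols(16, 31), y2;
    conv_node(st, L, 3, x2, y2);                   // g2
    cc.cols(16, 31) = y2;
    st.act[4] = u.cols(32, 47) + y2;               // z3
    arma::fmat y3;
    conv_node(st, L, 4, st.act[4], y3);            // g3
    cc.cols(32, 47) = y3;
    st.act[5] = u.cols(48, 63) + y3;               // z4
    arma::fmat y4;
    conv_node(st, L, 5, st.act[5], y4);            // g4
    cc.cols(48, 63) = y4;
  }
  conv_node(st, L, 6, cc, st.act[7]);              // block_out -> v
  conv_node(st, L, 7, st.act[7], st.act[8]);       // dec1
  conv_node(st, L, 8, st.act[8], st.act[9]);       // dec2
  conv_node(st, L, 9, st.act[9], st.act[10]);      // dec3
  conv_node(st, L, 10, st.act[10], st.act[11]);    // dec4 (linear)

  NumericVector out(HW * (size_t)B);
  std::copy(st.act[11].begin(), st.act[11].end(), out.begin());
  out.attr("dim") = IntegerVector::create(H, W, 1, B);
  return List::create(_["out"] = out, _["state"] = stp);
}

// [[Rcpp::export]]
List cpp_net_backward_fast(List layers, SEXP state, NumericVector gout) {
  Rcpp::XPtr<NetState> stp(state);
  NetState& st = *stp;
  std::vector<Layer> L = read_layers(layers);
  const size_t HW = (size_t)st.H * st.W;
  if ((size_t)gout.size() != HW * st.B)
    stop("loss gradient does not match the forward batch");

  std::vector<arma::fmat> gW(N_CONV);
  std::vector<arma::fvec> gB(N_CONV);

  arma::fmat g11(HW * st.B, 1);                    // d(loss)/d(out), linear
  std::copy(gout.begin(), gout.end(), g11.begin());

  arma::fmat g10, g9, g8, g7, gcc, gu, g2a, g1a;
  conv_node_bwd(st, L, 10, st.act[10], g11, &g10, false, gW[10], gB[10]);
  g10 = relu_mask(g10, st.act[10]);
  conv_node_bwd(st, L, 9, st.act[9], g10, &g9, false, gW[9], gB[9]);
  g9 = relu_mask(g9, st.act[9]);
  conv_node_bwd(st, L, 8, st.act[8], g9, &g8, false, gW[8], gB[8]);
  g8 = relu_mask(g8, st.act[8]);
  conv_node_bwd(st, L, 7, st.act[7], g8, &g7, false, gW[7], gB[7]);
  g7 = relu_mask(g7, st.act[7]);                   // grad at v
  conv_node_bwd(st, L, 6, st.act[6], g7, &gcc, false, gW[6], gB[6]);

  // Res2Net interior: cc columns hold (x1, y2, y3, y4).
  gu.set_size(st.act[3].n_rows, 64);
  arma::fmat gy4 = relu_mask(gcc.cols(48, 63),
                             arma::fmat(st.act[6].cols(48, 63)));
  arma::fmat gz4;
  conv_node_bwd(st, L, 5, st.act[5], gy4, &gz4, false, gW[5], gB[5]);
  gu.cols(48, 63) = gz4;
  arma::fmat gy3full = gcc.cols(32, 47) + gz4;
  arma::fmat gy3 = relu_mask(gy3full, arma::fmat(st.act[6].cols(32, 47)));
  arma::fmat gz3;
  conv_node_bwd(st, L, 4, st.act[4], gy3, &gz3, false, gW[4], gB[4]);
  gu.cols(32, 47) = gz3;
  arma::fmat gy2full = gcc.cols(16, 31) + gz3;
  arma::fmat gy2 = relu_mask(gy2full, arma::fmat(st.act[6].cols(16, 31)));
  { arma::fmat gx2, x2 = st.act[3].cols(16, 31);
    conv_node_bwd(st, L, 3, x2, gy2, &gx2, false, gW[3], gB[3]);
    gu.cols(16, 31) = gx2;
  }
  gu.cols(0, 15) = gcc.cols(0, 15);
  gu = relu_mask(gu, st.act[3]);                   // through u's ReLU
  conv_node_bwd(st, L, 2, st.act[2], gu, &g2a, false, gW[2], gB[2]);
  g2a = relu_mask(g2a, st.act[2]);
  conv_node_bwd(st, L, 1, st.act[1], g2a, &g1a, false, gW[1], gB[1]);
  g1a = relu_mask(g1a, st.act[1]);
  conv_node_bwd(st, L, 0, st.act[0], g1a, nullptr, false, gW[0], gB[0]);

  List grads(N_CONV);
  for (int i = 0; i < N_CONV; ++i) {
    NumericVector w(gW[i].n_elem);
    std::copy(gW[i].begin(), gW[i].end(), w.begin());
    w.attr("dim") = IntegerVector::create(L[i].kh, L[i].kw,
                                          L[i].cin, L[i].cout);
    NumericVector b(gB[i].n_elem);
    std::copy(gB[i].begin(), gB[i].end(), b.begin());
    grads[i] = List::create(_["w"] = w, _["b"] = b);
  }
  return grads;
}
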