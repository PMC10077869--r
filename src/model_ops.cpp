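// Whole-model training steps. One call runs forward, cross-entropy and
// backward for a mini-batch, keeping every intermediate inside C++; the R
// side only applies the Adam update. Dropout masks are generated from a
// per-step seed drawn from R's RNG stream by the caller, which keeps runs
// reproducible without moving mask arrays across the interface. The slower
// pure-R forward/backward path is retained in R code as an independent
// reference implementation; unit tests assert both routes agree.
//
// All graphs in a batch share the same node count R, so graph operators are
// passed as dense R x R x G cubes and applied slice-wise with BLAS gemms;
// the attention kernels use a transposed (feature-major) layout so edge
// gathers touch contiguous memory.

#define ARMA_NO_DEBUG   // the edge loops are element-access bound
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double SCORE_CLAMP = 25.0;   // keep exp() bounded
static const double LEAKY_SLOPE = 0.2;

static inline double act_apply(double x, int act) {
  if (act == 1) return x > 0 ? x : 0.0;
  if (act == 2) return x > 0 ? x : std::expm1(x);
  return x;
}
static inline double act_grad_out(double o, int act) {
  if (act == 1) return o > 0 ? 1.0 : 0.0;
  if (act == 2) return o > 0 ? 1.0 : o + 1.0;
  return 1.0;
}
static void act_inplace(mat& X, int act) {
  if (act == 0) return;
  X.transform([act](double v) { return act_apply(v, act); });
}
static void act_bwd_inplace(mat& dZ, const mat& out, int act) {
  if (act == 0) return;
  for (uword i = 0; i < dZ.n_elem; ++i) dZ[i] *= act_grad_out(out[i], act);
}

// splitmix64 -> uniform double in [0,1); cheap, reproducible given the seed
struct FastRng {
  uint64_t s;
  explicit FastRng(uint64_t seed) : s(seed) {}
  inline double unif() {
    s += 0x9E3779B97f4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    z = z ^ (z >> 31);
    return (double)(z >> 11) * 0x1.0p-53;
  }
};

// inverted dropout; mask stored for the backward pass
static mat dropout_mask(uword nr, uword nc, double p, FastRng& rng) {
  mat m(nr, nc);
  const double scale = 1.0 / (1.0 - p);
  for (uword i = 0; i < m.n_elem; ++i) m[i] = rng.unif() >= p ? scale : 0.0;
  return m;
}

// softmax cross-entropy over graphs; labels in {0,1}
static double ce_loss_grad(const mat& logits, const ivec& y, mat& dlogits) {
  const uword G = logits.n_rows;
  mat probs = logits;
  probs.each_col() -= max(logits, 1);
  probs = exp(probs);
  probs.each_col() /= sum(probs, 1);
  double loss = 0.0;
  dlogits = probs;
  for (uword g = 0; g < G; ++g) {
    const uword c = (uword)y[g];
    loss -= std::log(std::max(probs(g, c), 1e-12));
    dlogits(g, c) -= 1.0;
  }
  dlogits /= (double)G;
  return loss / (double)G;
}

// ---- attention kernels, feature-major layout -------------------------------

struct GatCacheT {
  mat HAt;      // H*Fh x N transformed features
  mat gt;       // H x E leaky-ReLU scores (pre-clamp)
  mat alphat;   // H x E attention coefficients
  mat outt;     // emb x N layer output (post-activation)
};

static void gat_fwd_t(const mat& X, const mat& W, const mat& a1,
                      const mat& a2, const ivec& recv, const ivec& send,
                      bool combine_mean, int act, GatCacheT& cc) {
  const uword N = X.n_rows, H = a1.n_cols, Fh = a1.n_rows;
  const uword E = recv.n_elem;
  cc.HAt = (X * W).t();                       // H*Fh x N
  mat st(H, N), tt(H, N);
  for (uword h = 0; h < H; ++h) {
    st.row(h) = a1.col(h).t() * cc.HAt.rows(h * Fh, (h + 1) * Fh - 1);
    tt.row(h) = a2.col(h).t() * cc.HAt.rows(h * Fh, (h + 1) * Fh - 1);
  }
  cc.gt.set_size(H, E);
  mat wt(H, E);
  mat dent(H, N, fill::zeros);
  for (uword e = 0; e < E; ++e) {
    const uword r = recv[e] - 1, sd = send[e] - 1;
    for (uword h = 0; h < H; ++h) {
      double v = st(h, r) + tt(h, sd);
      v = v > 0 ? v : LEAKY_SLOPE * v;
      cc.gt(h, e) = v;
      v = std::min(std::max(v, -SCORE_CLAMP), SCORE_CLAMP);
      const double ew = std::exp(v);
      wt(h, e) = ew;
      dent(h, r) += ew;
    }
  }
  cc.alphat.set_size(H, E);
  mat Ot(H * Fh, N, fill::zeros);
  for (uword e = 0; e < E; ++e) {
    const uword r = recv[e] - 1, sd = send[e] - 1;
    double* oc = Ot.colptr(r);
    const double* hc = cc.HAt.colptr(sd);
    for (uword h = 0; h < H; ++h) {
      const double a = wt(h, e) / dent(h, r);
      cc.alphat(h, e) = a;
      const uword b0 = h * Fh;
      for (uword f = 0; f < Fh; ++f) oc[b0 + f] += a * hc[b0 + f];
    }
  }
  if (combine_mean) {
    cc.outt.zeros(Fh, N);
    for (uword h = 0; h < H; ++h) cc.outt += Ot.rows(h * Fh, (h + 1) * Fh - 1);
    cc.outt /= (double)H;
  } else {
    cc.outt = std::move(Ot);
  }
  act_inplace(cc.outt, act);
}

// dX etc. are returned in the usual node-major layout
static void gat_bwd_t(const mat& X, const mat& W, const mat& a1,
                      const mat& a2, const ivec& recv, const ivec& send,
                      const GatCacheT& cc, const mat& doutt,
                      bool combine_mean, int act,
                      mat& dX, mat& dW, mat& da1, mat& da2) {
  const uword H = a1.n_cols, Fh = a1.n_rows;
  const uword N = X.n_rows, E = recv.n_elem;
  mat dcombt = doutt;                          // emb x N
  act_bwd_inplace(dcombt, cc.outt, act);
  const double scale = combine_mean ? 1.0 / (double)H : 1.0;

  mat dHAt(H * Fh, N, fill::zeros);
  mat dalphat(H, E);
  mat srowt(H, N, fill::zeros);
  for (uword e = 0; e < E; ++e) {
    const uword r = recv[e] - 1, sd = send[e] - 1;
    const double* dc = dcombt.colptr(r);
    const double* hc = cc.HAt.colptr(sd);
    double* dh = dHAt.colptr(sd);
    for (uword h = 0; h < H; ++h) {
      const uword b0 = h * Fh;
      const uword c0 = combine_mean ? 0 : b0;
      const double a = cc.alphat(h, e);
      double acc = 0.0;
      for (uword f = 0; f < Fh; ++f) {
        const double dOhf = scale * dc[c0 + f];
        acc += dOhf * hc[b0 + f];
        dh[b0 + f] += a * dOhf;
      }
      dalphat(h, e) = acc;
      srowt(h, r) += a * acc;
    }
  }
  mat ds(H, N, fill::zeros), dt(H, N, fill::zeros);
  for (uword e = 0; e < E; ++e) {
    const uword r = recv[e] - 1, sd = send[e] - 1;
    for (uword h = 0; h < H; ++h) {
      const double gv = cc.gt(h, e);
      if (std::abs(gv) >= SCORE_CLAMP) continue;      // clamp region
      double de = cc.alphat(h, e) * (dalphat(h, e) - srowt(h, r));
      de *= (gv > 0 ? 1.0 : LEAKY_SLOPE);             // leaky-ReLU grad
      ds(h, r) += de;
      dt(h, sd) += de;
    }
  }
  da1.set_size(Fh, H);
  da2.set_size(Fh, H);
  for (uword h = 0; h < H; ++h) {
    const uword b0 = h * Fh;
    dHAt.rows(b0, b0 + Fh - 1) += a1.col(h) * ds.row(h) + a2.col(h) * dt.row(h);
    da1.col(h) = cc.HAt.rows(b0, b0 + Fh - 1) * ds.row(h).t();
    da2.col(h) = cc.HAt.rows(b0, b0 + Fh - 1) * dt.row(h).t();
  }
  dX = (W * dHAt).t();
  dW = (dHAt * X).t();
}

// ---- whole-model step -------------------------------------------------------

// arch: 0 = gcn (op = normalised adjacency, symmetric), 1 = sage (op =
// row-normalised neighbour mean), 2 = gat (recv/send edge arrays). op is an
// R x R x G cube of per-graph operators; X stacks the G graphs' node
// features (rows g*R .. (g+1)*R - 1). Returns logits only in evaluation
// mode; in training mode also the loss and all gradients.

// [[Rcpp::export(name = ".model_step_cpp")]]
Rcpp::List model_step_cpp(int arch, const arma::mat& X, const arma::cube& op,
                          const arma::ivec& recv, const arma::ivec& send,
                          int n_nodes, int n_graphs,
                          Rcpp::List Wl, Rcpp::List bl, Rcpp::List Wl2,
                          Rcpp::List a1l, Rcpp::List a2l,
                          const arma::mat& Wfc, const arma::vec& bfc,
                          const arma::ivec& y, double dropout, int act,
                          bool training, double seed) {
  const uword L = Wl.size();
  const uword R = (uword)n_nodes, G = (uword)n_graphs;
  FastRng rng((uint64_t)seed);

  std::vector<mat> Xin(L), outs(L), MX(L), masks(L + 1);
  std::vector<GatCacheT> gcc(L);
  mat Xcur = X;
  for (uword l = 0; l < L; ++l) {
    if (training && dropout > 0) {
      masks[l] = dropout_mask(Xcur.n_rows, Xcur.n_cols, dropout, rng);
      Xcur %= masks[l];
    }
    Xin[l] = Xcur;
    const mat W = Rcpp::as<mat>(Wl[l]);
    if (arch == 0) {
      const vec b = Rcpp::as<vec>(bl[l]);
      mat XW = Xcur * W;
      mat Z(XW.n_rows, XW.n_cols);
      for (uword g = 0; g < G; ++g)
        Z.rows(g * R, (g + 1) * R - 1) = op.slice(g) * XW.rows(g * R, (g + 1) * R - 1);
      Z.each_row() += b.t();
      act_inplace(Z, act);
      outs[l] = std::move(Z);
    } else if (arch == 1) {
      const mat Wn = Rcpp::as<mat>(Wl2[l]);
      const vec b = Rcpp::as<vec>(bl[l]);
      MX[l].set_size(Xcur.n_rows, Xcur.n_cols);
      for (uword g = 0; g < G; ++g)
        MX[l].rows(g * R, (g + 1) * R - 1) = op.slice(g) * Xcur.rows(g * R, (g + 1) * R - 1);
      mat Z = Xcur * W + MX[l] * Wn;
      Z.each_row() += b.t();
      act_inplace(Z, act);
      outs[l] = std::move(Z);
    } else {
      const mat a1 = Rcpp::as<mat>(a1l[l]);
      const mat a2 = Rcpp::as<mat>(a2l[l]);
      gat_fwd_t(Xcur, W, a1, a2, recv, send, l == L - 1, act, gcc[l]);
      outs[l] = gcc[l].outt.t();
    }
    Xcur = outs[l];
  }
  // global mean pooling per graph
  const uword emb = Xcur.n_cols;
  mat pooled(G, emb);
  for (uword g = 0; g < G; ++g)
    pooled.row(g) = mean(Xcur.rows(g * R, (g + 1) * R - 1), 0);
  if (training && dropout > 0) {
    masks[L] = dropout_mask(G, emb, dropout, rng);
    pooled %= masks[L];
  }
  mat logits = pooled * Wfc;
  logits.each_row() += bfc.t();

  if (!training)
    return Rcpp::List::create(Rcpp::Named("logits") = logits);

  mat dlogits;
  const double loss = ce_loss_grad(logits, y, dlogits);

  Rcpp::List grads;
  grads["Wfc"] = mat(pooled.t() * dlogits);
  grads["bfc"] = vec(sum(dlogits, 0).t());
  mat dpooled = dlogits * Wfc.t();
  if (dropout > 0) dpooled %= masks[L];
  mat dX(G * R, emb);
  for (uword g = 0; g < G; ++g)
    dX.rows(g * R, (g + 1) * R - 1) = repmat(dpooled.row(g) / (double)R, R, 1);

  Rcpp::List gW(L), gb(L), gW2(L), ga1(L), ga2(L);
  for (int l = (int)L - 1; l >= 0; --l) {
    const mat W = Rcpp::as<mat>(Wl[l]);
    if (arch == 0) {
      mat dZ = std::move(dX);
      act_bwd_inplace(dZ, outs[l], act);
      gb[l] = vec(sum(dZ, 0).t());
      mat SdZ(dZ.n_rows, dZ.n_cols);
      for (uword g = 0; g < G; ++g)      // op symmetric
        SdZ.rows(g * R, (g + 1) * R - 1) = op.slice(g) * dZ.rows(g * R, (g + 1) * R - 1);
      gW[l] = mat(Xin[l].t() * SdZ);
      dX = SdZ * W.t();
    } else if (arch == 1) {
      const mat Wn = Rcpp::as<mat>(Wl2[l]);
      mat dZ = std::move(dX);
      act_bwd_inplace(dZ, outs[l], act);
      gb[l] = vec(sum(dZ, 0).t());
      gW[l] = mat(Xin[l].t() * dZ);
      gW2[l] = mat(MX[l].t() * dZ);
      mat dZWn = dZ * Wn.t();
      dX = dZ * W.t();
      for (uword g = 0; g < G; ++g)      // op is row-normalised: use transpose
        dX.rows(g * R, (g + 1) * R - 1) += op.slice(g).t() * dZWn.rows(g * R, (g + 1) * R - 1);
    } else {
      const mat a1 = Rcpp::as<mat>(a1l[l]);
      const mat a2 = Rcpp::as<mat>(a2l[l]);
      mat doutt = dX.t();
      mat dXl, dW, da1, da2;
      gat_bwd_t(Xin[l], W, a1, a2, recv, send, gcc[l], doutt,
                l == (int)L - 1, act, dXl, dW, da1, da2);
      gW[l] = dW; ga1[l] = da1; ga2[l] = da2;
      dX = std::move(dXl);
    }
    if (dropout > 0) dX %= masks[l];
  }
  grads["W"] = gW; grads["b"] = gb; grads["W2"] = gW2;
  grads["a1"] = ga1; grads["a2"] = ga2;
  return Rcpp::List::create(Rcpp::Named("logits") = logits,
                            Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = grads);
}

// ---- single-layer entry points (exported gat_layer() and the R reference
// ---- model path) ------------------------------------------------------------

// [[Rcpp::export(name = ".gat_fwd_cpp")]]
Rcpp::List gat_fwd_cpp(const arma::mat& X, const arma::mat& W,
                       const arma::mat& a1, const arma::mat& a2,
                       const arma::ivec& recv, const arma::ivec& send,
                       bool combine_mean, int act) {
  GatCacheT cc;
  gat_fwd_t(X, W, a1, a2, recv, send, combine_mean, act, cc);
  // node-major views for the R caller
  return Rcpp::List::create(Rcpp::Named("out") = mat(cc.outt.t()),
                            Rcpp::Named("HA") = mat(cc.HAt.t()),
                            Rcpp::Named("g") = mat(cc.gt.t()),
                            Rcpp::Named("alpha") = mat(cc.alphat.t()));
}

// [[Rcpp::export(name = ".gat_bwd_cpp")]]
Rcpp::List gat_bwd_cpp(const arma::mat& X, const arma::mat& W,
                       const arma::mat& a1, const arma::mat& a2,
                       const arma::ivec& recv, const arma::ivec& send,
                       const arma::mat& HA, const arma::mat& g,
                       const arma::mat& alpha, const arma::mat& out,
                       const arma::mat& dout, bool combine_mean, int act) {
  GatCacheT cc;
  cc.HAt = HA.t(); cc.gt = g.t(); cc.alphat = alpha.t(); cc.outt = out.t();
  mat dX, dW, da1, da2;
  gat_bwd_t(X, W, a1, a2, recv, send, cc, mat(dout.t()), combine_mean, act,
            dX, dW, da1, da2);
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("da1") = da1,
                            Rcpp::Named("da2") = da2);
}
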