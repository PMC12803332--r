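// Compiled core of the multiscale GNN: forward pass and reverse-mode
// gradients with respect to coordinates (forces) and parameters (training).
// Mirrors the reference R implementation in R/model.R one-to-one; the R
// path stays available via options(sspot.use_compiled = FALSE) and the test
// suite checks the two agree.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

static inline mat ssp_m(const mat& x) {
  // shifted softplus log(0.5 e^x + 0.5), numerically stable
  return arma::max(x, arma::zeros<mat>(x.n_rows, x.n_cols)) +
         arma::log1p(arma::exp(-arma::abs(x))) - std::log(2.0);
}
static inline mat sigmoid_m(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }
static inline vec sigmoid_v(const vec& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct Edges {
  uvec i, j;   // 0-based endpoints, directed both ways
  vec d;       // distances
  mat u;       // unit vectors x_i - x_j (n_e x 3)
  bool any() const { return i.n_elem > 0; }
};

static Edges edge_list_cpp(const mat& X, double r_cut) {
  Edges e;
  const arma::uword n = X.n_rows;
  std::vector<arma::uword> vi, vj;
  std::vector<double> vd;
  for (arma::uword a = 0; a < n; ++a) {
    for (arma::uword b = a + 1; b < n; ++b) {
      double dx = X(a,0)-X(b,0), dy = X(a,1)-X(b,1), dz = X(a,2)-X(b,2);
      double d = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (d <= r_cut) { vi.push_back(a); vj.push_back(b); vd.push_back(d); }
    }
  }
  const arma::uword m = vi.size();
  e.i.set_size(2*m); e.j.set_size(2*m); e.d.set_size(2*m); e.u.set_size(2*m, 3);
  for (arma::uword k = 0; k < m; ++k) {
    e.i(k) = vi[k]; e.j(k) = vj[k]; e.d(k) = vd[k];
    e.i(m+k) = vj[k]; e.j(m+k) = vi[k]; e.d(m+k) = vd[k];
    for (int c = 0; c < 3; ++c) {
      double uc = (X(vi[k],c) - X(vj[k],c)) / vd[k];
      e.u(k,c) = uc; e.u(m+k,c) = -uc;
    }
  }
  return e;
}

// scatter-add rows of V into an (n x k) zero matrix by 0-based group index
static mat scatter_rows(const mat& V, const uvec& g, arma::uword n) {
  mat out(n, V.n_cols, arma::fill::zeros);
  for (arma::uword r = 0; r < V.n_rows; ++r) out.row(g(r)) += V.row(r);
  return out;
}

// Layer-independent per-edge features: RBF expansion and cutoff envelope
struct EdgeFeat {
  mat R, D;
  vec env;
  double sigma = 0, r_cut = 0;
  void build(const Edges& e, int n_rbf, double rc) {
    r_cut = rc;
    if (!e.any()) return;
    vec mu = arma::linspace<vec>(0.0, rc, n_rbf);
    sigma = mu(1) - mu(0);
    D = arma::repmat(e.d, 1, n_rbf) - arma::repmat(mu.t(), e.d.n_elem, 1);
    R = arma::exp(-arma::square(D) / (2.0 * sigma * sigma));
    env = 0.5 * (arma::cos(M_PI * e.d / rc) + 1.0);
  }
};

struct ConvParams {
  mat Wf1, Wf2, Wv, Wo;
  vec bf1, bf2, bv, bo, att_w;
  double att_b = 0.0;
  bool attention = false;
  void load(const List& bp, bool att) {
    attention = att;
    Wf1 = as<mat>(bp["Wf1"]); bf1 = as<vec>(bp["bf1"]);
    Wf2 = as<mat>(bp["Wf2"]); bf2 = as<vec>(bp["bf2"]);
    Wv  = as<mat>(bp["Wv"]);  bv  = as<vec>(bp["bv"]);
    Wo  = as<mat>(bp["Wo"]);  bo  = as<vec>(bp["bo"]);
    if (att) { att_w = as<vec>(bp["att_w"]); att_b = as<double>(bp["att_b"]); }
  }
};

struct ConvCache {
  mat H, A1f, F1, Wmat, V, Vj, M, U;
  vec att, s_e;
  bool empty = true;
};

struct ConvGrads {
  mat Wf1, Wf2, Wv, Wo;
  vec bf1, bf2, bv, bo, att_w;
  double att_b = 0.0;
};

// forward through one continuous-filter convolution block
static mat conv_forward_cpp(const ConvParams& bp, const mat& H, const Edges& e,
                            const EdgeFeat& f, ConvCache& c) {
  c.H = H;
  if (!e.any()) {
    c.empty = true;
    c.M.zeros(H.n_rows, H.n_cols);
    c.U = ssp_m(c.M);
    mat O = c.U * bp.Wo.t();
    O.each_row() += bp.bo.t();
    return O;
  }
  c.empty = false;
  c.A1f = f.R * bp.Wf1.t();
  c.A1f.each_row() += bp.bf1.t();
  c.F1 = ssp_m(c.A1f);
  c.Wmat = c.F1 * bp.Wf2.t();
  c.Wmat.each_row() += bp.bf2.t();
  c.V = H * bp.Wv.t();
  c.V.each_row() += bp.bv.t();
  c.Vj = c.V.rows(e.j);
  if (bp.attention) {
    c.att = sigmoid_v(f.R * bp.att_w + bp.att_b);
    c.s_e = f.env % c.att;
  } else {
    c.s_e = f.env;
  }
  mat msg = c.Wmat % c.Vj;
  msg.each_col() %= c.s_e;
  c.M = scatter_rows(msg, e.i, H.n_rows);
  c.U = ssp_m(c.M);
  mat O = c.U * bp.Wo.t();
  O.each_row() += bp.bo.t();
  return O;
}

// backward through one conv block; dO is gradient on the block output.
static void conv_backward_cpp(const ConvParams& bp, const ConvCache& c,
                              const Edges& e, const EdgeFeat& f, const mat& dO,
                              mat& dH_out, mat& dX_local, ConvGrads* g,
                              bool want_coords) {
  if (g) { g->Wo = dO.t() * c.U; g->bo = arma::sum(dO, 0).t(); }
  mat dU = dO * bp.Wo;
  mat dM = dU % sigmoid_m(c.M);
  if (c.empty) {
    dH_out.zeros(c.H.n_rows, c.H.n_cols);
    if (want_coords) dX_local.zeros(c.H.n_rows, 3);
    if (g) {
      g->Wf1.zeros(bp.Wf1.n_rows, bp.Wf1.n_cols); g->bf1.zeros(bp.bf1.n_elem);
      g->Wf2.zeros(bp.Wf2.n_rows, bp.Wf2.n_cols); g->bf2.zeros(bp.bf2.n_elem);
      g->Wv.zeros(bp.Wv.n_rows, bp.Wv.n_cols);   g->bv.zeros(bp.bv.n_elem);
      if (bp.attention) { g->att_w.zeros(bp.att_w.n_elem); g->att_b = 0.0; }
    }
    return;
  }
  mat dmsg = dM.rows(e.i);
  mat WV = c.Wmat % c.Vj;
  mat dWmat = dmsg % c.Vj;
  dWmat.each_col() %= c.s_e;
  mat dVj = dmsg % c.Wmat;
  dVj.each_col() %= c.s_e;
  vec ds_e = arma::sum(dmsg % WV, 1);
  mat dV = scatter_rows(dVj, e.j, c.H.n_rows);
  dH_out = dV * bp.Wv;
  if (g) { g->Wv = dV.t() * c.H; g->bv = arma::sum(dV, 0).t(); }
  mat dF1 = dWmat * bp.Wf2;
  if (g) { g->Wf2 = dWmat.t() * c.F1; g->bf2 = arma::sum(dWmat, 0).t(); }
  mat dA1f = dF1 % sigmoid_m(c.A1f);
  mat dR = dA1f * bp.Wf1;
  if (g) { g->Wf1 = dA1f.t() * f.R; g->bf1 = arma::sum(dA1f, 0).t(); }
  vec denv;
  if (bp.attention) {
    vec datt = ds_e % f.env;
    denv = ds_e % c.att;
    vec dz = datt % c.att % (1.0 - c.att);
    dR += dz * bp.att_w.t();
    if (g) { g->att_w = f.R.t() * dz; g->att_b = arma::accu(dz); }
  } else {
    denv = ds_e;
  }
  if (want_coords) {
    mat dRdd = -(f.R % f.D) / (f.sigma * f.sigma);
    vec dd = arma::sum(dR % dRdd, 1) -
             denv % (0.5 * M_PI / f.r_cut * arma::sin(M_PI * e.d / f.r_cut));
    mat dXe = e.u;
    dXe.each_col() %= dd;
    dX_local = scatter_rows(dXe, e.i, c.H.n_rows) - scatter_rows(dXe, e.j, c.H.n_rows);
  }
}

struct ModelParams {
  mat E_aa, E_at, W_in, W1, W2, W3;
  vec b_in, b1, b2, b3;
  std::vector<ConvParams> shortp, longp;
  int n_layers = 0, n_rbf = 0;
  double r_cut_short = 0, r_cut_long = 0;
  void load(const List& params, const List& cfg) {
    E_aa = as<mat>(params["E_aa"]);
    E_at = as<mat>(params["E_at"]);
    W_in = as<mat>(params["W_in"]); b_in = as<vec>(params["b_in"]);
    List sh = params["short"], lo = params["long"], hd = params["head"];
    n_layers = sh.size();
    shortp.resize(n_layers); longp.resize(n_layers);
    for (int l = 0; l < n_layers; ++l) {
      shortp[l].load(sh[l], true);
      longp[l].load(lo[l], false);
    }
    W1 = as<mat>(hd["W1"]); b1 = as<vec>(hd["b1"]);
    W2 = as<mat>(hd["W2"]); b2 = as<vec>(hd["b2"]);
    W3 = as<mat>(hd["W3"]); b3 = as<vec>(hd["b3"]);
    n_rbf = as<int>(cfg["n_rbf"]);
    r_cut_short = as<double>(cfg["r_cut_short"]);
    r_cut_long = as<double>(cfg["r_cut_long"]);
  }
};

struct FwdCache {
  ModelParams P;                   // parameters reused by the backward pass
  mat X, H0raw, A1, Z1, A2, Z2, H_final;
  Edges es, el;
  EdgeFeat fs, fl;
  std::vector<ConvCache> cs, cl;   // per layer
  uvec aa, at, res, ca_rows;       // 0-based
};

static mat run_forward(FwdCache* C, List params, List cfg, const mat& X,
                       const uvec& aa1, const uvec& at1, const uvec& res1,
                       const uvec& ca1) {
  ModelParams& P = C->P;
  P.load(params, cfg);
  C->aa = aa1 - 1; C->at = at1 - 1; C->res = res1 - 1; C->ca_rows = ca1 - 1;
  C->X = X;
  const arma::uword n_atoms = X.n_rows;
  mat H0raw(n_atoms, P.E_aa.n_cols + P.E_at.n_cols);
  for (arma::uword k = 0; k < n_atoms; ++k) {
    H0raw(k, arma::span(0, P.E_aa.n_cols - 1)) = P.E_aa.row(C->aa(k));
    H0raw(k, arma::span(P.E_aa.n_cols, H0raw.n_cols - 1)) = P.E_at.row(C->at(k));
  }
  C->H0raw = H0raw;
  mat H = H0raw * P.W_in.t();
  H.each_row() += P.b_in.t();
  C->es = edge_list_cpp(X, P.r_cut_short);
  C->el = edge_list_cpp(X.rows(C->ca_rows), P.r_cut_long);
  C->fs.build(C->es, P.n_rbf, P.r_cut_short);
  C->fl.build(C->el, P.n_rbf, P.r_cut_long);
  C->cs.resize(P.n_layers); C->cl.resize(P.n_layers);
  for (int l = 0; l < P.n_layers; ++l) {
    mat O = conv_forward_cpp(P.shortp[l], H, C->es, C->fs, C->cs[l]);
    H += O;
    mat H_ca = H.rows(C->ca_rows);
    mat ctx = conv_forward_cpp(P.longp[l], H_ca, C->el, C->fl, C->cl[l]);
    H += ctx.rows(C->res);
  }
  C->A1 = H * P.W1.t(); C->A1.each_row() += P.b1.t();
  C->Z1 = ssp_m(C->A1);
  C->A2 = C->Z1 * P.W2.t(); C->A2.each_row() += P.b2.t();
  C->Z2 = ssp_m(C->A2);
  mat logits = C->Z2 * P.W3.t();
  logits.each_row() += P.b3.t();
  C->H_final = H;
  return logits;
}

// [[Rcpp::export]]
List cpp_schake_forward(List params, List cfg, arma::mat X,
                        arma::uvec aa1, arma::uvec at1, arma::uvec res1,
                        arma::uvec ca1, bool need_cache) {
  FwdCache* C = new FwdCache();
  mat logits = run_forward(C, params, cfg, X, aa1, at1, res1, ca1);
  List out = List::create(_["logits"] = logits);
  if (need_cache) {
    XPtr<FwdCache> ptr(C, true);
    out["cache"] = ptr;
  } else {
    delete C;
  }
  return out;
}

static List conv_grads_to_list(const ConvGrads& g, bool attention) {
  List out = List::create(
    _["Wf1"] = g.Wf1, _["bf1"] = g.bf1,
    _["Wf2"] = g.Wf2, _["bf2"] = g.bf2,
    _["Wv"] = g.Wv, _["bv"] = g.bv,
    _["Wo"] = g.Wo, _["bo"] = g.bo);
  if (attention) { out["att_w"] = g.att_w; out["att_b"] = g.att_b; }
  return out;
}

static List run_backward(FwdCache* C, const mat& dlogits,
                         bool want_coords, bool want_params) {
  const ModelParams& P = C->P;
  const arma::uword n_atoms = C->X.n_rows;
  mat dZ2 = dlogits * P.W3;
  mat dA2 = dZ2 % sigmoid_m(C->A2);
  mat dZ1 = dA2 * P.W2;
  mat dA1 = dZ1 % sigmoid_m(C->A1);
  mat dH = dA1 * P.W1;
  List dhead;
  if (want_params) {
    dhead = List::create(
      _["W1"] = mat(dA1.t() * C->H_final), _["b1"] = vec(arma::sum(dA1, 0).t()),
      _["W2"] = mat(dA2.t() * C->Z1), _["b2"] = vec(arma::sum(dA2, 0).t()),
      _["W3"] = mat(dlogits.t() * C->Z2), _["b3"] = vec(arma::sum(dlogits, 0).t()));
  }
  mat dX(n_atoms, 3, arma::fill::zeros);
  List dshort(P.n_layers), dlong(P.n_layers);
  for (int l = P.n_layers - 1; l >= 0; --l) {
    // long block: H_out = H_mid + broadcast(O_long(H_mid[ca]))
    mat dctx = scatter_rows(dH, C->res, C->ca_rows.n_elem);
    ConvGrads gl;
    mat dH_ca, dX_ca;
    conv_backward_cpp(P.longp[l], C->cl[l], C->el, C->fl, dctx, dH_ca, dX_ca,
                      want_params ? &gl : nullptr, want_coords);
    dH.rows(C->ca_rows) += dH_ca;
    if (want_coords && !C->cl[l].empty) dX.rows(C->ca_rows) += dX_ca;
    if (want_params) dlong[l] = conv_grads_to_list(gl, false);
    // short block: H_mid = H_in + O_short(H_in)
    ConvGrads gs;
    mat dH_in, dX_s;
    conv_backward_cpp(P.shortp[l], C->cs[l], C->es, C->fs, dH, dH_in, dX_s,
                      want_params ? &gs : nullptr, want_coords);
    dH += dH_in;
    if (want_coords && !C->cs[l].empty) dX += dX_s;
    if (want_params) dshort[l] = conv_grads_to_list(gs, true);
  }
  List out;
  if (want_params) {
    mat dW_in = dH.t() * C->H0raw;
    vec db_in = arma::sum(dH, 0).t();
    mat dH0raw = dH * P.W_in;
    mat dE_aa(P.E_aa.n_rows, P.E_aa.n_cols, arma::fill::zeros);
    mat dE_at(P.E_at.n_rows, P.E_at.n_cols, arma::fill::zeros);
    const arma::uword ds = P.E_aa.n_cols;
    for (arma::uword k = 0; k < n_atoms; ++k) {
      dE_aa.row(C->aa(k)) += dH0raw(k, arma::span(0, ds - 1));
      dE_at.row(C->at(k)) += dH0raw(k, arma::span(ds, dH0raw.n_cols - 1));
    }
    out["dparams"] = List::create(
      _["E_aa"] = dE_aa, _["E_at"] = dE_at,
      _["W_in"] = dW_in, _["b_in"] = db_in,
      _["short"] = dshort, _["long"] = dlong, _["head"] = dhead);
  }
  if (want_coords) out["dX"] = dX;
  return out;
}

// [[Rcpp::export]]
List cpp_schake_backward(SEXP cache_ptr, arma::mat dlogits,
                         bool want_coords, bool want_params) {
  XPtr<FwdCache> C(cache_ptr);
  return run_backward(C, dlogits, want_coords, want_params);
}

// One-call energy + forces for the MD loop: forward, per-atom likelihood
// energy (one-state with reference one-hot Y, or multi-state LogSumExp),
// softmax-jacobian contraction, and the coordinate gradient — with the
// cache kept local, so no allocation survives the call.
// mode: 0 = one-state (Y used), 1 = multi-state (beta used).
// [[Rcpp::export]]
List cpp_energy_force(List params, List cfg, arma::mat X,
                      arma::uvec aa1, arma::uvec at1, arma::uvec res1,
                      arma::uvec ca1, int mode, arma::mat Y,
                      double pref, double eps, double beta) {
  FwdCache C;
  mat logits = run_forward(&C, params, cfg, X, aa1, at1, res1, ca1);
  // row-wise softmax
  mat Q = logits;
  for (arma::uword r = 0; r < Q.n_rows; ++r) {
    double mx = Q.row(r).max();
    Q.row(r) = arma::exp(Q.row(r) - mx);
    Q.row(r) /= arma::accu(Q.row(r));
  }
  vec e(Q.n_rows);
  mat dlogits(Q.n_rows, Q.n_cols);
  if (mode == 0) {
    vec qref = arma::sum(Q % Y, 1);
    e = -pref * arma::log(qref + eps);
    vec dqref = -pref / (qref + eps);
    mat A = (Y % Q);
    A.each_col() %= dqref;
    dlogits = A - (Q.each_col() % arma::sum(A, 1));
  } else {
    mat V = arma::log(Q + eps);
    vec mx = arma::max(V, 1);
    mat W = arma::exp(beta * (V.each_col() - mx));
    vec sw = arma::sum(W, 1);
    e = -pref * (mx + arma::log(sw) / beta);
    mat dv = -pref * (W.each_col() / sw);
    mat A = dv % Q / (Q + eps);
    dlogits = A - (Q.each_col() % arma::sum(A, 1));
  }
  List bk = run_backward(&C, dlogits, true, false);
  return List::create(_["total"] = arma::accu(e), _["per_atom"] = e,
                      _["dX"] = bk["dX"]);
}
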