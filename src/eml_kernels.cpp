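// Fast forward/backward kernels for the fusion + contact-prototype model.
// Mirrors the reference R implementation in R/autograd.R exactly (tests
// assert agreement); used by the training loop and batch inference.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

struct Arrow {
  mat Wq, Wk, Wv;
};

struct Params {
  std::vector<Arrow> arrows; // ab, ba, eab, abe, eba, bae
  double tau_raw;
  int d, Nfull;
  vec thresholds, area_weights;
  double dropout;
  bool norm_n2;
};

static Params parse_params(const NumericVector &flat, int d, int Nfull,
                           const NumericVector &thresholds,
                           const NumericVector &area_weights,
                           double dropout, bool norm_n2) {
  Params P;
  P.d = d; P.Nfull = Nfull;
  P.thresholds = as<vec>(thresholds);
  P.area_weights = as<vec>(area_weights);
  P.dropout = dropout;
  P.norm_n2 = norm_n2;
  const double *p = flat.begin();
  size_t off = 0;
  for (int a = 0; a < 6; ++a) {
    Arrow ar;
    ar.Wq = mat(p + off, d, d); off += (size_t)d * d;
    ar.Wk = mat(p + off, d, d); off += (size_t)d * d;
    ar.Wv = mat(p + off, d, d); off += (size_t)d * d;
    P.arrows.push_back(ar);
  }
  P.tau_raw = flat[off];
  return P;
}

static inline double softplus(double x) {
  return x > 30 ? x : std::log1p(std::exp(x));
}
static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct AttnCache {
  mat Xq, Xkv, Q, K, V, P, dm;
  bool dropped;
};

static mat attn_forward(const mat &Xq, const mat &Xkv, const Arrow &W,
                        double dropout, bool train, AttnCache &c) {
  int d = Xq.n_cols;
  c.Xq = Xq; c.Xkv = Xkv;
  c.Q = Xq * W.Wq; c.K = Xkv * W.Wk; c.V = Xkv * W.Wv;
  mat Scr = c.Q * c.K.t() / std::sqrt((double)d);
  mat E = arma::exp(Scr.each_col() - arma::max(Scr, 1));
  c.P = E.each_col() / arma::sum(E, 1);
  mat O = c.P * c.V;
  c.dropped = train && dropout > 0;
  if (c.dropped) {
    c.dm.set_size(O.n_rows, O.n_cols);
    for (arma::uword j = 0; j < O.n_cols; ++j)
      for (arma::uword i = 0; i < O.n_rows; ++i)
        c.dm(i, j) = (unif_rand() < 1.0 - dropout) ? 1.0 : 0.0;
    O = O % c.dm / (1.0 - dropout);
  }
  return Xq + O;
}

struct AttnGrads { mat Wq, Wk, Wv; };

static void attn_backward(const mat &dH, const AttnCache &c, const Arrow &W,
                          double dropout, mat &dXq, mat &dXkv, AttnGrads &g) {
  int d = c.Xq.n_cols;
  mat dO = dH;
  if (c.dropped) dO = dO % c.dm / (1.0 - dropout);
  mat dP = dO * c.V.t();
  mat dV = c.P.t() * dO;
  mat dScr = c.P % (dP.each_col() - arma::sum(dP % c.P, 1));
  mat dQ = dScr * c.K / std::sqrt((double)d);
  mat dK = dScr.t() * c.Q / std::sqrt((double)d);
  dXq = dH + dQ * W.Wq.t();
  dXkv = dK * W.Wk.t() + dV * W.Wv.t();
  g.Wq = c.Xq.t() * dQ;
  g.Wk = c.Xkv.t() * dK;
  g.Wv = c.Xkv.t() * dV;
}

struct ProtoCache {
  mat E1, E2, Craw, C, S;
  std::vector<mat> Ms;
  vec nu, nv;
  arma::umat zero;
  double D, tau;
};

static double proto_forward(const mat &E1, const mat &E2, const Params &P,
                            ProtoCache &c) {
  c.E1 = E1; c.E2 = E2;
  c.tau = softplus(P.tau_raw);
  c.D = std::max(c.tau, 1.0);
  c.nu = arma::sqrt(arma::sum(E1 % E1, 1));
  c.nv = arma::sqrt(arma::sum(E2 % E2, 1));
  mat dn = c.nu * c.nv.t();
  c.zero = (dn == 0);
  dn.elem(arma::find(c.zero)).ones();
  c.Craw = (E1 * E2.t()) / dn;
  c.Craw.elem(arma::find(c.zero)).zeros();
  c.C = arma::clamp(c.Craw, 0.0, 1.0);
  c.S = c.C / c.D;
  int nT = P.thresholds.n_elem;
  mat A(E1.n_rows, E2.n_rows, arma::fill::zeros);
  c.Ms.clear();
  for (int i = 0; i < nT; ++i) {
    mat M = 1.0 / (1.0 + arma::exp(-(c.S - P.thresholds[i]) * P.Nfull));
    A += P.area_weights[i] * M;
    c.Ms.push_back(M);
  }
  A /= nT;
  double denom = P.norm_n2 ? (double)P.Nfull * P.Nfull
                           : (double)E1.n_rows * E2.n_rows;
  return arma::accu(A) / denom;
}

static void proto_backward(double dw, const ProtoCache &c, const Params &P,
                           mat &dE1, mat &dE2, double &dtau_raw) {
  int nT = P.thresholds.n_elem;
  double N = P.Nfull;
  double denom = P.norm_n2 ? N * N : (double)c.E1.n_rows * c.E2.n_rows;
  double dA = dw / denom;
  mat sig(c.E1.n_rows, c.E2.n_rows, arma::fill::zeros);
  for (int i = 0; i < nT; ++i)
    sig += P.area_weights[i] * (c.Ms[i] % (1.0 - c.Ms[i]));
  mat dS = dA * (N / nT) * sig;
  double dD = -arma::accu(dS % c.C) / (c.D * c.D);
  dtau_raw += dD * (c.tau > 1 ? 1.0 : 0.0) * sigmoid(P.tau_raw);
  mat G = dS / c.D;
  G.elem(arma::find(c.Craw <= 0)).zeros();
  G.elem(arma::find(c.Craw >= 1)).zeros();
  G.elem(arma::find(c.zero)).zeros();
  vec nu = c.nu, nv = c.nv;
  nu.elem(arma::find(nu == 0)).ones();
  nv.elem(arma::find(nv == 0)).ones();
  mat Gn = G / (nu * nv.t());
  dE1 = Gn * c.E2 - c.E1.each_col() % (arma::sum(G % c.Craw, 1) / (nu % nu));
  dE2 = Gn.t() * c.E1 -
    c.E2.each_col() % ((arma::sum(G % c.Craw, 0).t()) / (nv % nv));
}

struct RecordCache {
  AttnCache ab, ba, eab, abe, eba, bae;
  ProtoCache pa, pb;
  mat Hab, Hba, Heab, Habe, Heba, Hbae;
};

static double record_forward(const mat &ea, const mat &eb, const mat &ee,
                             const Params &P, bool train, RecordCache &rc,
                             double &w_a, double &w_b) {
  double p = train ? P.dropout : 0.0;
  rc.Hab = attn_forward(ea, eb, P.arrows[0], p, train, rc.ab);
  rc.Hba = attn_forward(eb, ea, P.arrows[1], p, train, rc.ba);
  rc.Heab = attn_forward(ee, rc.Hab, P.arrows[2], p, train, rc.eab);
  rc.Habe = attn_forward(rc.Hab, ee, P.arrows[3], p, train, rc.abe);
  rc.Heba = attn_forward(ee, rc.Hba, P.arrows[4], p, train, rc.eba);
  rc.Hbae = attn_forward(rc.Hba, ee, P.arrows[5], p, train, rc.bae);
  w_a = proto_forward(rc.Heab, rc.Habe, P, rc.pa);
  w_b = proto_forward(rc.Heba, rc.Hbae, P, rc.pb);
  return (w_a + w_b) / 2.0;
}

static void accum(AttnGrads &acc, const AttnGrads &g) {
  if (acc.Wq.n_elem == 0) { acc = g; return; }
  acc.Wq += g.Wq; acc.Wk += g.Wk; acc.Wv += g.Wv;
}

// accumulate one record's gradients (scaled by dy) into flat grad vector
static void record_backward(double dy, const RecordCache &rc, const Params &P,
                            std::vector<AttnGrads> &g, double &g_tau) {
  mat dHeab, dHabe, dHeba, dHbae;
  proto_backward(dy / 2.0, rc.pa, P, dHeab, dHabe, g_tau);
  proto_backward(dy / 2.0, rc.pb, P, dHeba, dHbae, g_tau);
  mat dXq, dXkv;
  AttnGrads ga;
  mat d_ab, d_ba;
  attn_backward(dHeab, rc.eab, P.arrows[2], P.dropout, dXq, dXkv, ga);
  d_ab = dXkv; accum(g[2], ga);
  attn_backward(dHabe, rc.abe, P.arrows[3], P.dropout, dXq, dXkv, ga);
  d_ab += dXq; accum(g[3], ga);
  attn_backward(dHeba, rc.eba, P.arrows[4], P.dropout, dXq, dXkv, ga);
  d_ba = dXkv; accum(g[4], ga);
  attn_backward(dHbae, rc.bae, P.arrows[5], P.dropout, dXq, dXkv, ga);
  d_ba += dXq; accum(g[5], ga);
  attn_backward(d_ab, rc.ab, P.arrows[0], P.dropout, dXq, dXkv, ga);
  accum(g[0], ga);
  attn_backward(d_ba, rc.ba, P.arrows[1], P.dropout, dXq, dXkv, ga);
  accum(g[1], ga);
}

// [[Rcpp::export]]
List cpp_batch(List blocks, NumericVector y, double pos_weight,
               NumericVector flat, int d, int Nfull,
               NumericVector thresholds, NumericVector area_weights,
               double dropout, bool train, bool want_grad,
               bool norm_n2 = true) {
  Params P = parse_params(flat, d, Nfull, thresholds, area_weights, dropout,
                          norm_n2);
  int B = blocks.size();
  NumericVector y_hat(B), wa_out(B), wb_out(B);
  std::vector<AttnGrads> g(6);
  double g_tau = 0.0;
  double loss = 0.0;
  const double eps = 1e-7;
  for (int r = 0; r < B; ++r) {
    List bl = blocks[r];
    mat ea = as<mat>(bl["ea"]), eb = as<mat>(bl["eb"]), ee = as<mat>(bl["ee"]);
    RecordCache rc;
    double w_a, w_b;
    double yh = record_forward(ea, eb, ee, P, train, rc, w_a, w_b);
    y_hat[r] = yh; wa_out[r] = w_a; wb_out[r] = w_b;
    if (y.size() == B) {
      double p = std::min(std::max(yh, eps), 1.0 - eps);
      loss += -(pos_weight * y[r] * std::log(p) +
                (1.0 - y[r]) * std::log(1.0 - p));
      if (want_grad && yh > eps && yh < 1.0 - eps) {
        double dy = (-pos_weight * y[r] / p + (1.0 - y[r]) / (1.0 - p)) / B;
        record_backward(dy, rc, P, g, g_tau);
      }
    }
  }
  loss /= B;
  List out = List::create(_["loss"] = loss, _["y_hat"] = y_hat,
                          _["w_a"] = wa_out, _["w_b"] = wb_out);
  if (want_grad) {
    NumericVector grad(flat.size());
    double *gp = grad.begin();
    size_t off = 0;
    for (int a = 0; a < 6; ++a) {
      if (g[a].Wq.n_elem == 0) { // no gradient reached this arrow
        off += 3 * (size_t)d * d;
        continue;
      }
      std::memcpy(gp + off, g[a].Wq.memptr(), sizeof(double) * d * d);
      off += (size_t)d * d;
      std::memcpy(gp + off, g[a].Wk.memptr(), sizeof(double) * d * d);
      off += (size_t)d * d;
      std::memcpy(gp + off, g[a].Wv.memptr(), sizeof(double) * d * d);
      off += (size_t)d * d;
    }
    grad[flat.size() - 1] = g_tau;
    out["grad"] = grad;
  }
  return out;
}
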