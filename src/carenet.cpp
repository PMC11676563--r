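// Core network: three stacked (bidirectional GRU encoder + attention
// pooling) layers over the [period][context][event] hierarchy, numeric
// concatenations, a feed-forward evidential head, the evidential loss, and
// an Adam training loop.  Forward and backward passes are hand-derived;
// everything is single-threaded and deterministic given the seed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

// ---------------------------------------------------------------------------
// parameter containers

struct Gru {          // gate order within the stacked 3H rows: z, r, candidate
  mat W;              // 3H x in
  mat U;              // 3H x H
  vec b;              // 3H
  int H() const { return U.n_cols; }
};

struct Att {
  mat W;              // A x I
  vec b;              // A
  vec q;              // A
};

struct Params {
  mat E;              // V x d token embeddings (row 0 = EMPTY, pinned at 0)
  mat empty_ctx;      // 2H x 6 learned empty-cell context embeddings
  Gru g1f, g1b, g2f, g2b, g3f, g3b;
  Att a1, a2, a3;
  mat ffW1; vec ffb1; // F x (2H + 2Q)
  mat ffW2; vec ffb2; // 8 x F
};

template <class F>
static void for_each_param(Params& a, F f) {
  f(a.E); f(a.empty_ctx);
  Gru* gs[6] = {&a.g1f, &a.g1b, &a.g2f, &a.g2b, &a.g3f, &a.g3b};
  for (auto g : gs) { f(g->W); f(g->U); f(g->b); }
  Att* as[3] = {&a.a1, &a.a2, &a.a3};
  for (auto t : as) { f(t->W); f(t->b); f(t->q); }
  f(a.ffW1); f(a.ffb1); f(a.ffW2); f(a.ffb2);
}

static Gru gru_from(const List& p, const std::string& nm) {
  Gru g;
  g.W = Rcpp::as<mat>(p[nm + "_W"]);
  g.U = Rcpp::as<mat>(p[nm + "_U"]);
  g.b = Rcpp::as<vec>(p[nm + "_b"]);
  return g;
}

static Att att_from(const List& p, const std::string& nm) {
  Att a;
  a.W = Rcpp::as<mat>(p[nm + "_W"]);
  a.b = Rcpp::as<vec>(p[nm + "_b"]);
  a.q = Rcpp::as<vec>(p[nm + "_q"]);
  return a;
}

static Params params_from(const List& p) {
  Params P;
  P.E = Rcpp::as<mat>(p["E"]);
  P.empty_ctx = Rcpp::as<mat>(p["empty_ctx"]);
  P.g1f = gru_from(p, "g1f"); P.g1b = gru_from(p, "g1b");
  P.g2f = gru_from(p, "g2f"); P.g2b = gru_from(p, "g2b");
  P.g3f = gru_from(p, "g3f"); P.g3b = gru_from(p, "g3b");
  P.a1 = att_from(p, "a1"); P.a2 = att_from(p, "a2"); P.a3 = att_from(p, "a3");
  P.ffW1 = Rcpp::as<mat>(p["ffW1"]); P.ffb1 = Rcpp::as<vec>(p["ffb1"]);
  P.ffW2 = Rcpp::as<mat>(p["ffW2"]); P.ffb2 = Rcpp::as<vec>(p["ffb2"]);
  return P;
}

static List params_to(const Params& P) {
  return List::create(
    Named("E") = P.E, Named("empty_ctx") = P.empty_ctx,
    Named("g1f_W") = P.g1f.W, Named("g1f_U") = P.g1f.U, Named("g1f_b") = P.g1f.b,
    Named("g1b_W") = P.g1b.W, Named("g1b_U") = P.g1b.U, Named("g1b_b") = P.g1b.b,
    Named("g2f_W") = P.g2f.W, Named("g2f_U") = P.g2f.U, Named("g2f_b") = P.g2f.b,
    Named("g2b_W") = P.g2b.W, Named("g2b_U") = P.g2b.U, Named("g2b_b") = P.g2b.b,
    Named("g3f_W") = P.g3f.W, Named("g3f_U") = P.g3f.U, Named("g3f_b") = P.g3f.b,
    Named("g3b_W") = P.g3b.W, Named("g3b_U") = P.g3b.U, Named("g3b_b") = P.g3b.b,
    Named("a1_W") = P.a1.W, Named("a1_b") = P.a1.b, Named("a1_q") = P.a1.q,
    Named("a2_W") = P.a2.W, Named("a2_b") = P.a2.b, Named("a2_q") = P.a2.q,
    Named("a3_W") = P.a3.W, Named("a3_b") = P.a3.b, Named("a3_q") = P.a3.q,
    Named("ffW1") = P.ffW1, Named("ffb1") = P.ffb1,
    Named("ffW2") = P.ffW2, Named("ffb2") = P.ffb2);
}

static Params zeros_like(const Params& P) {
  Params Z = P;
  for_each_param(Z, [](auto& m) { m.zeros(); });
  return Z;
}

// ---------------------------------------------------------------------------
// bundles

struct Bundle {
  std::vector<std::vector<uvec>> tokens;  // [M][6], 0-based token ids
  mat pnum;                               // 2P x M: values then mask
  vec onsite;                             // 2Q: values then mask
  vec y;                                  // 4 labels in {0, 1}
};

static Bundle bundle_from(const List& b) {
  Bundle out;
  List tok = b["tokens"];
  int M = tok.size();
  out.tokens.resize(M);
  for (int p = 0; p < M; ++p) {
    List row = tok[p];
    out.tokens[p].resize(6);
    for (int c = 0; c < 6; ++c) {
      Rcpp::IntegerVector v = row[c];
      uvec u(v.size());
      for (int t = 0; t < v.size(); ++t) u[t] = (uword)v[t];
      out.tokens[p][c] = u;
    }
  }
  mat vals = Rcpp::as<mat>(b["period_numeric"]);   // M x P
  mat mask = Rcpp::as<mat>(b["period_mask"]);      // M x P
  out.pnum = join_cols(vals.t(), mask.t());        // 2P x M
  vec ov = Rcpp::as<vec>(b["onsite"]);
  vec om = Rcpp::as<vec>(b["onsite_mask"]);
  out.onsite = join_cols(ov, om);
  Rcpp::LogicalVector lv = b["labels"];
  out.y.set_size(4);
  for (int j = 0; j < 4; ++j) out.y[j] = lv[j] ? 1.0 : 0.0;
  return out;
}

static std::vector<Bundle> bundles_from(const List& bl) {
  std::vector<Bundle> out;
  out.reserve(bl.size());
  for (int i = 0; i < bl.size(); ++i) out.push_back(bundle_from(bl[i]));
  return out;
}

// ---------------------------------------------------------------------------
// GRU forward/backward
//
//   z_t = sigma(Wz x_t + Uz h_{t-1} + bz)
//   r_t = sigma(Wr x_t + Ur h_{t-1} + br)
//   c_t = tanh(Wc x_t + Uc (r_t o h_{t-1}) + bc)
//   h_t = (1 - z_t) o h_{t-1} + z_t o c_t,  h_0 = 0

struct GruCache {
  mat X;              // in x T
  mat z, r, c;        // H x T
  mat h;              // H x (T + 1); col 0 is h_0 = 0
};

static void gru_forward(const Gru& g, const mat& X, GruCache& cc) {
  const int H = g.H(), T = X.n_cols;
  cc.X = X;
  cc.z.set_size(H, T); cc.r.set_size(H, T); cc.c.set_size(H, T);
  cc.h.zeros(H, T + 1);
  mat WX = g.W * X;                     // 3H x T
  const mat Uzr = g.U.rows(0, 2 * H - 1);
  const mat Uc = g.U.rows(2 * H, 3 * H - 1);
  for (int t = 0; t < T; ++t) {
    vec hp = cc.h.col(t);
    vec pre = WX.col(t) + g.b;
    vec uzr = Uzr * hp;
    vec z = 1.0 / (1.0 + exp(-(pre.head(H) + uzr.head(H))));
    vec r = 1.0 / (1.0 + exp(-(pre.subvec(H, 2 * H - 1) + uzr.tail(H))));
    vec c = tanh(pre.tail(H) + Uc * (r % hp));
    cc.z.col(t) = z; cc.r.col(t) = r; cc.c.col(t) = c;
    cc.h.col(t + 1) = (1.0 - z) % hp + z % c;
  }
}

// dH: H x T gradient wrt each output state h_t; accumulates parameter
// gradients into gg and returns dX (in x T).
static mat gru_backward(const Gru& g, const GruCache& cc, const mat& dH,
                        Gru& gg) {
  const int H = g.H(), T = cc.X.n_cols;
  const mat Uzr = g.U.rows(0, 2 * H - 1);
  const mat Uc = g.U.rows(2 * H, 3 * H - 1);
  mat DA(3 * H, T);                     // pre-activation grads (z, r, c)
  mat HP(H, T), RHP(H, T);              // h_{t-1} and r o h_{t-1} per step
  vec dh = zeros<vec>(H);
  for (int t = T - 1; t >= 0; --t) {
    dh += dH.col(t);
    vec hp = cc.h.col(t), z = cc.z.col(t), r = cc.r.col(t), c = cc.c.col(t);
    vec dz = dh % (c - hp);
    vec dc = dh % z;
    vec dhp = dh % (1.0 - z);
    vec dac = dc % (1.0 - c % c);
    vec drh = Uc.t() * dac;
    vec dr = drh % hp;
    dhp += drh % r;
    vec daz = dz % z % (1.0 - z);
    vec dar = dr % r % (1.0 - r);
    DA.col(t) = join_cols(daz, join_cols(dar, dac));
    HP.col(t) = hp; RHP.col(t) = r % hp;
    dhp += Uzr.t() * join_cols(daz, dar);
    dh = dhp;
  }
  gg.W += DA * cc.X.t();
  gg.U.rows(0, 2 * H - 1) += DA.rows(0, 2 * H - 1) * HP.t();
  gg.U.rows(2 * H, 3 * H - 1) += DA.rows(2 * H, 3 * H - 1) * RHP.t();
  gg.b += sum(DA, 1);
  return g.W.t() * DA;
}

// bidirectional wrapper: rows 0..H-1 forward states, H..2H-1 backward states
struct BiCache { GruCache f, b; };

static mat bigru_forward(const Gru& gf, const Gru& gb, const mat& X,
                         BiCache& cc) {
  gru_forward(gf, X, cc.f);
  gru_forward(gb, fliplr(X), cc.b);
  const int T = X.n_cols, H = gf.H();
  return join_cols(cc.f.h.cols(1, T), fliplr(cc.b.h.cols(1, T)));
}

static mat bigru_backward(const Gru& gf, const Gru& gb, const BiCache& cc,
                          const mat& dS, Gru& ggf, Gru& ggb) {
  const int H = gf.H();
  mat dXf = gru_backward(gf, cc.f, dS.rows(0, H - 1), ggf);
  mat dXb = gru_backward(gb, cc.b, fliplr(dS.rows(H, 2 * H - 1)), ggb);
  return dXf + fliplr(dXb);
}

// ---------------------------------------------------------------------------
// attention pooling: u_t = tanh(W h_t + b); a = softmax(u_t . q); s = sum a h

struct AttCache { mat S; mat U; vec a; };

static vec att_forward(const Att& at, const mat& S, AttCache& cc) {
  cc.S = S;
  cc.U = tanh(at.W * S + repmat(at.b, 1, S.n_cols));
  vec sc = cc.U.t() * at.q;
  sc -= sc.max();
  cc.a = exp(sc);
  cc.a /= accu(cc.a);
  return S * cc.a;
}

static mat att_backward(const Att& at, const AttCache& cc, const vec& ds,
                        Att& ga) {
  vec da = cc.S.t() * ds;
  mat dS = ds * cc.a.t();
  vec dsc = cc.a % (da - dot(cc.a, da));
  ga.q += cc.U * dsc;
  mat dpre = (at.q * dsc.t()) % (1.0 - cc.U % cc.U);
  ga.W += dpre * cc.S.t();
  ga.b += sum(dpre, 1);
  dS += at.W.t() * dpre;
  return dS;
}

// ---------------------------------------------------------------------------
// full forward

struct CellCache { BiCache enc; AttCache att; bool empty; };

struct VisitCache {
  std::vector<std::vector<CellCache>> cell;  // [M][6]
  std::vector<mat> ctx_emb;                  // per period, 2H x 6
  std::vector<BiCache> enc2;                 // per period
  std::vector<AttCache> att2;
  std::vector<mat> S2;                       // per period, 2H x 6
  mat X3;                                    // (2H + 2P) x M
  BiCache enc3; AttCache att3; mat S3;       // 2H x M
  vec patrep, h1, out, ev;
};

static double softplus(double x) {
  return x > 30 ? x : (x < -30 ? std::exp(x) : std::log1p(std::exp(x)));
}
static double sigmoidf(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static void cn_forward_one(const Params& P, const Bundle& b, VisitCache& vc) {
  const int M = b.tokens.size();
  const int H = P.g1f.H();
  vc.cell.assign(M, std::vector<CellCache>(6));
  vc.ctx_emb.assign(M, mat(2 * H, 6));
  vc.enc2.resize(M); vc.att2.resize(M); vc.S2.resize(M);
  vc.X3.set_size(2 * H + b.pnum.n_rows, M);

  for (int p = 0; p < M; ++p) {
    for (int c = 0; c < 6; ++c) {
      CellCache& cc = vc.cell[p][c];
      const uvec& tok = b.tokens[p][c];
      cc.empty = tok.n_elem == 0;
      if (cc.empty) {
        vc.ctx_emb[p].col(c) = P.empty_ctx.col(c);
      } else {
        mat X = P.E.rows(tok).t();                    // d x T
        mat S = bigru_forward(P.g1f, P.g1b, X, cc.enc);
        vc.ctx_emb[p].col(c) = att_forward(P.a1, S, cc.att);
      }
    }
    mat S2 = bigru_forward(P.g2f, P.g2b, vc.ctx_emb[p], vc.enc2[p]);
    vc.S2[p] = S2;
    vec s2 = att_forward(P.a2, S2, vc.att2[p]);
    vc.X3.col(p) = join_cols(s2, b.pnum.col(p));
  }
  vc.S3 = bigru_forward(P.g3f, P.g3b, vc.X3, vc.enc3);
  vec s3 = att_forward(P.a3, vc.S3, vc.att3);
  vc.patrep = join_cols(s3, b.onsite);
  vc.h1 = P.ffW1 * vc.patrep + P.ffb1;
  vc.h1.transform([](double x) { return x > 0 ? x : 0.0; });
  vc.out = P.ffW2 * vc.h1 + P.ffb2;
  vc.ev = vc.out;
  vc.ev.transform([](double x) { return softplus(x); });
}

// evidential loss for one visit; fills dev (dL/d evidence) when wanted
static double evid_loss(const vec& ev, const vec& y, double lambda,
                        vec* dev) {
  double L = 0;
  if (dev) dev->zeros(8);
  for (int j = 0; j < 4; ++j) {
    double ep = ev[j], en = ev[4 + j], yj = y[j];
    double al = ep + 1, be = en + 1, S = al + be, p = al / S;
    L += (yj - p) * (yj - p) + p * (1 - p) / (S + 1);
    double at = 1 + (1 - yj) * ep, bt = 1 + yj * en;
    double KL = std::lgamma(at + bt) - std::lgamma(at) - std::lgamma(bt) +
      (at - 1) * R::digamma(at) + (bt - 1) * R::digamma(bt) -
      (at + bt - 2) * R::digamma(at + bt);
    L += lambda * KL;
    if (dev) {
      double dp = -2 * (yj - p) + (1 - 2 * p) / (S + 1);
      double dS = -p * (1 - p) / ((S + 1) * (S + 1));
      double dal = dp * be / (S * S) + dS;
      double dbe = -dp * al / (S * S) + dS;
      double dat = (at - 1) * R::trigamma(at) -
        (at + bt - 2) * R::trigamma(at + bt);
      double dbt = (bt - 1) * R::trigamma(bt) -
        (at + bt - 2) * R::trigamma(at + bt);
      (*dev)[j] = dal + lambda * dat * (1 - yj);
      (*dev)[4 + j] = dbe + lambda * dbt * yj;
    }
  }
  return L;
}

// backward through the whole network; scale multiplies the loss gradient
static void cn_backward_one(const Params& P, const Bundle& b,
                            const VisitCache& vc, const vec& dev_in,
                            double scale, Params& G) {
  const int M = b.tokens.size();
  const int H = P.g1f.H();
  vec dout(8);
  for (int j = 0; j < 8; ++j) dout[j] = scale * dev_in[j] * sigmoidf(vc.out[j]);

  G.ffW2 += dout * vc.h1.t();
  G.ffb2 += dout;
  vec dh1 = P.ffW2.t() * dout;
  for (uword i = 0; i < dh1.n_elem; ++i) if (vc.h1[i] <= 0) dh1[i] = 0;
  G.ffW1 += dh1 * vc.patrep.t();
  G.ffb1 += dh1;
  vec dpat = P.ffW1.t() * dh1;
  vec ds3 = dpat.head(2 * H);

  mat dS3 = att_backward(P.a3, vc.att3, ds3, G.a3);
  mat dX3 = bigru_backward(P.g3f, P.g3b, vc.enc3, dS3, G.g3f, G.g3b);

  for (int p = 0; p < M; ++p) {
    vec ds2 = dX3.col(p).head(2 * H);
    mat dS2 = att_backward(P.a2, vc.att2[p], ds2, G.a2);
    mat dX2 = bigru_backward(P.g2f, P.g2b, vc.enc2[p], dS2, G.g2f, G.g2b);
    for (int c = 0; c < 6; ++c) {
      vec dctx = dX2.col(c);
      const CellCache& cc = vc.cell[p][c];
      if (cc.empty) {
        G.empty_ctx.col(c) += dctx;
      } else {
        mat dS1 = att_backward(P.a1, cc.att, dctx, G.a1);
        mat dX = bigru_backward(P.g1f, P.g1b, cc.enc, dS1, G.g1f, G.g1b);
        const uvec& tok = b.tokens[p][c];
        for (uword t = 0; t < tok.n_elem; ++t) {
          G.E.row(tok[t]) += dX.col(t).t();
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// exported entry points

// [[Rcpp::export(name = ".cn_forward_cpp")]]
List cn_forward_cpp(List params, List bundle, bool detail = false) {
  Params P = params_from(params);
  Bundle b = bundle_from(bundle);
  VisitCache vc;
  cn_forward_one(P, b, vc);
  const int M = b.tokens.size();

  List att_event(M);
  mat att_ctx(M, 6);
  List ev_hidden(M), ctx_hidden(M), ctx_emb(M), pooled_period(M);
  for (int p = 0; p < M; ++p) {
    List row(6), hrow(6);
    for (int c = 0; c < 6; ++c) {
      const CellCache& cc = vc.cell[p][c];
      if (cc.empty) {
        row[c] = Rcpp::NumericVector(0);
        if (detail) hrow[c] = mat(0, 0);
      } else {
        row[c] = Rcpp::wrap(cc.att.a);
        if (detail) hrow[c] = cc.att.S;
      }
    }
    att_event[p] = row;
    att_ctx.row(p) = vc.att2[p].a.t();
    if (detail) {
      ev_hidden[p] = hrow;
      ctx_hidden[p] = vc.S2[p];
      ctx_emb[p] = vc.ctx_emb[p];
      pooled_period[p] = Rcpp::wrap(vec(vc.X3.col(p).head(2 * P.g1f.H())));
    }
  }
  List out = List::create(
    Named("evidence") = vc.ev,
    Named("att_event") = att_event,
    Named("att_context") = att_ctx,
    Named("att_period") = vc.att3.a);
  if (detail) {
    out["event_hidden"] = ev_hidden;
    out["context_hidden"] = ctx_hidden;
    out["context_emb"] = ctx_emb;
    out["period_hidden"] = vc.S3;
    out["pooled_period"] = pooled_period;
    out["pooled_patient"] = vc.att3.S * vc.att3.a;
    out["patrep"] = vc.patrep;
  }
  return out;
}

// [[Rcpp::export(name = ".cn_predict_cpp")]]
arma::mat cn_predict_cpp(List params, List bundles) {
  Params P = params_from(params);
  std::vector<Bundle> bs = bundles_from(bundles);
  mat out(bs.size(), 8);
  VisitCache vc;
  for (size_t i = 0; i < bs.size(); ++i) {
    cn_forward_one(P, bs[i], vc);
    out.row(i) = vc.ev.t();
  }
  return out;
}

// [[Rcpp::export(name = ".cn_loss_grad_cpp")]]
List cn_loss_grad_cpp(List params, List bundles, double lambda) {
  Params P = params_from(params);
  std::vector<Bundle> bs = bundles_from(bundles);
  Params G = zeros_like(P);
  double total = 0;
  const double scale = 1.0 / bs.size();
  VisitCache vc;
  vec dev(8);
  for (size_t i = 0; i < bs.size(); ++i) {
    cn_forward_one(P, bs[i], vc);
    total += evid_loss(vc.ev, bs[i].y, lambda, &dev);
    cn_backward_one(P, bs[i], vc, dev, scale, G);
  }
  return List::create(Named("loss") = total * scale,
                      Named("grads") = params_to(G));
}

// [[Rcpp::export(name = ".cn_loss_cpp")]]
double cn_loss_cpp(List params, List bundles, double lambda) {
  Params P = params_from(params);
  std::vector<Bundle> bs = bundles_from(bundles);
  double total = 0;
  VisitCache vc;
  for (size_t i = 0; i < bs.size(); ++i) {
    cn_forward_one(P, bs[i], vc);
    total += evid_loss(vc.ev, bs[i].y, lambda, nullptr);
  }
  return total / bs.size();
}

// [[Rcpp::export(name = ".cn_train_cpp")]]
List cn_train_cpp(List params, List bundles, double lr, int batch,
                  int epochs, int seed, int anneal_epochs = 10) {
  Params P = params_from(params);
  std::vector<Bundle> bs = bundles_from(bundles);
  const int n = bs.size();
  Params G = zeros_like(P), Mo = zeros_like(P), Vo = zeros_like(P);
  std::mt19937 rng((uint32_t)seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  vec losses(epochs);
  VisitCache vc;
  vec dev(8);

  for (int epoch = 0; epoch < epochs; ++epoch) {
    double lambda = anneal_epochs > 0 ?
      std::min(1.0, (double)epoch / anneal_epochs) : 1.0;
    std::shuffle(order.begin(), order.end(), rng);
    double epoch_loss = 0;
    for (int start = 0; start < n; start += batch) {
      int end = std::min(n, start + batch);
      double scale = 1.0 / (end - start);
      for_each_param(G, [](auto& m) { m.zeros(); });
      for (int i = start; i < end; ++i) {
        const Bundle& b = bs[order[i]];
        cn_forward_one(P, b, vc);
        double L = evid_loss(vc.ev, b.y, lambda, &dev);
        if (!std::isfinite(L)) {
          Rcpp::stop("training diverged (non-finite loss) at epoch %d", epoch);
        }
        epoch_loss += L;
        cn_backward_one(P, b, vc, dev, scale, G);
      }
      // Adam update
      ++step;
      double corr = lr * std::sqrt(1.0 - std::pow(b2, (double)step)) /
        (1.0 - std::pow(b1, (double)step));
      mat* pp[64]; mat* pg[64]; mat* pm[64]; mat* pv[64];
      int np = 0;
      for_each_param(P, [&](mat& m) { pp[np++] = &m; });
      np = 0; for_each_param(G, [&](mat& m) { pg[np++] = &m; });
      np = 0; for_each_param(Mo, [&](mat& m) { pm[np++] = &m; });
      np = 0; for_each_param(Vo, [&](mat& m) { pv[np++] = &m; });
      for (int kk = 0; kk < np; ++kk) {
        mat& m = *pm[kk]; mat& v = *pv[kk];
        const mat& g = *pg[kk];
        m = b1 * m + (1 - b1) * g;
        v = b2 * v + (1 - b2) * square(g);
        *pp[kk] -= corr * m / (sqrt(v) + eps);
      }
      P.E.row(0).zeros();  // EMPTY embedding stays pinned at zero
    }
    losses[epoch] = epoch_loss / n;
  }
  return List::create(Named("params") = params_to(P),
                      Named("loss") = losses);
}

// standalone primitives, exposed for composition and testing

// [[Rcpp::export(name = ".cn_gru_cpp")]]
arma::mat cn_gru_cpp(arma::mat W, arma::mat U, arma::vec b, arma::mat X) {
  Gru g; g.W = W; g.U = U; g.b = b;
  GruCache cc;
  gru_forward(g, X, cc);
  return cc.h.cols(1, X.n_cols);
}

// [[Rcpp::export(name = ".cn_att_cpp")]]
List cn_att_cpp(arma::mat W, arma::vec b, arma::vec q, arma::mat S) {
  Att at; at.W = W; at.b = b; at.q = q;
  AttCache cc;
  vec s = att_forward(at, S, cc);
  return List::create(Named("weights") = cc.a, Named("pooled") = s);
}
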