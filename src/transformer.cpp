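// Sequence-to-sequence transformer (encoder-decoder, multi-head
// attention, sinusoidal positional encoding) with hand-derived
// backpropagation, Adam updates and multinomial sampling.
//
// Pre-norm residual layout (LayerNorm before each sublayer, final
// LayerNorm after each stack) is used for training stability at small
// scale. Token ids are 0-based with 0 = <pad>; activations are stored
// as (batch*time) x width matrices, row index b*T + t.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double ADAM_B1 = 0.9, ADAM_B2 = 0.98, ADAM_EPS = 1e-9;
static const double NEG_INF = -1e30;

struct Par {
  mat w, m, v;
  void init(int r, int c, std::mt19937_64 &rng, bool xavier = true,
            double fill_val = 0.0) {
    w.set_size(r, c);
    if (xavier) {
      double lim = std::sqrt(6.0 / (r + c));
      std::uniform_real_distribution<double> U(-lim, lim);
      for (uword i = 0; i < w.n_elem; ++i) w(i) = U(rng);
    } else {
      w.fill(fill_val);
    }
    m.zeros(r, c); v.zeros(r, c);
  }
  mat g;  // gradient accumulator for the current step
  void zero_grad() { g.zeros(w.n_rows, w.n_cols); }
};

struct Linear {
  Par W, b;
  void init(int din, int dout, std::mt19937_64 &rng) {
    W.init(din, dout, rng);
    b.init(1, dout, rng, false, 0.0);
  }
  mat fwd(const mat &X) { return X * W.w + repmat(b.w, X.n_rows, 1); }
  // returns dX; accumulates into W.g, b.g
  mat bwd(const mat &X, const mat &dY) {
    W.g += X.t() * dY;
    b.g += sum(dY, 0);
    return dY * W.w.t();
  }
};

struct LNorm {
  Par gmm, bta;
  void init(int d, std::mt19937_64 &rng) {
    gmm.init(1, d, rng, false, 1.0);
    bta.init(1, d, rng, false, 0.0);
  }
  struct Cache { mat xhat; vec invstd; };
  mat fwd(const mat &X, Cache &c) {
    vec mu = mean(X, 1);
    mat cen = X.each_col() - mu;
    vec var = mean(square(cen), 1);
    c.invstd = 1.0 / sqrt(var + 1e-6);
    c.xhat = cen.each_col() % c.invstd;
    mat Y = c.xhat.each_row() % gmm.w;
    return Y.each_row() + bta.w;
  }
  mat bwd(const mat &dY, const Cache &c) {
    gmm.g += sum(dY % c.xhat, 0);
    bta.g += sum(dY, 0);
    mat dxhat = dY.each_row() % gmm.w;
    double D = (double)dY.n_cols;
    vec t1 = sum(dxhat, 1) / D;
    vec t2 = sum(dxhat % c.xhat, 1) / D;
    mat dX = dxhat;
    dX.each_col() -= t1;
    dX -= c.xhat.each_col() % t2;
    dX.each_col() %= c.invstd;
    return dX;
  }
};

struct MHA {
  Linear lq, lk, lv, lo;
  int H, D, dh;
  void init(int d, int heads, std::mt19937_64 &rng) {
    D = d; H = heads; dh = d / heads;
    lq.init(d, d, rng); lk.init(d, d, rng);
    lv.init(d, d, rng); lo.init(d, d, rng);
  }
  struct Cache {
    mat Q, K, V, ctx;      // (B*Tq|Tk) x D
    cube P;                // Tq x Tk x (B*H) attention weights
    const mat *Xq, *Xkv;   // inputs (borrowed)
  };
  // key_mask: B x Tk, 1 = usable key; causal: only attend to <= own pos
  mat fwd(const mat &Xq, const mat &Xkv, int B, int Tq, int Tk,
          const umat &key_mask, bool causal, Cache &c) {
    c.Xq = &Xq; c.Xkv = &Xkv;
    c.Q = lq.fwd(Xq); c.K = lk.fwd(Xkv); c.V = lv.fwd(Xkv);
    c.P.set_size(Tq, Tk, B * H);
    c.ctx.set_size(B * Tq, D);
    double scale = 1.0 / std::sqrt((double)dh);
    for (int b = 0; b < B; ++b) {
      for (int h = 0; h < H; ++h) {
        mat Qh = c.Q.submat(b * Tq, h * dh, b * Tq + Tq - 1, h * dh + dh - 1);
        mat Kh = c.K.submat(b * Tk, h * dh, b * Tk + Tk - 1, h * dh + dh - 1);
        mat Vh = c.V.submat(b * Tk, h * dh, b * Tk + Tk - 1, h * dh + dh - 1);
        mat S = Qh * Kh.t() * scale;
        for (int tk = 0; tk < Tk; ++tk)
          if (key_mask(b, tk) == 0) S.col(tk).fill(NEG_INF);
        if (causal)
          for (int tq = 0; tq < Tq; ++tq)
            for (int tk = tq + 1; tk < Tk; ++tk) S(tq, tk) = NEG_INF;
        // row softmax
        vec mx = max(S, 1);
        S.each_col() -= mx;
        mat P = exp(S);
        vec Z = sum(P, 1);
        P.each_col() /= Z;
        c.P.slice(b * H + h) = P;
        c.ctx.submat(b * Tq, h * dh, b * Tq + Tq - 1, h * dh + dh - 1) =
          P * Vh;
      }
    }
    return lo.fwd(c.ctx);
  }
  // returns dXq; adds dXkv into dXkv_acc
  mat bwd(const mat &dY, int B, int Tq, int Tk, Cache &c, mat &dXkv_acc) {
    mat dctx = lo.bwd(c.ctx, dY);
    mat dQ(size(c.Q), fill::zeros), dK(size(c.K), fill::zeros),
        dV(size(c.V), fill::zeros);
    double scale = 1.0 / std::sqrt((double)dh);
    for (int b = 0; b < B; ++b) {
      for (int h = 0; h < H; ++h) {
        mat Qh = c.Q.submat(b * Tq, h * dh, b * Tq + Tq - 1, h * dh + dh - 1);
        mat Kh = c.K.submat(b * Tk, h * dh, b * Tk + Tk - 1, h * dh + dh - 1);
        mat Vh = c.V.submat(b * Tk, h * dh, b * Tk + Tk - 1, h * dh + dh - 1);
        const mat &P = c.P.slice(b * H + h);
        mat dctx_h = dctx.submat(b * Tq, h * dh, b * Tq + Tq - 1,
                                 h * dh + dh - 1);
        mat dP = dctx_h * Vh.t();
        dV.submat(b * Tk, h * dh, b * Tk + Tk - 1, h * dh + dh - 1) +=
          P.t() * dctx_h;
        // softmax backward: dS = P % (dP - rowsum(dP % P))
        vec rs = sum(dP % P, 1);
        mat dS = P % (dP.each_col() - rs);
        dQ.submat(b * Tq, h * dh, b * Tq + Tq - 1, h * dh + dh - 1) +=
          dS * Kh * scale;
        dK.submat(b * Tk, h * dh, b * Tk + Tk - 1, h * dh + dh - 1) +=
          dS.t() * Qh * scale;
      }
    }
    mat dXq = lq.bwd(*c.Xq, dQ);
    dXkv_acc += lk.bwd(*c.Xkv, dK);
    dXkv_acc += lv.bwd(*c.Xkv, dV);
    return dXq;
  }
};

struct FFN {
  Linear l1, l2;
  void init(int d, int f, std::mt19937_64 &rng) {
    l1.init(d, f, rng); l2.init(f, d, rng);
  }
  struct Cache { mat h; const mat *X; };
  mat fwd(const mat &X, Cache &c) {
    c.X = &X;
    c.h = l1.fwd(X);
    c.h.transform([](double x) { return x > 0 ? x : 0.0; });
    return l2.fwd(c.h);
  }
  mat bwd(const mat &dY, Cache &c) {
    mat dh = l2.bwd(c.h, dY);
    dh %= conv_to<mat>::from(c.h > 0);
    return l1.bwd(*c.X, dh);
  }
};

struct EncLayer {
  LNorm ln1, ln2; MHA att; FFN ff;
  struct Cache {
    LNorm::Cache c1, c2; MHA::Cache ca; FFN::Cache cf;
    mat x, n1, n2, m1, m2;  // inputs, normed, dropout masks
  };
};

struct DecLayer {
  LNorm ln1, ln2, ln3; MHA self_att, cross; FFN ff;
  struct Cache {
    LNorm::Cache c1, c2, c3; MHA::Cache cs, cc; FFN::Cache cf;
    mat x, n1, n2, n3, m1, m2, m3;
  };
};

struct Model {
  int V, D, H, F, L, maxT;
  double dropout;
  Par emb, out_b;
  Linear out;
  mat pe;
  std::vector<EncLayer> enc;
  std::vector<DecLayer> dec;
  LNorm ln_enc, ln_dec;
  LNorm::Cache ce_f, cd_f;
  long step = 0;
  std::mt19937_64 rng;
  bool training = true;
  int dh_of() const { return D / H; }

  std::vector<Par *> pars;

  void build(int v, int d, int heads, int layers, int f, int maxt,
             double drop, uint64_t seed) {
    V = v; D = d; H = heads; L = layers; F = f; maxT = maxt;
    dropout = drop;
    rng.seed(seed);
    emb.init(V, D, rng);
    out.init(D, V, rng);
    enc.resize(L); dec.resize(L);
    for (auto &e : enc) {
      e.ln1.init(D, rng); e.ln2.init(D, rng);
      e.att.init(D, H, rng); e.ff.init(D, F, rng);
    }
    for (auto &d2 : dec) {
      d2.ln1.init(D, rng); d2.ln2.init(D, rng); d2.ln3.init(D, rng);
      d2.self_att.init(D, H, rng); d2.cross.init(D, H, rng);
      d2.ff.init(D, F, rng);
    }
    ln_enc.init(D, rng); ln_dec.init(D, rng);
    pe.set_size(maxT, D);
    for (int t = 0; t < maxT; ++t)
      for (int i = 0; i < D; ++i) {
        double ang = t / std::pow(10000.0, 2.0 * (i / 2) / D);
        pe(t, i) = (i % 2 == 0) ? std::sin(ang) : std::cos(ang);
      }
    collect();
  }

  void collect() {
    pars.clear();
    auto lin = [&](Linear &l) { pars.push_back(&l.W); pars.push_back(&l.b); };
    auto ln = [&](LNorm &l) { pars.push_back(&l.gmm); pars.push_back(&l.bta); };
    pars.push_back(&emb);
    lin(out);
    for (auto &e : enc) {
      ln(e.ln1); lin(e.att.lq); lin(e.att.lk); lin(e.att.lv); lin(e.att.lo);
      ln(e.ln2); lin(e.ff.l1); lin(e.ff.l2);
    }
    for (auto &d2 : dec) {
      ln(d2.ln1); lin(d2.self_att.lq); lin(d2.self_att.lk);
      lin(d2.self_att.lv); lin(d2.self_att.lo);
      ln(d2.ln2); lin(d2.cross.lq); lin(d2.cross.lk); lin(d2.cross.lv);
      lin(d2.cross.lo);
      ln(d2.ln3); lin(d2.ff.l1); lin(d2.ff.l2);
    }
    ln(ln_enc); ln(ln_dec);
  }

  mat drop_mask(int r, int c) {
    mat m(r, c);
    if (!training || dropout <= 0) { m.ones(); return m; }
    std::uniform_real_distribution<double> U(0.0, 1.0);
    double keep = 1.0 - dropout;
    for (uword i = 0; i < m.n_elem; ++i)
      m(i) = (U(rng) < keep) ? 1.0 / keep : 0.0;
    return m;
  }

  mat embed(const imat &ids, int B, int T) {
    mat X(B * T, D);
    double s = std::sqrt((double)D);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < T; ++t)
        X.row(b * T + t) = emb.w.row(ids(b, t)) * s + pe.row(t);
    return X;
  }

  void embed_bwd(const imat &ids, int B, int T, const mat &dX) {
    double s = std::sqrt((double)D);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < T; ++t)
        emb.g.row(ids(b, t)) += dX.row(b * T + t) * s;
  }

  // ---- encoder ----
  mat enc_fwd(const imat &src, int B, int Ts, const umat &smask,
              std::vector<EncLayer::Cache> &cc, mat &emb_mask) {
    mat x = embed(src, B, Ts);
    emb_mask = drop_mask(x.n_rows, x.n_cols);
    x %= emb_mask;
    cc.resize(L);
    for (int l = 0; l < L; ++l) {
      EncLayer &e = enc[l]; EncLayer::Cache &c = cc[l];
      c.x = x;
      c.n1 = e.ln1.fwd(x, c.c1);
      mat a = e.att.fwd(c.n1, c.n1, B, Ts, Ts, smask, false, c.ca);
      c.m1 = drop_mask(a.n_rows, a.n_cols);
      x += a % c.m1;
      c.n2 = e.ln2.fwd(x, c.c2);
      mat f = e.ff.fwd(c.n2, c.cf);
      c.m2 = drop_mask(f.n_rows, f.n_cols);
      x += f % c.m2;
    }
    return ln_enc.fwd(x, ce_f);
  }

  mat enc_bwd(const imat &src, int B, int Ts,
              std::vector<EncLayer::Cache> &cc, const mat &d_enc_out,
              const mat &emb_mask) {
    mat dx = ln_enc.bwd(d_enc_out, ce_f);
    for (int l = L - 1; l >= 0; --l) {
      EncLayer &e = enc[l]; EncLayer::Cache &c = cc[l];
      mat df = dx % c.m2;
      mat dn2 = e.ff.bwd(df, c.cf);
      dx += e.ln2.bwd(dn2, c.c2);
      mat da = dx % c.m1;
      mat dkv(size(dx), fill::zeros);
      mat dn1 = e.att.bwd(da, B, Ts, Ts, c.ca, dkv);
      dn1 += dkv;  // self-attention: query and key/value share the input
      dx += e.ln1.bwd(dn1, c.c1);
    }
    dx %= emb_mask;
    embed_bwd(src, B, Ts, dx);
    return dx;
  }

  // ---- decoder ----
  mat dec_fwd(const imat &tgt, int B, int Tt, const mat &enc_out, int Ts,
              const umat &smask, std::vector<DecLayer::Cache> &cc,
              mat &emb_mask) {
    mat x = embed(tgt, B, Tt);
    emb_mask = drop_mask(x.n_rows, x.n_cols);
    x %= emb_mask;
    umat allkeys(B, Tt, fill::ones);
    cc.resize(L);
    for (int l = 0; l < L; ++l) {
      DecLayer &d2 = dec[l]; DecLayer::Cache &c = cc[l];
      c.x = x;
      c.n1 = d2.ln1.fwd(x, c.c1);
      mat a = d2.self_att.fwd(c.n1, c.n1, B, Tt, Tt, allkeys, true, c.cs);
      c.m1 = drop_mask(a.n_rows, a.n_cols);
      x += a % c.m1;
      c.n2 = d2.ln2.fwd(x, c.c2);
      mat cr = d2.cross.fwd(c.n2, enc_out, B, Tt, Ts, smask, false, c.cc);
      c.m2 = drop_mask(cr.n_rows, cr.n_cols);
      x += cr % c.m2;
      c.n3 = d2.ln3.fwd(x, c.c3);
      mat f = d2.ff.fwd(c.n3, c.cf);
      c.m3 = drop_mask(f.n_rows, f.n_cols);
      x += f % c.m3;
    }
    return ln_dec.fwd(x, cd_f);
  }

  mat dec_bwd(const imat &tgt, int B, int Tt, int Ts,
              std::vector<DecLayer::Cache> &cc, const mat &d_dec_out,
              const mat &emb_mask, mat &d_enc_out) {
    mat dx = ln_dec.bwd(d_dec_out, cd_f);
    for (int l = L - 1; l >= 0; --l) {
      DecLayer &d2 = dec[l]; DecLayer::Cache &c = cc[l];
      mat df = dx % c.m3;
      mat dn3 = d2.ff.bwd(df, c.cf);
      dx += d2.ln3.bwd(dn3, c.c3);
      mat dcr = dx % c.m2;
      mat dn2 = d2.cross.bwd(dcr, B, Tt, Ts, c.cc, d_enc_out);
      dx += d2.ln2.bwd(dn2, c.c2);
      mat da = dx % c.m1;
      mat dkv(size(dx), fill::zeros);
      mat dn1 = d2.self_att.bwd(da, B, Tt, Tt, c.cs, dkv);
      dn1 += dkv;
      dx += d2.ln1.bwd(dn1, c.c1);
    }
    dx %= emb_mask;
    embed_bwd(tgt, B, Tt, dx);
    return dx;
  }

  // cross-entropy on logits rows where tgt_out != 0; fills dlogits
  double loss_and_grad(const mat &hdec, const imat &tgt_out, int B, int Tt,
                       mat &dh, bool want_grad) {
    mat logits = out.fwd(hdec);
    int nvalid = 0;
    for (uword i = 0; i < tgt_out.n_elem; ++i)
      if (tgt_out(i) != 0) ++nvalid;
    double loss = 0;
    mat dlogits;
    if (want_grad) dlogits.zeros(size(logits));
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < Tt; ++t) {
        int y = tgt_out(b, t);
        if (y == 0) continue;
        rowvec z = logits.row(b * Tt + t);
        double mx = z.max();
        rowvec p = exp(z - mx);
        double Z = accu(p);
        p /= Z;
        loss += -std::log(std::max(p(y), 1e-12));
        if (want_grad) {
          p(y) -= 1.0;
          dlogits.row(b * Tt + t) = p / nvalid;
        }
      }
    loss /= std::max(nvalid, 1);
    if (want_grad) dh = out.bwd(hdec, dlogits);
    return loss;
  }

  void adam(double lr) {
    ++step;
    double bc1 = 1.0 - std::pow(ADAM_B1, (double)step);
    double bc2 = 1.0 - std::pow(ADAM_B2, (double)step);
    // global grad-norm clip at 5
    double nrm2 = 0;
    for (Par *p : pars) nrm2 += accu(square(p->g));
    double clip = std::sqrt(nrm2) > 5.0 ? 5.0 / std::sqrt(nrm2) : 1.0;
    for (Par *p : pars) {
      mat g = p->g * clip;
      p->m = ADAM_B1 * p->m + (1 - ADAM_B1) * g;
      p->v = ADAM_B2 * p->v + (1 - ADAM_B2) * square(g);
      p->w -= lr * (p->m / bc1) / (sqrt(p->v / bc2) + ADAM_EPS);
    }
  }
};

static umat pad_mask(const imat &ids) {
  umat m(ids.n_rows, ids.n_cols);
  for (uword i = 0; i < ids.n_elem; ++i) m(i) = ids(i) != 0;
  return m;
}

// [[Rcpp::export(name = ".tfCreate")]]
SEXP tfCreate(int vocab, int d_model, int n_heads, int n_layers, int d_ff,
              int max_len, double dropout, int seed) {
  if (d_model % n_heads != 0)
    Rcpp::stop("model width must be divisible by the number of heads");
  Model *m = new Model();
  m->build(vocab, d_model, n_heads, n_layers, d_ff, max_len, dropout,
           (uint64_t)seed);
  Rcpp::XPtr<Model> p(m, true);
  return p;
}

static void check_ids(Model *m, const imat &ids) {
  if ((int)ids.max() >= m->V || ids.min() < 0)
    Rcpp::stop("token id out of vocabulary range");
  if ((int)ids.n_cols > m->maxT)
    Rcpp::stop("sequence exceeds maximum length");
}

// one optimization step; returns the batch loss
// [[Rcpp::export(name = ".tfTrainStep")]]
double tfTrainStep(SEXP ptr, arma::imat src, arma::imat tgt_in,
                   arma::imat tgt_out, double lr) {
  Rcpp::XPtr<Model> m(ptr);
  check_ids(m, src); check_ids(m, tgt_in); check_ids(m, tgt_out);
  int B = src.n_rows, Ts = src.n_cols, Tt = tgt_in.n_cols;
  m->training = true;
  for (Par *p : m->pars) p->zero_grad();
  umat smask = pad_mask(src);
  std::vector<EncLayer::Cache> ec;
  std::vector<DecLayer::Cache> dc;
  mat em1, em2;
  mat enc_out = m->enc_fwd(src, B, Ts, smask, ec, em1);
  mat hdec = m->dec_fwd(tgt_in, B, Tt, enc_out, Ts, smask, dc, em2);
  mat dh;
  double loss = m->loss_and_grad(hdec, tgt_out, B, Tt, dh, true);
  mat d_enc(size(enc_out), fill::zeros);
  m->dec_bwd(tgt_in, B, Tt, Ts, dc, dh, em2, d_enc);
  m->enc_bwd(src, B, Ts, ec, d_enc, em1);
  m->adam(lr);
  return loss;
}

// evaluation loss (no dropout, no update)
// [[Rcpp::export(name = ".tfEvalLoss")]]
double tfEvalLoss(SEXP ptr, arma::imat src, arma::imat tgt_in,
                  arma::imat tgt_out) {
  Rcpp::XPtr<Model> m(ptr);
  check_ids(m, src); check_ids(m, tgt_in); check_ids(m, tgt_out);
  int B = src.n_rows, Ts = src.n_cols, Tt = tgt_in.n_cols;
  m->training = false;
  umat smask = pad_mask(src);
  std::vector<EncLayer::Cache> ec;
  std::vector<DecLayer::Cache> dc;
  mat em1, em2;
  mat enc_out = m->enc_fwd(src, B, Ts, smask, ec, em1);
  mat hdec = m->dec_fwd(tgt_in, B, Tt, enc_out, Ts, smask, dc, em2);
  mat dh;
  return m->loss_and_grad(hdec, tgt_out, B, Tt, dh, false);
}

// numerical gradient check hook: loss at current params for fixed batch
// [[Rcpp::export(name = ".tfLossNoDropout")]]
double tfLossNoDropout(SEXP ptr, arma::imat src, arma::imat tgt_in,
                       arma::imat tgt_out) {
  return tfEvalLoss(ptr, src, tgt_in, tgt_out);
}

// analytic gradients for a batch without updating (for the check)
// [[Rcpp::export(name = ".tfGradients")]]
Rcpp::List tfGradients(SEXP ptr, arma::imat src, arma::imat tgt_in,
                       arma::imat tgt_out) {
  Rcpp::XPtr<Model> m(ptr);
  int B = src.n_rows, Ts = src.n_cols, Tt = tgt_in.n_cols;
  m->training = false;  // deterministic: no dropout in the check
  for (Par *p : m->pars) p->zero_grad();
  umat smask = pad_mask(src);
  std::vector<EncLayer::Cache> ec;
  std::vector<DecLayer::Cache> dc;
  mat em1, em2;
  mat enc_out = m->enc_fwd(src, B, Ts, smask, ec, em1);
  mat hdec = m->dec_fwd(tgt_in, B, Tt, enc_out, Ts, smask, dc, em2);
  mat dh;
  double loss = m->loss_and_grad(hdec, tgt_out, B, Tt, dh, true);
  mat d_enc(size(enc_out), fill::zeros);
  m->dec_bwd(tgt_in, B, Tt, Ts, dc, dh, em2, d_enc);
  m->enc_bwd(src, B, Ts, ec, d_enc, em1);
  Rcpp::List out(m->pars.size());
  for (size_t i = 0; i < m->pars.size(); ++i)
    out[i] = Rcpp::wrap(m->pars[i]->g);
  out.attr("loss") = loss;
  return out;
}

// [[Rcpp::export(name = ".tfGetParams")]]
Rcpp::List tfGetParams(SEXP ptr) {
  Rcpp::XPtr<Model> m(ptr);
  Rcpp::List out(m->pars.size());
  for (size_t i = 0; i < m->pars.size(); ++i)
    out[i] = Rcpp::wrap(m->pars[i]->w);
  return out;
}

// [[Rcpp::export(name = ".tfSetParams")]]
void tfSetParams(SEXP ptr, Rcpp::List params) {
  Rcpp::XPtr<Model> m(ptr);
  if ((size_t)params.size() != m->pars.size())
    Rcpp::stop("parameter list does not match the model architecture");
  for (size_t i = 0; i < m->pars.size(); ++i) {
    mat w = Rcpp::as<mat>(params[i]);
    if (w.n_rows != m->pars[i]->w.n_rows ||
        w.n_cols != m->pars[i]->w.n_cols)
      Rcpp::stop("parameter shape mismatch");
    m->pars[i]->w = w;
  }
}

// perturb one scalar parameter (for finite-difference checks)
// [[Rcpp::export(name = ".tfNudgeParam")]]
void tfNudgeParam(SEXP ptr, int par_idx, int elem_idx, double delta) {
  Rcpp::XPtr<Model> m(ptr);
  m->pars[par_idx]->w(elem_idx) += delta;
}

// LayerNorm on plain rows (no cache) for incremental decoding
static mat ln_rows(LNorm &l, const mat &X) {
  vec mu = mean(X, 1);
  mat cen = X.each_col() - mu;
  vec invstd = 1.0 / sqrt(mean(square(cen), 1) + 1e-6);
  mat xhat = cen.each_col() % invstd;
  mat Y = xhat.each_row() % l.gmm.w;
  return Y.each_row() + l.bta.w;
}

// autoregressive decoding with per-layer key/value caching; each row of
// src is decoded independently. greedy = false draws each next token
// from the full output distribution (multinomial); returns sampled ids,
// 0-filled after <end>.
// [[Rcpp::export(name = ".tfSample")]]
arma::imat tfSample(SEXP ptr, arma::imat src, int max_len, int start_id,
                    int end_id, int seed, bool greedy) {
  Rcpp::XPtr<Model> m(ptr);
  check_ids(m, src);
  if (max_len > m->maxT) Rcpp::stop("max_len exceeds model maximum length");
  int B = src.n_rows, Ts = src.n_cols, D = m->D, H = m->H, dh = m->dh_of();
  m->training = false;
  umat smask = pad_mask(src);
  std::vector<EncLayer::Cache> ec;
  mat em1;
  mat enc_out = m->enc_fwd(src, B, Ts, smask, ec, em1);
  double scale = 1.0 / std::sqrt((double)dh);
  // precompute cross-attention keys/values per layer
  std::vector<mat> crossK(m->L), crossV(m->L);
  for (int l = 0; l < m->L; ++l) {
    crossK[l] = m->dec[l].cross.lk.fwd(enc_out);
    crossV[l] = m->dec[l].cross.lv.fwd(enc_out);
  }
  // growing self-attention caches: rows b*max_len + t
  std::vector<mat> selfK(m->L), selfV(m->L);
  for (int l = 0; l < m->L; ++l) {
    selfK[l].zeros(B * max_len, D);
    selfV[l].zeros(B * max_len, D);
  }
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  imat out(B, max_len, fill::zeros);
  std::vector<bool> done(B, false);
  ivec cur(B);
  cur.fill(start_id);
  double es = std::sqrt((double)D);
  for (int t = 0; t < max_len; ++t) {
    mat x(B, D);
    for (int b = 0; b < B; ++b)
      x.row(b) = m->emb.w.row(cur(b)) * es + m->pe.row(t);
    for (int l = 0; l < m->L; ++l) {
      DecLayer &d2 = m->dec[l];
      // masked self-attention over the cached prefix
      mat n1 = ln_rows(d2.ln1, x);
      mat q = d2.self_att.lq.fwd(n1);
      mat k = d2.self_att.lk.fwd(n1);
      mat v = d2.self_att.lv.fwd(n1);
      mat ctx(B, D);
      for (int b = 0; b < B; ++b) {
        selfK[l].row(b * max_len + t) = k.row(b);
        selfV[l].row(b * max_len + t) = v.row(b);
        for (int h = 0; h < H; ++h) {
          rowvec qh = q.row(b).cols(h * dh, h * dh + dh - 1);
          mat Kh = selfK[l].submat(b * max_len, h * dh,
                                   b * max_len + t, h * dh + dh - 1);
          mat Vh = selfV[l].submat(b * max_len, h * dh,
                                   b * max_len + t, h * dh + dh - 1);
          rowvec s = qh * Kh.t() * scale;
          s -= s.max();
          rowvec p = exp(s);
          p /= accu(p);
          ctx.row(b).cols(h * dh, h * dh + dh - 1) = p * Vh;
        }
      }
      x += d2.self_att.lo.fwd(ctx);
      // cross-attention onto the encoder output
      mat n2 = ln_rows(d2.ln2, x);
      mat q2 = d2.cross.lq.fwd(n2);
      mat ctx2(B, D);
      for (int b = 0; b < B; ++b) {
        for (int h = 0; h < H; ++h) {
          rowvec qh = q2.row(b).cols(h * dh, h * dh + dh - 1);
          mat Kh = crossK[l].submat(b * Ts, h * dh, b * Ts + Ts - 1,
                                    h * dh + dh - 1);
          mat Vh = crossV[l].submat(b * Ts, h * dh, b * Ts + Ts - 1,
                                    h * dh + dh - 1);
          rowvec s = qh * Kh.t() * scale;
          for (int tk = 0; tk < Ts; ++tk)
            if (smask(b, tk) == 0) s(tk) = NEG_INF;
          s -= s.max();
          rowvec p = exp(s);
          p /= accu(p);
          ctx2.row(b).cols(h * dh, h * dh + dh - 1) = p * Vh;
        }
      }
      x += d2.cross.lo.fwd(ctx2);
      // feed-forward
      mat n3 = ln_rows(d2.ln3, x);
      mat hft = d2.ff.l1.fwd(n3);
      hft.transform([](double z) { return z > 0 ? z : 0.0; });
      x += d2.ff.l2.fwd(hft);
    }
    mat hfin = ln_rows(m->ln_dec, x);
    for (int b = 0; b < B; ++b) {
      if (done[b]) { cur(b) = 0; continue; }
      rowvec z = (hfin.row(b) * m->out.W.w) + m->out.b.w;
      double mx = z.max();
      rowvec p = exp(z - mx);
      p /= accu(p);
      int pick;
      if (greedy) {
        pick = (int)p.index_max();
      } else {
        double u = U(rng), acc = 0;
        pick = m->V - 1;
        for (int kk = 0; kk < m->V; ++kk) {
          acc += p(kk);
          if (u <= acc) { pick = kk; break; }
        }
      }
      out(b, t) = pick;
      cur(b) = pick;
      if (pick == end_id) done[b] = true;
    }
    bool all_done = true;
    for (int b = 0; b < B; ++b) if (!done[b]) all_done = false;
    if (all_done) break;
  }
  return out;
}

// does an external pointer still hold a live model?
// [[Rcpp::export(name = ".tfAlive")]]
bool tfAlive(SEXP ptr) {
  return TYPEOF(ptr) == EXTPTRSXP && R_ExternalPtrAddr(ptr) != NULL;
}

// number of parameter matrices (for tests)
// [[Rcpp::export(name = ".tfParamCount")]]
int tfParamCount(SEXP ptr) {
  Rcpp::XPtr<Model> m(ptr);
  return (int)m->pars.size();
}
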