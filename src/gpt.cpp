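// Decoder-only transformer over discrete state tokens, written from scratch:
// token embedding + fixed sinusoidal positional encoding, pre-norm residual
// blocks of masked multi-head self-attention and GELU feed-forward layers,
// cross-entropy loss with analytic backprop, and autoregressive multinomial
// generation with a sliding context window.  The attention-ablated variant
// drops the attention sublayer only, leaving the position-wise path intact.
// Sampling and any stochastic choice use R's RNG (reproducible via set.seed).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::uword;

struct GPTCfg {
  int V, d, H, nb, Tmax;
  bool attn;
  double scale;     // per-head scaling width: d/H (default) or d (literal-Eq reading)
  double dropout;
};

static GPTCfg read_cfg(const List& cfg) {
  GPTCfg c;
  c.V = as<int>(cfg["vocab_size"]);
  c.d = as<int>(cfg["embed_dim"]);
  c.H = as<int>(cfg["n_heads"]);
  c.nb = as<int>(cfg["n_blocks"]);
  c.Tmax = as<int>(cfg["block_size"]);
  c.attn = as<bool>(cfg["attention_enabled"]);
  bool per_head = as<bool>(cfg["scale_per_head"]);
  c.scale = per_head ? (double)c.d / c.H : (double)c.d;
  c.dropout = cfg.containsElementNamed("dropout") ? as<double>(cfg["dropout"]) : 0.0;
  return c;
}

struct BlockW {
  mat ln1_g, ln1_b, wqkv, bqkv, wo, bo;
  mat ln2_g, ln2_b, w1, b1, w2, b2;
};

struct Weights {
  mat wte, pe, lnf_g, lnf_b, head_w, head_b;
  std::vector<BlockW> blocks;
};

static mat getm(const List& p, const std::string& nm) {
  if (!p.containsElementNamed(nm.c_str()))
    stop("missing parameter matrix '%s'", nm.c_str());
  return as<mat>(p[nm]);
}

static Weights read_weights(const List& p, const GPTCfg& c) {
  Weights w;
  w.wte = getm(p, "wte");
  w.pe = getm(p, "pe");
  w.lnf_g = getm(p, "lnf_g"); w.lnf_b = getm(p, "lnf_b");
  w.head_w = getm(p, "head_w"); w.head_b = getm(p, "head_b");
  w.blocks.resize(c.nb);
  for (int b = 0; b < c.nb; ++b) {
    std::string pre = "b" + std::to_string(b) + "_";
    BlockW& bw = w.blocks[b];
    if (c.attn) {
      bw.ln1_g = getm(p, pre + "ln1_g"); bw.ln1_b = getm(p, pre + "ln1_b");
      bw.wqkv = getm(p, pre + "attn_wqkv"); bw.bqkv = getm(p, pre + "attn_bqkv");
      bw.wo = getm(p, pre + "attn_wo"); bw.bo = getm(p, pre + "attn_bo");
    }
    bw.ln2_g = getm(p, pre + "ln2_g"); bw.ln2_b = getm(p, pre + "ln2_b");
    bw.w1 = getm(p, pre + "ff_w1"); bw.b1 = getm(p, pre + "ff_b1");
    bw.w2 = getm(p, pre + "ff_w2"); bw.b2 = getm(p, pre + "ff_b2");
  }
  return w;
}

static const double LN_EPS = 1e-5;

// layer norm over rows; caches xhat and inv-std for backward
static mat ln_fwd(const mat& x, const mat& g, const mat& b, mat& xhat,
                  arma::vec& istd) {
  arma::vec mu = arma::mean(x, 1);
  mat xc = x.each_col() - mu;
  arma::vec var = arma::mean(arma::square(xc), 1);
  istd = 1.0 / arma::sqrt(var + LN_EPS);
  xhat = xc.each_col() % istd;
  mat y = xhat.each_row() % g;
  y.each_row() += b;
  return y;
}

static mat ln_bwd(const mat& dy, const mat& g, const mat& xhat,
                  const arma::vec& istd, mat& dg, mat& db) {
  dg += arma::sum(dy % xhat, 0);
  db += arma::sum(dy, 0);
  mat dxh = dy.each_row() % g;
  arma::vec m1 = arma::mean(dxh, 1);
  arma::vec m2 = arma::mean(dxh % xhat, 1);
  mat dx = dxh;
  dx.each_col() -= m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() %= istd;
  return dx;
}

static mat gelu(const mat& x) { return x % arma::normcdf(x); }
static mat gelu_grad(const mat& x) {
  return arma::normcdf(x) + x % arma::normpdf(x);
}

struct BlockCache {
  mat x_in, ln1_xhat, xn, qkv, attn_o, x_mid, ln2_xhat, xn2, hpre, hact;
  arma::vec ln1_istd, ln2_istd;
  arma::cube P;          // post-softmax attention weights, per head
  mat drop1, drop2;      // dropout masks (empty when dropout = 0)
};

struct FwdCache {
  mat x0;
  std::vector<BlockCache> blocks;
  mat lnf_xhat, xf, logits;
  arma::vec lnf_istd;
};

// next-token distribution at the last position only: identical numbers to
// the full forward pass, but the final block's attention/feed-forward and
// the head are evaluated for the last row alone, since generation never
// consumes the other rows of the last block.
static arma::rowvec gpt_last_probs(const arma::ivec& tok, const Weights& w,
                                   const GPTCfg& c) {
  const int T = tok.n_elem;
  if (T > c.Tmax) stop("window longer than block_size");
  const int dh = c.d / c.H;
  const double sc = std::sqrt(c.scale);
  mat x(T, c.d);
  for (int t = 0; t < T; ++t) {
    if (tok[t] < 0 || tok[t] >= c.V) stop("token out of vocabulary");
    x.row(t) = w.wte.row(tok[t]) + w.pe.row(t);
  }
  mat xhat; arma::vec istd;
  for (int b = 0; b < c.nb; ++b) {
    const BlockW& bw = w.blocks[b];
    const bool last = (b == c.nb - 1);
    if (c.attn) {
      mat xn = ln_fwd(x, bw.ln1_g, bw.ln1_b, xhat, istd);
      mat qkv = xn * bw.wqkv;
      qkv.each_row() += bw.bqkv;
      if (!last) {
        mat neg(T, T, arma::fill::zeros);
        for (int i = 0; i < T; ++i)
          for (int j = i + 1; j < T; ++j) neg(i, j) = -arma::datum::inf;
        mat O(T, c.d);
        for (int h = 0; h < c.H; ++h) {
          mat Q = qkv.cols(h * dh, (h + 1) * dh - 1);
          mat K = qkv.cols(c.d + h * dh, c.d + (h + 1) * dh - 1);
          mat Vv = qkv.cols(2 * c.d + h * dh, 2 * c.d + (h + 1) * dh - 1);
          mat S = (Q * K.t()) / sc + neg;
          S.each_col() -= arma::max(S, 1);
          mat P = arma::exp(S);
          P.each_col() /= arma::sum(P, 1);
          O.cols(h * dh, (h + 1) * dh - 1) = P * Vv;
        }
        mat a = O * bw.wo;
        a.each_row() += bw.bo;
        x = x + a;
      } else {
        arma::rowvec o(c.d);
        for (int h = 0; h < c.H; ++h) {
          arma::rowvec q = qkv.submat(T - 1, h * dh, T - 1, (h + 1) * dh - 1);
          mat K = qkv.cols(c.d + h * dh, c.d + (h + 1) * dh - 1);
          mat Vv = qkv.cols(2 * c.d + h * dh, 2 * c.d + (h + 1) * dh - 1);
          arma::rowvec s = (q * K.t()) / sc;   // last row attends everywhere
          s -= s.max();
          arma::rowvec p = arma::exp(s);
          p /= arma::accu(p);
          o.cols(h * dh, (h + 1) * dh - 1) = p * Vv;
        }
        mat xl = x.tail_rows(1);
        x = xl + o * bw.wo + bw.bo;
      }
    } else if (last) {
      x = mat(x.tail_rows(1));
    }
    // feed-forward (on the single remaining row once in the last block)
    mat xn2 = ln_fwd(x, bw.ln2_g, bw.ln2_b, xhat, istd);
    mat hpre = xn2 * bw.w1;
    hpre.each_row() += bw.b1;
    mat f = gelu(hpre) * bw.w2;
    f.each_row() += bw.b2;
    x = x + f;
  }
  mat xf = ln_fwd(x.tail_rows(1), w.lnf_g, w.lnf_b, xhat, istd);
  arma::rowvec z = xf * w.head_w + w.head_b;
  z -= z.max();
  arma::rowvec p = arma::exp(z);
  return p / arma::accu(p);
}

// forward pass for one token window; optionally collects raw (pre-softmax,
// masked) attention scores averaged over heads per block
static mat gpt_fwd(const arma::ivec& tok, const Weights& w, const GPTCfg& c,
                   FwdCache* cache, bool training,
                   std::vector<mat>* raw_scores = nullptr) {
  const int T = tok.n_elem;
  if (T > c.Tmax) stop("window longer than block_size");
  const int dh = c.d / c.H;
  mat x(T, c.d);
  for (int t = 0; t < T; ++t) {
    if (tok[t] < 0 || tok[t] >= c.V) stop("token out of vocabulary");
    x.row(t) = w.wte.row(tok[t]) + w.pe.row(t);
  }
  if (cache) { cache->x0 = x; cache->blocks.resize(c.nb); }
  const double sc = std::sqrt(c.scale);
  for (int b = 0; b < c.nb; ++b) {
    const BlockW& bw = w.blocks[b];
    BlockCache local;
    BlockCache& bc = cache ? cache->blocks[b] : local;
    if (c.attn) {
      bc.x_in = x;
      bc.xn = ln_fwd(x, bw.ln1_g, bw.ln1_b, bc.ln1_xhat, bc.ln1_istd);
      bc.qkv = bc.xn * bw.wqkv;
      bc.qkv.each_row() += bw.bqkv;
      bc.P.set_size(T, T, c.H);
      mat O(T, c.d);
      mat raw;
      if (raw_scores) raw.zeros(T, T);
      // additive causal mask: 0 on/below the diagonal, -inf above
      mat neg(T, T, arma::fill::zeros);
      for (int i = 0; i < T; ++i)
        for (int j = i + 1; j < T; ++j) neg(i, j) = -arma::datum::inf;
      for (int h = 0; h < c.H; ++h) {
        mat Q = bc.qkv.cols(h * dh, (h + 1) * dh - 1);
        mat K = bc.qkv.cols(c.d + h * dh, c.d + (h + 1) * dh - 1);
        mat Vv = bc.qkv.cols(2 * c.d + h * dh, 2 * c.d + (h + 1) * dh - 1);
        mat S = (Q * K.t()) / sc;
        if (raw_scores) raw += arma::trimatl(S);
        S += neg;
        // row softmax over the causal support, vectorized
        S.each_col() -= arma::max(S, 1);
        mat P = arma::exp(S);
        P.each_col() /= arma::sum(P, 1);
        bc.P.slice(h) = P;
        O.cols(h * dh, (h + 1) * dh - 1) = P * Vv;
      }
      if (raw_scores) raw_scores->push_back(raw / c.H);
      bc.attn_o = O;
      mat a = O * bw.wo;
      a.each_row() += bw.bo;
      if (training && c.dropout > 0) {
        bc.drop1.set_size(T, c.d);
        for (uword i = 0; i < bc.drop1.n_elem; ++i)
          bc.drop1(i) = (unif_rand() < c.dropout) ? 0.0 : 1.0 / (1.0 - c.dropout);
        a %= bc.drop1;
      }
      x = x + a;
    }
    bc.x_mid = x;
    bc.xn2 = ln_fwd(x, bw.ln2_g, bw.ln2_b, bc.ln2_xhat, bc.ln2_istd);
    bc.hpre = bc.xn2 * bw.w1;
    bc.hpre.each_row() += bw.b1;
    bc.hact = gelu(bc.hpre);
    mat f = bc.hact * bw.w2;
    f.each_row() += bw.b2;
    if (training && c.dropout > 0) {
      bc.drop2.set_size(T, c.d);
      for (uword i = 0; i < bc.drop2.n_elem; ++i)
        bc.drop2(i) = (unif_rand() < c.dropout) ? 0.0 : 1.0 / (1.0 - c.dropout);
      f %= bc.drop2;
    }
    x = x + f;
  }
  mat xhat; arma::vec istd;
  mat xf = ln_fwd(x, w.lnf_g, w.lnf_b, xhat, istd);
  mat logits = xf * w.head_w;
  logits.each_row() += w.head_b;
  if (cache) {
    cache->lnf_xhat = xhat; cache->lnf_istd = istd;
    cache->xf = xf; cache->logits = logits;
  }
  return logits;
}

static mat softmax_rows(const mat& z) {
  mat p = z.each_col() - arma::max(z, 1);
  p = arma::exp(p);
  p.each_col() /= arma::sum(p, 1);
  return p;
}

struct Grads {
  mat wte, lnf_g, lnf_b, head_w, head_b;
  std::vector<BlockW> blocks;
  void init(const Weights& w) {
    wte.zeros(arma::size(w.wte));
    lnf_g.zeros(arma::size(w.lnf_g)); lnf_b.zeros(arma::size(w.lnf_b));
    head_w.zeros(arma::size(w.head_w)); head_b.zeros(arma::size(w.head_b));
    blocks.resize(w.blocks.size());
    for (size_t b = 0; b < w.blocks.size(); ++b) {
      const BlockW& s = w.blocks[b]; BlockW& g = blocks[b];
      if (s.wqkv.n_elem) {
        g.ln1_g.zeros(arma::size(s.ln1_g)); g.ln1_b.zeros(arma::size(s.ln1_b));
        g.wqkv.zeros(arma::size(s.wqkv)); g.bqkv.zeros(arma::size(s.bqkv));
        g.wo.zeros(arma::size(s.wo)); g.bo.zeros(arma::size(s.bo));
      }
      g.ln2_g.zeros(arma::size(s.ln2_g)); g.ln2_b.zeros(arma::size(s.ln2_b));
      g.w1.zeros(arma::size(s.w1)); g.b1.zeros(arma::size(s.b1));
      g.w2.zeros(arma::size(s.w2)); g.b2.zeros(arma::size(s.b2));
    }
  }
};

static void gpt_bwd(const arma::ivec& tok, const mat& dlogits,
                    const Weights& w, const GPTCfg& c, const FwdCache& cc,
                    Grads& g) {
  const int T = tok.n_elem;
  const int dh = c.d / c.H;
  const double sc = std::sqrt(c.scale);
  g.head_w += cc.xf.t() * dlogits;
  g.head_b += arma::sum(dlogits, 0);
  mat dxf = dlogits * w.head_w.t();
  mat dx = ln_bwd(dxf, w.lnf_g, cc.lnf_xhat, cc.lnf_istd, g.lnf_g, g.lnf_b);
  for (int b = c.nb - 1; b >= 0; --b) {
    const BlockW& bw = w.blocks[b];
    const BlockCache& bc = cc.blocks[b];
    BlockW& gb = g.blocks[b];
    // feed-forward sublayer
    mat df = dx;                       // grad of the FF branch output
    if (bc.drop2.n_elem) df %= bc.drop2;
    gb.w2 += bc.hact.t() * df;
    gb.b2 += arma::sum(df, 0);
    mat dhact = df * bw.w2.t();
    mat dhpre = dhact % gelu_grad(bc.hpre);
    gb.w1 += bc.xn2.t() * dhpre;
    gb.b1 += arma::sum(dhpre, 0);
    mat dxn2 = dhpre * bw.w1.t();
    mat dmid = dx + ln_bwd(dxn2, bw.ln2_g, bc.ln2_xhat, bc.ln2_istd,
                           gb.ln2_g, gb.ln2_b);
    if (c.attn) {
      mat da = dmid;                   // grad of the attention branch output
      if (bc.drop1.n_elem) da %= bc.drop1;
      gb.wo += bc.attn_o.t() * da;
      gb.bo += arma::sum(da, 0);
      mat dO = da * bw.wo.t();
      mat dqkv(T, 3 * c.d, arma::fill::zeros);
      for (int h = 0; h < c.H; ++h) {
        mat Q = bc.qkv.cols(h * dh, (h + 1) * dh - 1);
        mat K = bc.qkv.cols(c.d + h * dh, c.d + (h + 1) * dh - 1);
        mat Vv = bc.qkv.cols(2 * c.d + h * dh, 2 * c.d + (h + 1) * dh - 1);
        const mat& P = bc.P.slice(h);
        mat dOh = dO.cols(h * dh, (h + 1) * dh - 1);
        mat dP = dOh * Vv.t();
        mat dVv = P.t() * dOh;
        arma::vec rs = arma::sum(dP % P, 1);
        mat dS = P % (dP.each_col() - rs);
        dqkv.cols(h * dh, (h + 1) * dh - 1) += (dS * K) / sc;
        dqkv.cols(c.d + h * dh, c.d + (h + 1) * dh - 1) += (dS.t() * Q) / sc;
        dqkv.cols(2 * c.d + h * dh, 2 * c.d + (h + 1) * dh - 1) += dVv;
      }
      gb.wqkv += bc.xn.t() * dqkv;
      gb.bqkv += arma::sum(dqkv, 0);
      mat dxn = dqkv * bw.wqkv.t();
      dx = dmid + ln_bwd(dxn, bw.ln1_g, bc.ln1_xhat, bc.ln1_istd,
                         gb.ln1_g, gb.ln1_b);
    } else {
      dx = dmid;
    }
  }
  for (int t = 0; t < T; ++t) g.wte.row(tok[t]) += dx.row(t);
}

// [[Rcpp::export]]
List gpt_loss_grad_cpp(const List& params, const List& cfg,
                       const arma::imat& X, const arma::imat& Y) {
  GPTCfg c = read_cfg(cfg);
  Weights w = read_weights(params, c);
  const int B = X.n_rows, T = X.n_cols;
  Grads g;
  g.init(w);
  double loss = 0.0;
  const double inv = 1.0 / (double)(B * T);
  for (int s = 0; s < B; ++s) {
    arma::ivec tok = X.row(s).t();
    arma::ivec tgt = Y.row(s).t();
    FwdCache cc;
    gpt_fwd(tok, w, c, &cc, true);
    mat P = softmax_rows(cc.logits);
    mat dlogits = P;
    for (int t = 0; t < T; ++t) {
      loss -= std::log(std::max(P(t, tgt[t]), 1e-300)) * inv;
      dlogits(t, tgt[t]) -= 1.0;
    }
    dlogits *= inv;
    gpt_bwd(tok, dlogits, w, c, cc, g);
  }
  if (!std::isfinite(loss)) stop("training diverged: non-finite loss");
  List out;
  out["loss"] = loss;
  List gl;
  gl["wte"] = g.wte;
  gl["lnf_g"] = g.lnf_g; gl["lnf_b"] = g.lnf_b;
  gl["head_w"] = g.head_w; gl["head_b"] = g.head_b;
  for (int b = 0; b < c.nb; ++b) {
    std::string pre = "b" + std::to_string(b) + "_";
    BlockW& gb = g.blocks[b];
    if (c.attn) {
      gl[pre + "ln1_g"] = gb.ln1_g; gl[pre + "ln1_b"] = gb.ln1_b;
      gl[pre + "attn_wqkv"] = gb.wqkv; gl[pre + "attn_bqkv"] = gb.bqkv;
      gl[pre + "attn_wo"] = gb.wo; gl[pre + "attn_bo"] = gb.bo;
    }
    gl[pre + "ln2_g"] = gb.ln2_g; gl[pre + "ln2_b"] = gb.ln2_b;
    gl[pre + "ff_w1"] = gb.w1; gl[pre + "ff_b1"] = gb.b1;
    gl[pre + "ff_w2"] = gb.w2; gl[pre + "ff_b2"] = gb.b2;
  }
  out["grads"] = gl;
  return out;
}

// [[Rcpp::export]]
double gpt_loss_cpp(const List& params, const List& cfg, const arma::imat& X,
                    const arma::imat& Y) {
  GPTCfg c = read_cfg(cfg);
  Weights w = read_weights(params, c);
  const int B = X.n_rows, T = X.n_cols;
  double loss = 0.0;
  const double inv = 1.0 / (double)(B * T);
  for (int s = 0; s < B; ++s) {
    arma::ivec tok = X.row(s).t();
    mat logits = gpt_fwd(tok, w, c, nullptr, false);
    mat P = softmax_rows(logits);
    for (int t = 0; t < T; ++t)
      loss -= std::log(std::max(P(t, Y(s, t)), 1e-300)) * inv;
  }
  return loss;
}

// [[Rcpp::export]]
arma::mat gpt_probs_cpp(const List& params, const List& cfg,
                        const arma::ivec& tokens) {
  GPTCfg c = read_cfg(cfg);
  Weights w = read_weights(params, c);
  mat logits = gpt_fwd(tokens, w, c, nullptr, false);
  return softmax_rows(logits);
}

// [[Rcpp::export]]
arma::rowvec gpt_last_probs_cpp(const List& params, const List& cfg,
                                const arma::ivec& tokens) {
  GPTCfg c = read_cfg(cfg);
  Weights w = read_weights(params, c);
  return gpt_last_probs(tokens, w, c);
}

// [[Rcpp::export]]
arma::ivec gpt_generate_cpp(const List& params, const List& cfg,
                            const arma::ivec& prompt, int n_tokens,
                            double temperature) {
  GPTCfg c = read_cfg(cfg);
  Weights w = read_weights(params, c);
  std::vector<int> seq(prompt.begin(), prompt.end());
  arma::ivec out(n_tokens);
  for (int k = 0; k < n_tokens; ++k) {
    int start = std::max(0, (int)seq.size() - c.Tmax);
    arma::ivec win((int)seq.size() - start);
    for (int i = 0; i < (int)win.n_elem; ++i) win[i] = seq[start + i];
    arma::rowvec p = gpt_last_probs(win, w, c);
    if (temperature != 1.0) {
      p = arma::pow(p, 1.0 / temperature);
      p /= arma::accu(p);
    }
    double u = unif_rand(), acc = 0.0;
    int pick = c.V - 1;
    for (int v = 0; v < c.V; ++v) {
      acc += p[v];
      if (u <= acc) { pick = v; break; }
    }
    seq.push_back(pick);
    out[k] = pick;
    if (k % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// post-softmax attention weights of one block, per head (for testing and
// introspection: rows sum to 1 over the causal prefix, zero above diagonal)
// [[Rcpp::export]]
arma::cube gpt_attn_weights_cpp(const List& params, const List& cfg,
                                const arma::ivec& tokens, int block) {
  GPTCfg c = read_cfg(cfg);
  if (!c.attn) stop("attention weights are unavailable for an attention-ablated model");
  if (block < 0 || block >= c.nb) stop("block out of range");
  Weights w = read_weights(params, c);
  FwdCache cc;
  gpt_fwd(tokens, w, c, &cc, false);
  return cc.blocks[block].P;
}

// [[Rcpp::export]]
List gpt_attention_cpp(const List& params, const List& cfg,
                       const arma::ivec& tokens) {
  GPTCfg c = read_cfg(cfg);
  if (!c.attn) stop("attention scores are unavailable for an attention-ablated model");
  Weights w = read_weights(params, c);
  std::vector<mat> raw;
  gpt_fwd(tokens, w, c, nullptr, false, &raw);
  List out(raw.size());
  for (size_t i = 0; i < raw.size(); ++i) out[i] = raw[i];
  return out;
}
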