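// Numeric core of the bi-LSTM-CRF tagger: forward pass, analytic
// back-propagation, CRF forward-backward, Viterbi decoding and the
// per-sentence SGD epoch loop.
//
// The LSTM cell is the coupled-gate, full-matrix-peephole variant:
//   i_t = sigma(Wxi x_t + Whi h_{t-1} + Wci c_{t-1} + b_i)
//   c_t = (1 - i_t) . c_{t-1} + i_t . tanh(Wxc x_t + Whc h_{t-1} + b_c)
//   o_t = sigma(Wxo x_t + Who h_{t-1} + Wco c_t + b_o)
//   h_t = o_t . tanh(c_t)
// There is no separate forget gate; the output gate peeps at the *current*
// cell state, so its gradient flows back into c_t through Wco.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct CellP {
  arma::mat Wxi, Whi, Wci, Wxc, Whc, Wxo, Who, Wco;
  arma::vec bi, bc, bo;
};

struct ModelP {
  arma::mat tok_emb, char_emb;
  CellP cf, cb, tf, tb;       // char fwd/bwd, token fwd/bwd
  arma::mat projW;
  arma::vec projB;
  arma::mat trans;
  arma::vec start_v, end_v;
};

static CellP cell_from_list(List p) {
  CellP c;
  c.Wxi = as<arma::mat>(p["W_xi"]);
  c.Whi = as<arma::mat>(p["W_hi"]);
  c.Wci = as<arma::mat>(p["W_ci"]);
  c.bi  = as<arma::vec>(p["b_i"]);
  c.Wxc = as<arma::mat>(p["W_xc"]);
  c.Whc = as<arma::mat>(p["W_hc"]);
  c.bc  = as<arma::vec>(p["b_c"]);
  c.Wxo = as<arma::mat>(p["W_xo"]);
  c.Who = as<arma::mat>(p["W_ho"]);
  c.Wco = as<arma::mat>(p["W_co"]);
  c.bo  = as<arma::vec>(p["b_o"]);
  return c;
}

static List cell_to_list(const CellP& c) {
  return List::create(
    _["W_xi"] = c.Wxi, _["W_hi"] = c.Whi, _["W_ci"] = c.Wci,
    _["b_i"] = NumericVector(c.bi.begin(), c.bi.end()),
    _["W_xc"] = c.Wxc, _["W_hc"] = c.Whc,
    _["b_c"] = NumericVector(c.bc.begin(), c.bc.end()),
    _["W_xo"] = c.Wxo, _["W_ho"] = c.Who, _["W_co"] = c.Wco,
    _["b_o"] = NumericVector(c.bo.begin(), c.bo.end()));
}

static ModelP model_from_list(List P) {
  ModelP m;
  m.tok_emb  = as<arma::mat>(P["token_embedding"]);
  m.char_emb = as<arma::mat>(P["char_embedding"]);
  m.cf = cell_from_list(P["char_lstm_fwd"]);
  m.cb = cell_from_list(P["char_lstm_bwd"]);
  m.tf = cell_from_list(P["token_lstm_fwd"]);
  m.tb = cell_from_list(P["token_lstm_bwd"]);
  m.projW   = as<arma::mat>(P["projection_W"]);
  m.projB   = as<arma::vec>(P["projection_b"]);
  m.trans   = as<arma::mat>(P["crf_transitions"]);
  m.start_v = as<arma::vec>(P["crf_start"]);
  m.end_v   = as<arma::vec>(P["crf_end"]);
  return m;
}

static List model_to_list(const ModelP& m) {
  return List::create(
    _["token_embedding"] = m.tok_emb,
    _["char_embedding"] = m.char_emb,
    _["char_lstm_fwd"] = cell_to_list(m.cf),
    _["char_lstm_bwd"] = cell_to_list(m.cb),
    _["token_lstm_fwd"] = cell_to_list(m.tf),
    _["token_lstm_bwd"] = cell_to_list(m.tb),
    _["projection_W"] = m.projW,
    _["projection_b"] = NumericVector(m.projB.begin(), m.projB.end()),
    _["crf_transitions"] = m.trans,
    _["crf_start"] = NumericVector(m.start_v.begin(), m.start_v.end()),
    _["crf_end"] = NumericVector(m.end_v.begin(), m.end_v.end()));
}

// ---------------------------------------------------------------- LSTM runs

struct LSTMCache {
  arma::mat X;            // D x T inputs
  arma::mat H, C;         // Hn x (T+1), column 0 is the zero initial state
  arma::mat I, G, O, TC;  // Hn x T gate activations
};

static void lstm_forward(const CellP& p, const arma::mat& X, LSTMCache& cc) {
  const int T = X.n_cols;
  const int Hn = p.bi.n_elem;
  cc.X = X;
  cc.H.zeros(Hn, T + 1);
  cc.C.zeros(Hn, T + 1);
  cc.I.set_size(Hn, T); cc.G.set_size(Hn, T);
  cc.O.set_size(Hn, T); cc.TC.set_size(Hn, T);
  for (int t = 0; t < T; ++t) {
    arma::vec x = X.col(t), hp = cc.H.col(t), cp = cc.C.col(t);
    arma::vec i = 1.0 / (1.0 + arma::exp(-(p.Wxi * x + p.Whi * hp + p.Wci * cp + p.bi)));
    arma::vec g = arma::tanh(p.Wxc * x + p.Whc * hp + p.bc);
    arma::vec c = (1.0 - i) % cp + i % g;
    arma::vec o = 1.0 / (1.0 + arma::exp(-(p.Wxo * x + p.Who * hp + p.Wco * c + p.bo)));
    arma::vec tc = arma::tanh(c);
    cc.I.col(t) = i; cc.G.col(t) = g; cc.O.col(t) = o; cc.TC.col(t) = tc;
    cc.C.col(t + 1) = c;
    cc.H.col(t + 1) = o % tc;
  }
}

struct CellG {
  arma::mat Wxi, Whi, Wci, Wxc, Whc, Wxo, Who, Wco;
  arma::vec bi, bc, bo;
  void init(const CellP& p) {
    Wxi.zeros(arma::size(p.Wxi)); Whi.zeros(arma::size(p.Whi));
    Wci.zeros(arma::size(p.Wci)); Wxc.zeros(arma::size(p.Wxc));
    Whc.zeros(arma::size(p.Whc)); Wxo.zeros(arma::size(p.Wxo));
    Who.zeros(arma::size(p.Who)); Wco.zeros(arma::size(p.Wco));
    bi.zeros(arma::size(p.bi)); bc.zeros(arma::size(p.bc)); bo.zeros(arma::size(p.bo));
  }
  void zero() {
    Wxi.zeros(); Whi.zeros(); Wci.zeros(); Wxc.zeros(); Whc.zeros();
    Wxo.zeros(); Who.zeros(); Wco.zeros(); bi.zeros(); bc.zeros(); bo.zeros();
  }
};

// Back-propagate through one LSTM run. dH_ext holds the gradient arriving at
// each h_t from above; returns the gradient with respect to the inputs X and
// accumulates parameter gradients into g.
static arma::mat lstm_backward(const CellP& p, const LSTMCache& cc,
                               const arma::mat& dH_ext, CellG& g) {
  const int T = cc.X.n_cols;
  const int D = cc.X.n_rows;
  const int Hn = p.bi.n_elem;
  arma::mat dX(D, T, arma::fill::zeros);
  arma::vec dh_next(Hn, arma::fill::zeros), dc_next(Hn, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    arma::vec x = cc.X.col(t), hp = cc.H.col(t), cp = cc.C.col(t), ct = cc.C.col(t + 1);
    arma::vec i = cc.I.col(t), gg = cc.G.col(t), o = cc.O.col(t), tc = cc.TC.col(t);
    arma::vec dh = dH_ext.col(t) + dh_next;
    arma::vec dc = dc_next + dh % o % (1.0 - tc % tc);
    arma::vec dao = (dh % tc) % o % (1.0 - o);
    g.Wxo += dao * x.t(); g.Who += dao * hp.t(); g.Wco += dao * ct.t(); g.bo += dao;
    dc += p.Wco.t() * dao;  // output gate peeps at the current cell state
    arma::vec dai = (dc % (gg - cp)) % i % (1.0 - i);
    arma::vec dag = (dc % i) % (1.0 - gg % gg);
    g.Wxi += dai * x.t(); g.Whi += dai * hp.t(); g.Wci += dai * cp.t(); g.bi += dai;
    g.Wxc += dag * x.t(); g.Whc += dag * hp.t(); g.bc += dag;
    dX.col(t) = p.Wxi.t() * dai + p.Wxc.t() * dag + p.Wxo.t() * dao;
    dh_next = p.Whi.t() * dai + p.Whc.t() * dag + p.Who.t() * dao;
    dc_next = dc % (1.0 - i) + p.Wci.t() * dai;
  }
  return dX;
}

// ------------------------------------------------------------ sentence pass

struct SentCache {
  std::vector<LSTMCache> char_f, char_b;
  LSTMCache tok_f, tok_b;
  arma::mat E, Emask, Mask;  // E x T
  arma::mat H2;              // 2H x T
  arma::mat Emis;            // L x T
};

static void sentence_forward(const ModelP& m, const std::vector<int>& tok,
                             const std::vector<std::vector<int>>& chars,
                             const arma::mat& mask, SentCache& sc) {
  const int T = tok.size();
  const int dt = m.tok_emb.n_cols;
  const int dc = m.char_emb.n_cols;
  const int cH = m.cf.bi.n_elem;
  const int E = dt + 2 * cH;
  sc.char_f.resize(T); sc.char_b.resize(T);
  sc.E.set_size(E, T);
  for (int t = 0; t < T; ++t) {
    const int Lc = chars[t].size();
    arma::mat CX(dc, Lc);
    for (int j = 0; j < Lc; ++j) CX.col(j) = m.char_emb.row(chars[t][j] - 1).t();
    lstm_forward(m.cf, CX, sc.char_f[t]);
    arma::mat CXr = arma::fliplr(CX);
    lstm_forward(m.cb, CXr, sc.char_b[t]);
    sc.E.col(t).subvec(0, dt - 1) = m.tok_emb.row(tok[t] - 1).t();
    sc.E.col(t).subvec(dt, dt + cH - 1) = sc.char_f[t].H.col(Lc);
    sc.E.col(t).subvec(dt + cH, E - 1) = sc.char_b[t].H.col(Lc);
  }
  if (mask.n_elem > 0) {
    sc.Mask = mask;
    sc.Emask = sc.E % mask;
  } else {
    sc.Mask.reset();
    sc.Emask = sc.E;
  }
  lstm_forward(m.tf, sc.Emask, sc.tok_f);
  arma::mat Er = arma::fliplr(sc.Emask);
  lstm_forward(m.tb, Er, sc.tok_b);
  const int H = m.tf.bi.n_elem;
  sc.H2.set_size(2 * H, T);
  for (int t = 0; t < T; ++t) {
    sc.H2.col(t).subvec(0, H - 1) = sc.tok_f.H.col(t + 1);
    // position t of the original sequence is column T-1-t of the reversed
    // run, i.e. state column (T-1-t)+1 = T-t
    sc.H2.col(t).subvec(H, 2 * H - 1) = sc.tok_b.H.col(T - t);
  }
  sc.Emis = m.projW * sc.H2;
  sc.Emis.each_col() += m.projB;
}

// -------------------------------------------------------------------- CRF

static double logsumexp(const arma::vec& v) {
  double mx = v.max();
  return mx + std::log(arma::accu(arma::exp(v - mx)));
}

static double crf_alpha(const arma::mat& emis, const arma::mat& trans,
                        const arma::vec& sv, const arma::vec& ev, arma::mat& alpha) {
  const int L = emis.n_rows, T = emis.n_cols;
  alpha.set_size(L, T);
  alpha.col(0) = sv + emis.col(0);
  for (int t = 1; t < T; ++t)
    for (int b = 0; b < L; ++b)
      alpha(b, t) = logsumexp(alpha.col(t - 1) + trans.col(b)) + emis(b, t);
  return logsumexp(alpha.col(T - 1) + ev);
}

static arma::mat crf_beta_mat(const arma::mat& emis, const arma::mat& trans,
                              const arma::vec& ev) {
  const int L = emis.n_rows, T = emis.n_cols;
  arma::mat beta(L, T);
  beta.col(T - 1) = ev;
  for (int t = T - 2; t >= 0; --t)
    for (int a = 0; a < L; ++a)
      beta(a, t) = logsumexp(trans.row(a).t() + emis.col(t + 1) + beta.col(t + 1));
  return beta;
}

// ------------------------------------------------------------- full model

struct ModelG {
  arma::mat tok_emb, char_emb;
  CellG cf, cb, tf, tb;
  arma::mat projW;
  arma::vec projB;
  arma::mat trans;
  arma::vec start_v, end_v;
  void init(const ModelP& m) {
    tok_emb.zeros(arma::size(m.tok_emb));
    char_emb.zeros(arma::size(m.char_emb));
    cf.init(m.cf); cb.init(m.cb); tf.init(m.tf); tb.init(m.tb);
    projW.zeros(arma::size(m.projW));
    projB.zeros(arma::size(m.projB));
    trans.zeros(arma::size(m.trans));
    start_v.zeros(arma::size(m.start_v));
    end_v.zeros(arma::size(m.end_v));
  }
  void zero() {
    tok_emb.zeros(); char_emb.zeros();
    cf.zero(); cb.zero(); tf.zero(); tb.zero();
    projW.zeros(); projB.zeros(); trans.zeros(); start_v.zeros(); end_v.zeros();
  }
};

static void collect_cell(std::vector<arma::mat*>& ms, std::vector<arma::vec*>& vs, CellG& c) {
  ms.push_back(&c.Wxi); ms.push_back(&c.Whi); ms.push_back(&c.Wci);
  ms.push_back(&c.Wxc); ms.push_back(&c.Whc);
  ms.push_back(&c.Wxo); ms.push_back(&c.Who); ms.push_back(&c.Wco);
  vs.push_back(&c.bi); vs.push_back(&c.bc); vs.push_back(&c.bo);
}

static void collect_cell_p(std::vector<arma::mat*>& ms, std::vector<arma::vec*>& vs, CellP& c) {
  ms.push_back(&c.Wxi); ms.push_back(&c.Whi); ms.push_back(&c.Wci);
  ms.push_back(&c.Wxc); ms.push_back(&c.Whc);
  ms.push_back(&c.Wxo); ms.push_back(&c.Who); ms.push_back(&c.Wco);
  vs.push_back(&c.bi); vs.push_back(&c.bc); vs.push_back(&c.bo);
}

static void collect_grads(ModelG& g, std::vector<arma::mat*>& ms, std::vector<arma::vec*>& vs) {
  ms.push_back(&g.tok_emb); ms.push_back(&g.char_emb);
  collect_cell(ms, vs, g.cf); collect_cell(ms, vs, g.cb);
  collect_cell(ms, vs, g.tf); collect_cell(ms, vs, g.tb);
  ms.push_back(&g.projW); vs.push_back(&g.projB);
  ms.push_back(&g.trans); vs.push_back(&g.start_v); vs.push_back(&g.end_v);
}

static void collect_params(ModelP& m, std::vector<arma::mat*>& ms, std::vector<arma::vec*>& vs) {
  ms.push_back(&m.tok_emb); ms.push_back(&m.char_emb);
  collect_cell_p(ms, vs, m.cf); collect_cell_p(ms, vs, m.cb);
  collect_cell_p(ms, vs, m.tf); collect_cell_p(ms, vs, m.tb);
  ms.push_back(&m.projW); vs.push_back(&m.projB);
  ms.push_back(&m.trans); vs.push_back(&m.start_v); vs.push_back(&m.end_v);
}

// Loss and gradient of the CRF negative log-likelihood for one sentence.
// Labels are 0-based here.
static double sentence_loss_grad(const ModelP& m, const std::vector<int>& tok,
                                 const std::vector<std::vector<int>>& chars,
                                 const std::vector<int>& lab,
                                 const arma::mat& mask, ModelG& g, SentCache& sc) {
  sentence_forward(m, tok, chars, mask, sc);
  const int T = tok.size();
  const int L = m.projB.n_elem;
  arma::mat alpha;
  const double logZ = crf_alpha(sc.Emis, m.trans, m.start_v, m.end_v, alpha);
  arma::mat beta = crf_beta_mat(sc.Emis, m.trans, m.end_v);

  double gold = m.start_v(lab[0]) + m.end_v(lab[T - 1]);
  for (int t = 0; t < T; ++t) gold += sc.Emis(lab[t], t);
  for (int t = 1; t < T; ++t) gold += m.trans(lab[t - 1], lab[t]);
  const double loss = logZ - gold;

  arma::mat marg = arma::exp(alpha + beta - logZ);  // unary marginals, L x T
  arma::mat dE = marg;
  for (int t = 0; t < T; ++t) dE(lab[t], t) -= 1.0;

  for (int t = 1; t < T; ++t)
    for (int b = 0; b < L; ++b)
      for (int a = 0; a < L; ++a)
        g.trans(a, b) += std::exp(alpha(a, t - 1) + m.trans(a, b) + sc.Emis(b, t) + beta(b, t) - logZ);
  for (int t = 1; t < T; ++t) g.trans(lab[t - 1], lab[t]) -= 1.0;
  g.start_v += marg.col(0);  g.start_v(lab[0]) -= 1.0;
  g.end_v += marg.col(T - 1); g.end_v(lab[T - 1]) -= 1.0;

  g.projW += dE * sc.H2.t();
  g.projB += arma::sum(dE, 1);
  arma::mat dH2 = m.projW.t() * dE;

  const int H = m.tf.bi.n_elem;
  arma::mat dXf = lstm_backward(m.tf, sc.tok_f, dH2.rows(0, H - 1), g.tf);
  arma::mat dXb = lstm_backward(m.tb, sc.tok_b, arma::fliplr(dH2.rows(H, 2 * H - 1)), g.tb);
  arma::mat dEmask = dXf + arma::fliplr(dXb);
  arma::mat dEraw = sc.Mask.n_elem > 0 ? arma::mat(dEmask % sc.Mask) : dEmask;

  const int dt = m.tok_emb.n_cols;
  const int cH = m.cf.bi.n_elem;
  for (int t = 0; t < T; ++t) {
    g.tok_emb.row(tok[t] - 1) += dEraw.col(t).subvec(0, dt - 1).t();
    const int Lc = chars[t].size();
    arma::mat dHcf(cH, Lc, arma::fill::zeros);
    dHcf.col(Lc - 1) = dEraw.col(t).subvec(dt, dt + cH - 1);
    arma::mat dCXf = lstm_backward(m.cf, sc.char_f[t], dHcf, g.cf);
    arma::mat dHcb(cH, Lc, arma::fill::zeros);
    dHcb.col(Lc - 1) = dEraw.col(t).subvec(dt + cH, dt + 2 * cH - 1);
    arma::mat dCXb = lstm_backward(m.cb, sc.char_b[t], dHcb, g.cb);
    arma::mat dCX = dCXf + arma::fliplr(dCXb);
    for (int j = 0; j < Lc; ++j)
      g.char_emb.row(chars[t][j] - 1) += dCX.col(j).t();
  }
  return loss;
}

static List cellg_to_list(const CellG& c) {
  return List::create(
    _["W_xi"] = c.Wxi, _["W_hi"] = c.Whi, _["W_ci"] = c.Wci,
    _["b_i"] = NumericVector(c.bi.begin(), c.bi.end()),
    _["W_xc"] = c.Wxc, _["W_hc"] = c.Whc,
    _["b_c"] = NumericVector(c.bc.begin(), c.bc.end()),
    _["W_xo"] = c.Wxo, _["W_ho"] = c.Who, _["W_co"] = c.Wco,
    _["b_o"] = NumericVector(c.bo.begin(), c.bo.end()));
}

static std::vector<int> int_vec(SEXP s) {
  IntegerVector v(s);
  return std::vector<int>(v.begin(), v.end());
}

static void parse_sentence(List s, std::vector<int>& tok,
                           std::vector<std::vector<int>>& chars) {
  tok = int_vec(s["tok"]);
  List ch = s["chars"];
  chars.clear();
  chars.reserve(ch.size());
  for (int i = 0; i < ch.size(); ++i) chars.push_back(int_vec(ch[i]));
}

// ------------------------------------------------------------- exported API

// [[Rcpp::export]]
NumericMatrix cpp_emissions(List params, List sentence, SEXP mask) {
  ModelP m = model_from_list(params);
  std::vector<int> tok;
  std::vector<std::vector<int>> chars;
  parse_sentence(sentence, tok, chars);
  arma::mat mk;
  if (!Rf_isNull(mask)) mk = as<arma::mat>(mask);
  SentCache sc;
  sentence_forward(m, tok, chars, mk, sc);
  arma::mat out = sc.Emis.t();  // T x L
  return wrap(out);
}

// [[Rcpp::export]]
double cpp_crf_log_partition(NumericMatrix emissions, NumericMatrix transitions,
                             NumericVector start, NumericVector end) {
  arma::mat emis = as<arma::mat>(emissions).t();  // L x T
  arma::mat tr = as<arma::mat>(transitions);
  arma::vec sv = as<arma::vec>(start), ev = as<arma::vec>(end);
  arma::mat alpha;
  return crf_alpha(emis, tr, sv, ev, alpha);
}

// [[Rcpp::export]]
List cpp_viterbi(NumericMatrix emissions, NumericMatrix transitions,
                 NumericVector start, NumericVector end) {
  arma::mat emis = as<arma::mat>(emissions).t();  // L x T
  arma::mat tr = as<arma::mat>(transitions);
  arma::vec sv = as<arma::vec>(start), ev = as<arma::vec>(end);
  const int L = emis.n_rows, T = emis.n_cols;
  arma::mat delta(L, T);
  arma::imat bp(L, T, arma::fill::zeros);
  delta.col(0) = sv + emis.col(0);
  for (int t = 1; t < T; ++t)
    for (int b = 0; b < L; ++b) {
      double best = -std::numeric_limits<double>::infinity();
      int arg = 0;
      for (int a = 0; a < L; ++a) {
        double sc = delta(a, t - 1) + tr(a, b);
        if (sc > best) { best = sc; arg = a; }  // strict ">": lowest index wins ties
      }
      delta(b, t) = best + emis(b, t);
      bp(b, t) = arg;
    }
  double best = -std::numeric_limits<double>::infinity();
  int arg = 0;
  for (int b = 0; b < L; ++b) {
    double sc = delta(b, T - 1) + ev(b);
    if (sc > best) { best = sc; arg = b; }
  }
  IntegerVector path(T);
  path[T - 1] = arg + 1;
  for (int t = T - 1; t > 0; --t) {
    arg = bp(arg, t);
    path[t - 1] = arg + 1;
  }
  return List::create(_["path"] = path, _["score"] = best);
}

// [[Rcpp::export]]
List cpp_sentence_grad(List params, List sentence, SEXP mask, IntegerVector labels) {
  ModelP m = model_from_list(params);
  std::vector<int> tok;
  std::vector<std::vector<int>> chars;
  parse_sentence(sentence, tok, chars);
  std::vector<int> lab(labels.size());
  for (int i = 0; i < labels.size(); ++i) lab[i] = labels[i] - 1;
  if ((int)tok.size() != (int)lab.size())
    stop("label sequence length does not match token count");
  arma::mat mk;
  if (!Rf_isNull(mask)) mk = as<arma::mat>(mask);
  ModelG g;
  g.init(m);
  SentCache sc;
  double loss = sentence_loss_grad(m, tok, chars, lab, mk, g, sc);
  List gl = List::create(
    _["token_embedding"] = g.tok_emb,
    _["char_embedding"] = g.char_emb,
    _["char_lstm_fwd"] = cellg_to_list(g.cf),
    _["char_lstm_bwd"] = cellg_to_list(g.cb),
    _["token_lstm_fwd"] = cellg_to_list(g.tf),
    _["token_lstm_bwd"] = cellg_to_list(g.tb),
    _["projection_W"] = g.projW,
    _["projection_b"] = NumericVector(g.projB.begin(), g.projB.end()),
    _["crf_transitions"] = g.trans,
    _["crf_start"] = NumericVector(g.start_v.begin(), g.start_v.end()),
    _["crf_end"] = NumericVector(g.end_v.begin(), g.end_v.end()));
  return List::create(_["loss"] = loss, _["gradients"] = gl);
}

// [[Rcpp::export]]
List cpp_train_epoch(List params, List sentences, IntegerVector order,
                     SEXP masks, double lr, double clip) {
  ModelP m = model_from_list(params);
  ModelG g;
  g.init(m);
  std::vector<arma::mat*> gms; std::vector<arma::vec*> gvs;
  collect_grads(g, gms, gvs);
  std::vector<arma::mat*> pms; std::vector<arma::vec*> pvs;
  collect_params(m, pms, pvs);
  bool have_masks = !Rf_isNull(masks);
  List ml;
  if (have_masks) ml = List(masks);
  SentCache sc;
  double total = 0.0;
  for (int k = 0; k < order.size(); ++k) {
    int idx = order[k] - 1;
    List s = sentences[idx];
    std::vector<int> tok;
    std::vector<std::vector<int>> chars;
    parse_sentence(s, tok, chars);
    IntegerVector labR = s["labels"];
    std::vector<int> lab(labR.size());
    for (int i = 0; i < labR.size(); ++i) lab[i] = labR[i] - 1;
    arma::mat mk;
    if (have_masks && !Rf_isNull(ml[idx])) mk = as<arma::mat>(ml[idx]);
    g.zero();
    total += sentence_loss_grad(m, tok, chars, lab, mk, g, sc);
    double sq = 0.0;
    for (auto* p : gms) sq += arma::accu(arma::square(*p));
    for (auto* p : gvs) sq += arma::accu(arma::square(*p));
    double nrm = std::sqrt(sq);
    double scale = (nrm > clip && nrm > 0.0) ? clip / nrm : 1.0;
    for (size_t j = 0; j < gms.size(); ++j) *pms[j] -= (lr * scale) * (*gms[j]);
    for (size_t j = 0; j < gvs.size(); ++j) *pvs[j] -= (lr * scale) * (*gvs[j]);
  }
  return List::create(_["params"] = model_to_list(m),
                      _["mean_loss"] = total / std::max(1, (int)order.size()));
}

// [[Rcpp::export]]
List cpp_predict_corpus(List params, List sentences) {
  ModelP m = model_from_list(params);
  arma::mat mk;  // no dropout at evaluation time
  SentCache sc;
  List out(sentences.size());
  for (int i = 0; i < sentences.size(); ++i) {
    List s = sentences[i];
    std::vector<int> tok;
    std::vector<std::vector<int>> chars;
    parse_sentence(s, tok, chars);
    sentence_forward(m, tok, chars, mk, sc);
    arma::mat emisTL = sc.Emis.t();
    List vt = cpp_viterbi(wrap(emisTL), wrap(m.trans),
                          NumericVector(m.start_v.begin(), m.start_v.end()),
                          NumericVector(m.end_v.begin(), m.end_v.end()));
    out[i] = vt["path"];
  }
  return out;
}
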