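// Numerical core of the single-task tagger: character-CNN word embeddings,
// BiLSTM encoder with a collaborator-feature slot, emission layer,
// linear-chain CRF (forward algorithm + Viterbi), and full backpropagation.
// All ids arriving from R are 1-based; the PAD character is id 1.
// Emission matrix z is n_tags x T; transition matrix A is (n_tags+1) x n_tags
// with the start row last. Dropout uses R's RNG so set.seed() controls it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

static inline double lse(const vec &x) {
  double m = x.max();
  return m + std::log(arma::accu(arma::exp(x - m)));
}

static inline vec sigmoid(const vec &x) { return 1.0 / (1.0 + arma::exp(-x)); }

// ---------------------------------------------------------------------------
// Parameters

struct StmParams {
  mat Eword, Echar;
  std::vector<int> wins;
  std::vector<mat> convW;
  std::vector<vec> convb;
  mat fWx, fWh, bWx, bWh, Wy, A;
  vec fb, bb, by;
  int d_word, d_char, d_clwe, H, n_tags, d_in;
};

static StmParams parse_params(const List &params, const IntegerVector &windows) {
  StmParams P;
  P.Eword = as<mat>(params["Eword"]);
  P.Echar = as<mat>(params["Echar"]);
  for (int w = 0; w < windows.size(); ++w) {
    int k = windows[w];
    P.wins.push_back(k);
    P.convW.push_back(as<mat>(params[std::string("convW_") + std::to_string(k)]));
    P.convb.push_back(as<vec>(params[std::string("convb_") + std::to_string(k)]));
  }
  P.fWx = as<mat>(params["fWx"]); P.fWh = as<mat>(params["fWh"]); P.fb = as<vec>(params["fb"]);
  P.bWx = as<mat>(params["bWx"]); P.bWh = as<mat>(params["bWh"]); P.bb = as<vec>(params["bb"]);
  P.Wy = as<mat>(params["Wy"]); P.by = as<vec>(params["by"]);
  P.A = as<mat>(params["A"]);
  P.d_word = P.Eword.n_rows;
  P.d_char = P.Echar.n_rows;
  P.d_clwe = 0;
  for (size_t w = 0; w < P.convW.size(); ++w) P.d_clwe += P.convW[w].n_rows;
  P.H = P.fWh.n_cols;
  P.n_tags = P.Wy.n_rows;
  P.d_in = P.fWx.n_cols;
  return P;
}

struct StmGrads {
  mat Eword, Echar;
  std::vector<mat> convW;
  std::vector<vec> convb;
  mat fWx, fWh, bWx, bWh, Wy, A;
  vec fb, bb, by;
  void init(const StmParams &P) {
    Eword.zeros(P.Eword.n_rows, P.Eword.n_cols);
    Echar.zeros(P.Echar.n_rows, P.Echar.n_cols);
    convW.clear(); convb.clear();
    for (size_t w = 0; w < P.convW.size(); ++w) {
      convW.push_back(arma::zeros<mat>(P.convW[w].n_rows, P.convW[w].n_cols));
      convb.push_back(arma::zeros<vec>(P.convb[w].n_elem));
    }
    fWx.zeros(arma::size(P.fWx)); fWh.zeros(arma::size(P.fWh)); fb.zeros(P.fb.n_elem);
    bWx.zeros(arma::size(P.bWx)); bWh.zeros(arma::size(P.bWh)); bb.zeros(P.bb.n_elem);
    Wy.zeros(arma::size(P.Wy)); by.zeros(P.by.n_elem);
    A.zeros(arma::size(P.A));
  }
  List to_list(const StmParams &P) const {
    List g;
    g["Eword"] = Eword; g["Echar"] = Echar;
    for (size_t w = 0; w < convW.size(); ++w) {
      g[std::string("convW_") + std::to_string(P.wins[w])] = convW[w];
      g[std::string("convb_") + std::to_string(P.wins[w])] = convb[w];
    }
    g["fWx"] = fWx; g["fWh"] = fWh; g["fb"] = fb;
    g["bWx"] = bWx; g["bWh"] = bWh; g["bb"] = bb;
    g["Wy"] = Wy; g["by"] = by; g["A"] = A;
    return g;
  }
};

// ---------------------------------------------------------------------------
// Character CNN

// Window vector for character position i (0-based) of a word, window size k.
static vec char_window_vec(const StmParams &P, const std::vector<int> &chars, int i, int k) {
  int pad = (k - 1) / 2;
  vec win(k * P.d_char);
  for (int s = 0; s < k; ++s) {
    int pos = i - pad + s;
    int cid = (pos < 0 || pos >= (int)chars.size()) ? 0 : chars[pos] - 1; // PAD = col 0
    win.subvec(s * P.d_char, (s + 1) * P.d_char - 1) = P.Echar.col(cid);
  }
  return win;
}

// Forward CLWE for one word; records per-output-coordinate argmax windows.
static vec char_cnn_forward(const StmParams &P, const std::vector<int> &chars,
                            std::vector<arma::uvec> &argmax) {
  int M = chars.size();
  vec xc(P.d_clwe);
  int off = 0;
  argmax.resize(P.wins.size());
  for (size_t w = 0; w < P.wins.size(); ++w) {
    int k = P.wins[w];
    int dk = P.convW[w].n_rows;
    mat scores(dk, M);
    for (int i = 0; i < M; ++i) {
      scores.col(i) = P.convW[w] * char_window_vec(P, chars, i, k) + P.convb[w];
    }
    arma::uvec am(dk);
    for (int j = 0; j < dk; ++j) {
      arma::rowvec r = scores.row(j);
      am[j] = r.index_max();
      xc[off + j] = r[am[j]];
    }
    argmax[w] = am;
    off += dk;
  }
  return xc;
}

static void char_cnn_backward(const StmParams &P, StmGrads &G,
                              const std::vector<int> &chars,
                              const std::vector<arma::uvec> &argmax,
                              const vec &dxc) {
  int off = 0;
  for (size_t w = 0; w < P.wins.size(); ++w) {
    int k = P.wins[w];
    int pad = (k - 1) / 2;
    int dk = P.convW[w].n_rows;
    for (int j = 0; j < dk; ++j) {
      double dv = dxc[off + j];
      if (dv == 0.0) continue;
      int i = argmax[w][j];
      vec win = char_window_vec(P, chars, i, k);
      G.convW[w].row(j) += dv * win.t();
      G.convb[w][j] += dv;
      vec dwin = P.convW[w].row(j).t() * dv;
      for (int s = 0; s < k; ++s) {
        int pos = i - pad + s;
        int cid = (pos < 0 || pos >= (int)chars.size()) ? 0 : chars[pos] - 1;
        G.Echar.col(cid) += dwin.subvec(s * P.d_char, (s + 1) * P.d_char - 1);
      }
    }
    off += dk;
  }
}

// ---------------------------------------------------------------------------
// LSTM

struct LstmCache { mat i, f, g, o, c, tc, h; };

static void lstm_forward(const mat &Wx, const mat &Wh, const vec &b,
                         const mat &X, bool reverse, LstmCache &C) {
  int H = Wh.n_cols, T = X.n_cols;
  C.i.set_size(H, T); C.f.set_size(H, T); C.g.set_size(H, T); C.o.set_size(H, T);
  C.c.set_size(H, T); C.tc.set_size(H, T); C.h.set_size(H, T);
  vec hprev(H, arma::fill::zeros), cprev(H, arma::fill::zeros);
  for (int s = 0; s < T; ++s) {
    int t = reverse ? T - 1 - s : s;
    vec a = Wx * X.col(t) + Wh * hprev + b;
    vec i = sigmoid(a.subvec(0, H - 1));
    vec f = sigmoid(a.subvec(H, 2 * H - 1));
    vec g = arma::tanh(a.subvec(2 * H, 3 * H - 1));
    vec o = sigmoid(a.subvec(3 * H, 4 * H - 1));
    vec c = f % cprev + i % g;
    vec tc = arma::tanh(c);
    vec h = o % tc;
    C.i.col(t) = i; C.f.col(t) = f; C.g.col(t) = g; C.o.col(t) = o;
    C.c.col(t) = c; C.tc.col(t) = tc; C.h.col(t) = h;
    hprev = h; cprev = c;
  }
}

// dh: H x T gradient on this direction's hidden states. Accumulates into
// dWx/dWh/db and dX.
static void lstm_backward(const mat &Wx, const mat &Wh, const mat &X,
                          const LstmCache &C, const mat &dh_in, bool reverse,
                          mat &dWx, mat &dWh, vec &db, mat &dX) {
  int H = Wh.n_cols, T = X.n_cols;
  vec dh_carry(H, arma::fill::zeros), dc(H, arma::fill::zeros);
  for (int s = T - 1; s >= 0; --s) {
    int t = reverse ? T - 1 - s : s;
    vec dh = dh_in.col(t) + dh_carry;
    vec i = C.i.col(t), f = C.f.col(t), g = C.g.col(t), o = C.o.col(t), tc = C.tc.col(t);
    vec do_ = dh % tc;
    dc += dh % o % (1.0 - tc % tc);
    vec cprev(H, arma::fill::zeros), hprev(H, arma::fill::zeros);
    if (s > 0) {
      int tp = reverse ? T - s : s - 1;
      cprev = C.c.col(tp);
      hprev = C.h.col(tp);
    }
    vec df = dc % cprev;
    vec di = dc % g;
    vec dg = dc % i;
    vec da(4 * H);
    da.subvec(0, H - 1) = di % i % (1.0 - i);
    da.subvec(H, 2 * H - 1) = df % f % (1.0 - f);
    da.subvec(2 * H, 3 * H - 1) = dg % (1.0 - g % g);
    da.subvec(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    dWx += da * X.col(t).t();
    dWh += da * hprev.t();
    db += da;
    dX.col(t) += Wx.t() * da;
    dh_carry = Wh.t() * da;
    dc = dc % f;
  }
}

// ---------------------------------------------------------------------------
// CRF

static double path_score_impl(const mat &z, const mat &A, const std::vector<int> &y) {
  int T = z.n_cols, start = z.n_rows;
  double s = A(start, y[0]) + z(y[0], 0);
  for (int t = 1; t < T; ++t) s += A(y[t - 1], y[t]) + z(y[t], t);
  return s;
}

// CRF loss and (optionally) gradients wrt z and A.
// mode "nll": forward-algorithm negative log likelihood.
// mode "neg_score": negative gold-path score (the literal printed variant).
static double crf_loss_grad(const mat &z, const mat &A, const std::vector<int> &y,
                            const std::string &mode, mat *dz, mat *dA) {
  int n = z.n_rows, T = z.n_cols, start = n;
  double gold = path_score_impl(z, A, y);
  if (mode == "neg_score") {
    if (dz) {
      (*dz)(y[0], 0) -= 1.0;
      (*dA)(start, y[0]) -= 1.0;
      for (int t = 1; t < T; ++t) {
        (*dz)(y[t], t) -= 1.0;
        (*dA)(y[t - 1], y[t]) -= 1.0;
      }
    }
    return -gold;
  }
  mat alpha(n, T);
  alpha.col(0) = z.col(0) + A.row(start).t();
  for (int t = 1; t < T; ++t) {
    for (int v = 0; v < n; ++v) {
      alpha(v, t) = z(v, t) + lse(alpha.col(t - 1) + A.col(v).head(n));
    }
  }
  double logZ = lse(alpha.col(T - 1));
  double loss = logZ - gold;
  if (dz) {
    mat beta(n, T, arma::fill::zeros);
    for (int t = T - 2; t >= 0; --t) {
      for (int u = 0; u < n; ++u) {
        vec arow = A.row(u).t();
        beta(u, t) = lse(arow + z.col(t + 1) + beta.col(t + 1));
      }
    }
    for (int t = 0; t < T; ++t) {
      vec marg = arma::exp(alpha.col(t) + beta.col(t) - logZ);
      (*dz).col(t) += marg;
      (*dz)(y[t], t) -= 1.0;
      if (t == 0) {
        (*dA).row(start) += marg.t();
        (*dA)(start, y[0]) -= 1.0;
      } else {
        for (int u = 0; u < n; ++u) {
          for (int v = 0; v < n; ++v) {
            (*dA)(u, v) += std::exp(alpha(u, t - 1) + A(u, v) + z(v, t) +
                                    beta(v, t) - logZ);
          }
        }
        (*dA)(y[t - 1], y[t]) -= 1.0;
      }
    }
  }
  return loss;
}

// ---------------------------------------------------------------------------
// Full single-task model run over one sentence

struct SentenceData {
  std::vector<int> wid;                    // 1-based word ids
  std::vector<std::vector<int>> chars;     // 1-based char ids per token
  mat slot;                                // 2H x T collaborator features
  std::vector<int> gold;                   // 0-based tag ids (may be empty)
};

static mat dropout_mask(int nr, int nc, double p) {
  mat m(nr, nc);
  double keep = 1.0 - p;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      m(i, j) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
  return m;
}

struct RunResult {
  double loss_total = 0, loss_lstm = 0, loss_crf = 0;
  mat z, h, dslot, X;
};

static void run_sentence(const StmParams &P, const SentenceData &S,
                         double p_clwe, double p_lstm, bool training,
                         const std::string &crf_mode, bool want_grad,
                         StmGrads *G, RunResult &out) {
  int T = S.wid.size();
  int H = P.H, n = P.n_tags;
  int d_slot = P.d_in - P.d_word - P.d_clwe;

  // Embedding layer
  std::vector<std::vector<arma::uvec>> argmax(T);
  mat X(P.d_in, T, arma::fill::zeros);
  mat clwe_mask;
  if (training && p_clwe > 0) clwe_mask = dropout_mask(P.d_clwe, T, p_clwe);
  for (int t = 0; t < T; ++t) {
    X.submat(0, t, P.d_word - 1, t) = P.Eword.col(S.wid[t] - 1);
    vec xc = char_cnn_forward(P, S.chars[t], argmax[t]);
    if (clwe_mask.n_elem) xc %= clwe_mask.col(t);
    X.submat(P.d_word, t, P.d_word + P.d_clwe - 1, t) = xc;
    if (d_slot > 0 && S.slot.n_elem) {
      X.submat(P.d_word + P.d_clwe, t, P.d_in - 1, t) = S.slot.col(t);
    }
  }

  // Encoder
  LstmCache CF, CB;
  lstm_forward(P.fWx, P.fWh, P.fb, X, false, CF);
  lstm_forward(P.bWx, P.bWh, P.bb, X, true, CB);
  mat h = arma::join_cols(CF.h, CB.h);
  mat lstm_mask;
  mat hd = h;
  if (training && p_lstm > 0) {
    lstm_mask = dropout_mask(2 * H, T, p_lstm);
    hd = h % lstm_mask;
  }

  // Emissions
  mat z = P.Wy * hd;
  z.each_col() += P.by;
  out.z = z;
  out.h = h;
  out.X = X;

  if (S.gold.empty()) return;

  // Losses
  mat dz(n, T, arma::fill::zeros);
  mat dA(n + 1, n, arma::fill::zeros);
  double l_lstm = 0;
  for (int t = 0; t < T; ++t) {
    double logZt = lse(z.col(t));
    l_lstm += logZt - z(S.gold[t], t);
    if (want_grad) {
      dz.col(t) += arma::exp(z.col(t) - logZt);
      dz(S.gold[t], t) -= 1.0;
    }
  }
  double l_crf = crf_loss_grad(z, P.A, S.gold, crf_mode,
                               want_grad ? &dz : nullptr,
                               want_grad ? &dA : nullptr);
  out.loss_lstm = l_lstm;
  out.loss_crf = l_crf;
  out.loss_total = l_lstm + l_crf;
  if (!want_grad) return;

  // Backward
  G->A += dA;
  G->Wy += dz * hd.t();
  G->by += arma::sum(dz, 1);
  mat dhd = P.Wy.t() * dz;
  mat dh = lstm_mask.n_elem ? mat(dhd % lstm_mask) : dhd;
  mat dX(P.d_in, T, arma::fill::zeros);
  lstm_backward(P.fWx, P.fWh, X, CF, dh.rows(0, H - 1), false, G->fWx, G->fWh, G->fb, dX);
  lstm_backward(P.bWx, P.bWh, X, CB, dh.rows(H, 2 * H - 1), true, G->bWx, G->bWh, G->bb, dX);
  for (int t = 0; t < T; ++t) {
    G->Eword.col(S.wid[t] - 1) += dX.submat(0, t, P.d_word - 1, t);
    vec dxc = dX.submat(P.d_word, t, P.d_word + P.d_clwe - 1, t);
    if (clwe_mask.n_elem) dxc %= clwe_mask.col(t);
    char_cnn_backward(P, *G, S.chars[t], argmax[t], dxc);
  }
  if (d_slot > 0) {
    out.dslot = dX.rows(P.d_word + P.d_clwe, P.d_in - 1);
  }
}

static SentenceData sentence_from_list(const List &sent, int two_H) {
  SentenceData S;
  IntegerVector wid = sent["wid"];
  S.wid = std::vector<int>(wid.begin(), wid.end());
  List cl = sent["chars"];
  for (int i = 0; i < cl.size(); ++i) {
    IntegerVector ci = cl[i];
    S.chars.push_back(std::vector<int>(ci.begin(), ci.end()));
  }
  if (sent.containsElementNamed("slot") && !Rf_isNull(sent["slot"])) {
    S.slot = as<mat>(sent["slot"]);
  } else {
    S.slot = mat(two_H, S.wid.size(), arma::fill::zeros);
  }
  if (sent.containsElementNamed("gold") && !Rf_isNull(sent["gold"])) {
    IntegerVector g = sent["gold"];
    for (int i = 0; i < g.size(); ++i) S.gold.push_back(g[i] - 1); // to 0-based
  }
  return S;
}

// ---------------------------------------------------------------------------
// Exports

// Run the model over one sentence. `sent` is a list with elements `wid`
// (1-based word ids), `chars` (list of 1-based char-id vectors), optional
// `slot` (2H x T matrix) and optional `gold` (1-based tag ids).
// [[Rcpp::export]]
List cpp_stm_run(List params, IntegerVector windows, List sent,
                 double p_clwe, double p_lstm, bool training,
                 std::string crf_mode, bool want_grad) {
  StmParams P = parse_params(params, windows);
  SentenceData S = sentence_from_list(sent, P.d_in - P.d_word - P.d_clwe);
  StmGrads G;
  if (want_grad) G.init(P);
  RunResult out;
  run_sentence(P, S, p_clwe, p_lstm, training, crf_mode, want_grad,
               want_grad ? &G : nullptr, out);
  List res = List::create(
      _["loss_total"] = out.loss_total, _["loss_lstm"] = out.loss_lstm,
      _["loss_crf"] = out.loss_crf, _["z"] = out.z, _["h"] = out.h,
      _["X"] = out.X);
  if (want_grad) {
    res["grads"] = G.to_list(P);
    res["dslot"] = out.dslot;
  }
  return res;
}

// Run a mini-batch: returns grads summed over sentences, per-sentence losses,
// and per-sentence dslot matrices (for training the aggregation weights).
// [[Rcpp::export]]
List cpp_stm_batch(List params, IntegerVector windows, List sentences,
                   double p_clwe, double p_lstm, std::string crf_mode) {
  StmParams P = parse_params(params, windows);
  StmGrads G;
  G.init(P);
  int B = sentences.size();
  NumericVector losses(B), losses_lstm(B), losses_crf(B);
  List dslots(B);
  for (int b = 0; b < B; ++b) {
    SentenceData S = sentence_from_list(sentences[b], P.d_in - P.d_word - P.d_clwe);
    RunResult out;
    run_sentence(P, S, p_clwe, p_lstm, true, crf_mode, true, &G, out);
    losses[b] = out.loss_total;
    losses_lstm[b] = out.loss_lstm;
    losses_crf[b] = out.loss_crf;
    dslots[b] = out.dslot;
  }
  return List::create(_["grads"] = G.to_list(P), _["loss_total"] = losses,
                      _["loss_lstm"] = losses_lstm, _["loss_crf"] = losses_crf,
                      _["dslot"] = dslots);
}

// Inference-mode encoder outputs h^bi (2H x T); no dropout.
// [[Rcpp::export]]
arma::mat cpp_stm_encode(List params, IntegerVector windows, List sent) {
  StmParams P = parse_params(params, windows);
  SentenceData S = sentence_from_list(sent, P.d_in - P.d_word - P.d_clwe);
  S.gold.clear();
  RunResult out;
  run_sentence(P, S, 0.0, 0.0, false, "nll", false, nullptr, out);
  return out.h;
}

// Inference-mode emissions z (n_tags x T); no dropout.
// [[Rcpp::export]]
arma::mat cpp_stm_emissions(List params, IntegerVector windows, List sent) {
  StmParams P = parse_params(params, windows);
  SentenceData S = sentence_from_list(sent, P.d_in - P.d_word - P.d_clwe);
  S.gold.clear();
  RunResult out;
  run_sentence(P, S, 0.0, 0.0, false, "nll", false, nullptr, out);
  return out.z;
}

// Viterbi decoding; ties broken toward the lowest tag index. Returns the
// 1-based tag index path and its score.
// [[Rcpp::export]]
List cpp_viterbi(arma::mat z, arma::mat A) {
  int n = z.n_rows, T = z.n_cols, start = n;
  mat delta(n, T);
  arma::imat back(n, T);
  delta.col(0) = z.col(0) + A.row(start).t();
  for (int t = 1; t < T; ++t) {
    for (int v = 0; v < n; ++v) {
      int arg = 0;
      double best = delta(0, t - 1) + A(0, v);
      for (int u = 1; u < n; ++u) {
        double s = delta(u, t - 1) + A(u, v);
        if (s > best) { best = s; arg = u; }   // strict: keeps lowest index
      }
      delta(v, t) = best + z(v, t);
      back(v, t) = arg;
    }
  }
  int last = 0;
  double best = delta(0, T - 1);
  for (int v = 1; v < n; ++v) {
    if (delta(v, T - 1) > best) { best = delta(v, T - 1); last = v; }
  }
  IntegerVector path(T);
  path[T - 1] = last + 1;
  for (int t = T - 1; t > 0; --t) {
    last = back(last, t);
    path[t - 1] = last + 1;
  }
  return List::create(_["path"] = path, _["score"] = best);
}

// [[Rcpp::export]]
double cpp_path_score(arma::mat z, arma::mat A, IntegerVector y) {
  std::vector<int> y0;
  for (int i = 0; i < y.size(); ++i) y0.push_back(y[i] - 1);
  return path_score_impl(z, A, y0);
}

// [[Rcpp::export]]
double cpp_crf_loss(arma::mat z, arma::mat A, IntegerVector y, std::string mode) {
  std::vector<int> y0;
  for (int i = 0; i < y.size(); ++i) y0.push_back(y[i] - 1);
  return crf_loss_grad(z, A, y0, mode, nullptr, nullptr);
}

// Log partition function of the linear-chain CRF (forward algorithm).
// [[Rcpp::export]]
double cpp_crf_logZ(arma::mat z, arma::mat A) {
  int n = z.n_rows, T = z.n_cols, start = n;
  mat alpha(n, T);
  alpha.col(0) = z.col(0) + A.row(start).t();
  for (int t = 1; t < T; ++t) {
    for (int v = 0; v < n; ++v) {
      alpha(v, t) = z(v, t) + lse(alpha.col(t - 1) + A.col(v).head(n));
    }
  }
  return lse(alpha.col(T - 1));
}
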