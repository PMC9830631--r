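// Bidirectional LSTM sequence classifier: batched forward pass,
// backpropagation through time, and Adam updates.
//
// Layout conventions (fixed across the package):
//  * a batch of sequences is a cube X with dimensions (D, B, T):
//    slice t is the D x B matrix of inputs at time step t;
//  * gate pre-activations are stacked row blocks [input; forget;
//    candidate; output], each H rows, so W is (4H x D), U is (4H x H),
//    b is (4H);
//  * the readout concatenates the forward direction's hidden state after
//    its last step with the backward direction's hidden state after its
//    last step (i.e. after reading time step 1), then applies a fully
//    connected layer (R x 2H) and softmax.
//
// All randomness (initial weights, shuffling) is generated on the R side
// and passed in, so training is bit-reproducible given a seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct LstmCache {
  cube gi, gf, gg, go, cs, hs;  // each (H, B, T), indexed by processing step
};

inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// One direction over a batch; returns hidden state after the last
// processing step, filling caches when requested.
mat run_dir(const mat& W, const mat& U, const vec& b, const cube& X,
            bool reverse, LstmCache* cache) {
  const uword H = U.n_cols, B = X.n_cols, T = X.n_slices;
  mat h(H, B, fill::zeros), c(H, B, fill::zeros);
  if (cache) {
    cache->gi.set_size(H, B, T); cache->gf.set_size(H, B, T);
    cache->gg.set_size(H, B, T); cache->go.set_size(H, B, T);
    cache->cs.set_size(H, B, T); cache->hs.set_size(H, B, T);
  }
  for (uword s = 0; s < T; ++s) {
    const uword t = reverse ? (T - 1 - s) : s;
    mat a = W * X.slice(t) + U * h;
    a.each_col() += b;
    mat i = sigm(a.rows(0, H - 1));
    mat f = sigm(a.rows(H, 2 * H - 1));
    mat g = tanh(a.rows(2 * H, 3 * H - 1));
    mat o = sigm(a.rows(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % tanh(c);
    if (cache) {
      cache->gi.slice(s) = i; cache->gf.slice(s) = f;
      cache->gg.slice(s) = g; cache->go.slice(s) = o;
      cache->cs.slice(s) = c; cache->hs.slice(s) = h;
    }
  }
  return h;
}

// BPTT for one direction given the gradient at the final hidden state.
void back_dir(const mat& W, const mat& U, const cube& X, bool reverse,
              const LstmCache& cache, const mat& dh_final,
              mat& dW, mat& dU, vec& db) {
  const uword H = U.n_cols, B = X.n_cols, T = X.n_slices;
  dW.zeros(4 * H, W.n_cols); dU.zeros(4 * H, H); db.zeros(4 * H);
  mat dh = dh_final, dc(H, B, fill::zeros);
  for (uword s = T; s-- > 0;) {
    const uword t = reverse ? (T - 1 - s) : s;
    const mat& i = cache.gi.slice(s);
    const mat& f = cache.gf.slice(s);
    const mat& g = cache.gg.slice(s);
    const mat& o = cache.go.slice(s);
    const mat& c = cache.cs.slice(s);
    mat c_prev = (s == 0) ? mat(H, B, fill::zeros) : cache.cs.slice(s - 1);
    mat h_prev = (s == 0) ? mat(H, B, fill::zeros) : cache.hs.slice(s - 1);
    mat tc = tanh(c);
    mat do_pre = (dh % tc) % (o % (1.0 - o));
    dc += dh % o % (1.0 - tc % tc);
    mat di_pre = (dc % g) % (i % (1.0 - i));
    mat df_pre = (dc % c_prev) % (f % (1.0 - f));
    mat dg_pre = (dc % i) % (1.0 - g % g);
    mat da = join_cols(join_cols(di_pre, df_pre), join_cols(dg_pre, do_pre));
    dW += da * X.slice(t).t();
    dU += da * h_prev.t();
    db += sum(da, 1);
    dh = U.t() * da;
    dc = dc % f;
  }
}

struct Params {
  mat Wf, Uf, Wb, Ub, Wfc;
  vec bf, bb, bfc;
};

Params unpack(const Rcpp::List& p) {
  Params q;
  q.Wf = Rcpp::as<mat>(p["Wf"]); q.Uf = Rcpp::as<mat>(p["Uf"]);
  q.bf = Rcpp::as<vec>(p["bf"]);
  q.Wb = Rcpp::as<mat>(p["Wb"]); q.Ub = Rcpp::as<mat>(p["Ub"]);
  q.bb = Rcpp::as<vec>(p["bb"]);
  q.Wfc = Rcpp::as<mat>(p["Wfc"]); q.bfc = Rcpp::as<vec>(p["bfc"]);
  return q;
}

Rcpp::List pack(const Params& q) {
  return Rcpp::List::create(
      Rcpp::Named("Wf") = q.Wf, Rcpp::Named("Uf") = q.Uf,
      Rcpp::Named("bf") = q.bf, Rcpp::Named("Wb") = q.Wb,
      Rcpp::Named("Ub") = q.Ub, Rcpp::Named("bb") = q.bb,
      Rcpp::Named("Wfc") = q.Wfc, Rcpp::Named("bfc") = q.bfc);
}

mat softmax_cols(mat z) {
  rowvec m = max(z, 0);
  z.each_row() -= m;
  mat e = exp(z);
  rowvec s = sum(e, 0);
  e.each_row() /= s;
  return e;
}

// Forward probabilities for a batch; caches filled when given.
mat probs_batch(const Params& q, const cube& X,
                LstmCache* cf, LstmCache* cb, mat* concat_out) {
  mat hf = run_dir(q.Wf, q.Uf, q.bf, X, false, cf);
  mat hb = run_dir(q.Wb, q.Ub, q.bb, X, true, cb);
  mat concat = join_cols(hf, hb);
  if (concat_out) *concat_out = concat;
  mat z = q.Wfc * concat;
  z.each_col() += q.bfc;
  return softmax_cols(z);
}

// Loss and full gradient on a batch (y is 0-based class index).
double grad_batch(const Params& q, const cube& X, const uvec& y,
                  Params& g) {
  const uword B = X.n_cols, H = q.Uf.n_cols;
  LstmCache cf, cb;
  mat concat;
  mat p = probs_batch(q, X, &cf, &cb, &concat);
  double loss = 0.0;
  mat dz = p;
  for (uword n = 0; n < B; ++n) {
    loss -= std::log(std::max(p(y(n), n), 1e-300));
    dz(y(n), n) -= 1.0;
  }
  loss /= B;
  dz /= double(B);
  g.Wfc = dz * concat.t();
  g.bfc = sum(dz, 1);
  mat dconcat = q.Wfc.t() * dz;
  back_dir(q.Wf, q.Uf, X, false, cf, dconcat.rows(0, H - 1),
           g.Wf, g.Uf, g.bf);
  back_dir(q.Wb, q.Ub, X, true, cb, dconcat.rows(H, 2 * H - 1),
           g.Wb, g.Ub, g.bb);
  return loss;
}

void adam_update(mat& w, const mat& dw, mat& m, mat& v, double lr,
                 double b1, double b2, double eps, double t) {
  m = b1 * m + (1 - b1) * dw;
  v = b2 * v + (1 - b2) * (dw % dw);
  w -= lr * (m / (1 - std::pow(b1, t))) /
       (sqrt(v / (1 - std::pow(b2, t))) + eps);
}

}  // namespace

// [[Rcpp::export]]
arma::mat cpp_bilstm_probs(Rcpp::List params, arma::cube X) {
  Params q = unpack(params);
  return probs_batch(q, X, nullptr, nullptr, nullptr);
}

// [[Rcpp::export]]
Rcpp::List cpp_bilstm_grad(Rcpp::List params, arma::cube X,
                           arma::uvec y) {
  Params q = unpack(params), g;
  double loss = grad_batch(q, X, y, g);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = pack(g));
}

// [[Rcpp::export]]
Rcpp::List cpp_bilstm_train(Rcpp::List params, arma::cube X, arma::uvec y,
                            double lr, int batch_size, int max_epochs,
                            int patience, double tol, arma::umat perms) {
  Params q = unpack(params);
  const uword N = X.n_cols;

  // Adam state, one (m, v) pair per parameter
  Params m, v;
  m.Wf.zeros(size(q.Wf)); v.Wf.zeros(size(q.Wf));
  m.Uf.zeros(size(q.Uf)); v.Uf.zeros(size(q.Uf));
  m.bf.zeros(q.bf.n_elem); v.bf.zeros(q.bf.n_elem);
  m.Wb.zeros(size(q.Wb)); v.Wb.zeros(size(q.Wb));
  m.Ub.zeros(size(q.Ub)); v.Ub.zeros(size(q.Ub));
  m.bb.zeros(q.bb.n_elem); v.bb.zeros(q.bb.n_elem);
  m.Wfc.zeros(size(q.Wfc)); v.Wfc.zeros(size(q.Wfc));
  m.bfc.zeros(q.bfc.n_elem); v.bfc.zeros(q.bfc.n_elem);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  // loss of the untrained network (mean over all sequences)
  double initial_loss;
  {
    mat p = probs_batch(q, X, nullptr, nullptr, nullptr);
    double l = 0.0;
    for (uword n = 0; n < N; ++n)
      l -= std::log(std::max(p(y(n), n), 1e-300));
    initial_loss = l / N;
  }

  std::vector<double> loss_hist;
  double best = datum::inf;
  int stall = 0, epochs_run = 0, step = 0;

  for (int e = 0; e < max_epochs; ++e) {
    const uvec ord = perms.col(e);
    double epoch_loss = 0.0;
    uword done = 0;
    while (done < N) {
      const uword bsz = std::min<uword>(batch_size, N - done);
      uvec idx = ord.subvec(done, done + bsz - 1);
      cube Xb(X.n_rows, bsz, X.n_slices);
      uvec yb(bsz);
      for (uword j = 0; j < bsz; ++j) {
        Xb(span::all, span(j, j), span::all) =
            X(span::all, span(idx(j), idx(j)), span::all);
        yb(j) = y(idx(j));
      }
      Params g;
      double loss = grad_batch(q, Xb, yb, g);
      epoch_loss += loss * bsz;
      ++step;
      adam_update(q.Wf, g.Wf, m.Wf, v.Wf, lr, b1, b2, eps, step);
      adam_update(q.Uf, g.Uf, m.Uf, v.Uf, lr, b1, b2, eps, step);
      adam_update(q.Wb, g.Wb, m.Wb, v.Wb, lr, b1, b2, eps, step);
      adam_update(q.Ub, g.Ub, m.Ub, v.Ub, lr, b1, b2, eps, step);
      adam_update(q.Wfc, g.Wfc, m.Wfc, v.Wfc, lr, b1, b2, eps, step);
      // vector parameters updated through 1-column matrix copies
      {
        mat w(q.bf), d(g.bf), mm(m.bf), vv(v.bf);
        adam_update(w, d, mm, vv, lr, b1, b2, eps, step);
        q.bf = w.col(0); m.bf = mm.col(0); v.bf = vv.col(0);
      }
      {
        mat w(q.bb), d(g.bb), mm(m.bb), vv(v.bb);
        adam_update(w, d, mm, vv, lr, b1, b2, eps, step);
        q.bb = w.col(0); m.bb = mm.col(0); v.bb = vv.col(0);
      }
      {
        mat w(q.bfc), d(g.bfc), mm(m.bfc), vv(v.bfc);
        adam_update(w, d, mm, vv, lr, b1, b2, eps, step);
        q.bfc = w.col(0); m.bfc = mm.col(0); v.bfc = vv.col(0);
      }
      done += bsz;
    }
    epoch_loss /= N;
    loss_hist.push_back(epoch_loss);
    epochs_run = e + 1;
    if (epoch_loss < best - tol) {
      best = epoch_loss;
      stall = 0;
    } else if (++stall >= patience) {
      break;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("params") = pack(q),
      Rcpp::Named("loss_history") = loss_hist,
      Rcpp::Named("initial_loss") = initial_loss,
      Rcpp::Named("epochs_run") = epochs_run);
}
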