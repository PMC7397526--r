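#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Online delta-rule training of the single-layer softmax network.
//
// W          : (n_verbs + 1 + n_sem + 1) x 3 initial weights (not modified)
// sem        : n_verbs x n_sem unit-interval semantic activations
// probs      : length 3*n_verbs sampling probabilities, verb-major order
//              (LESS, MORE, OTHER) per verb; sums to 1
// lambda_step: per-update decay; the update is
//              W <- W*(1 - eta*lambda_step) + eta*(t - y) x
// judge_idx  : 0-based verbs judged (causative unit = 1, learning off) after
//              every epoch and once before training (epoch 0)
//
// Consumes one unif_rand() per utterance, matching the pure-R engine.
// [[Rcpp::export]]
List cpp_train(NumericMatrix W, NumericMatrix sem, NumericVector probs,
               double eta, double lambda_step, int epochs,
               int utterances_per_epoch, IntegerVector judge_idx) {
  const int n_verbs = sem.nrow();
  const int n_sem = sem.ncol();
  const int d = n_verbs + 1 + n_sem + 1;
  const int K = W.ncol();
  if (W.nrow() != d) stop("weight matrix has %d rows, expected %d", W.nrow(), d);
  if (K != 3) stop("expected 3 output units");
  if (probs.size() != 3 * n_verbs) stop("probs must have 3*n_verbs entries");

  std::vector<double> w(W.begin(), W.end());  // column-major copy
  std::vector<double> cum(probs.size());
  std::partial_sum(probs.begin(), probs.end(), cum.begin());
  cum.back() = 1.0;

  const int n_judge = judge_idx.size();
  NumericVector acts(Dimension(n_judge, K, epochs + 1));
  const int causative_row = n_verbs;
  const int bias_row = d - 1;

  // forward pass on the (<= 7 nonzero) active input rows
  int active[16];
  double xval[16];
  double net[3], y[3];
  auto forward = [&](int n_active) {
    double mx = R_NegInf;
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      const double* col = &w[(size_t)j * d];
      for (int a = 0; a < n_active; ++a) s += col[active[a]] * xval[a];
      net[j] = s;
      if (s > mx) mx = s;
    }
    double tot = 0.0;
    for (int j = 0; j < K; ++j) { y[j] = std::exp(net[j] - mx); tot += y[j]; }
    for (int j = 0; j < K; ++j) y[j] /= tot;
  };
  auto encode = [&](int v, bool causative) {
    int n_active = 0;
    active[n_active] = v; xval[n_active++] = 1.0;
    if (causative) { active[n_active] = causative_row; xval[n_active++] = 1.0; }
    for (int s = 0; s < n_sem; ++s) {
      active[n_active] = n_verbs + 1 + s;
      xval[n_active++] = sem(v, s);
    }
    active[n_active] = bias_row; xval[n_active++] = 1.0;
    return n_active;
  };
  auto judge_epoch = [&](int ep) {
    for (int q = 0; q < n_judge; ++q) {
      int n_active = encode(judge_idx[q], true);
      forward(n_active);
      for (int j = 0; j < K; ++j)
        acts[q + n_judge * (j + K * ep)] = y[j];
    }
  };

  judge_epoch(0);
  const double shrink = 1.0 - eta * lambda_step;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int it = 0; it < utterances_per_epoch; ++it) {
      double u = unif_rand();
      int cell = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
      if (cell >= (int)cum.size()) cell = (int)cum.size() - 1;
      int v = cell / 3;
      int form = cell % 3;  // 0 LESS, 1 MORE, 2 OTHER
      int n_active = encode(v, form != 2);
      forward(n_active);
      if (shrink != 1.0)
        for (size_t k = 0; k < w.size(); ++k) w[k] *= shrink;
      for (int j = 0; j < K; ++j) {
        double err = ((j == form) ? 1.0 : 0.0) - y[j];
        double step = eta * err;
        double* col = &w[(size_t)j * d];
        for (int a = 0; a < n_active; ++a) col[active[a]] += step * xval[a];
      }
    }
    judge_epoch(ep + 1);
  }

  NumericMatrix Wout(d, K);
  std::copy(w.begin(), w.end(), Wout.begin());
  return List::create(_["W"] = Wout, _["activations"] = acts);
}
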