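// Inner loops of the linear-chain CRF: log-domain forward-backward and
// the penalized negative log-likelihood with its exact gradient,
// accumulated over a whole corpus.  All structure (masking, observation
// sharing) arrives pre-encoded: trans_slot > 0 marks a permitted
// transition and names its parameter; obs_slot > 0 names the parameter
// of a (binding target, symbol) pair.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double log_sum_exp(const std::vector<double>& v) {
  double m = NEG_INF;
  for (double x : v) if (x > m) m = x;
  if (m == NEG_INF) return NEG_INF;
  double s = 0.0;
  for (double x : v) s += std::exp(x - m);
  return m + std::log(s);
}

// [[Rcpp::export]]
List cpp_corpus_nll_grad(List obs_ids, List gold_states,
                         IntegerMatrix obs_slot,
                         IntegerVector target_of_state,
                         IntegerMatrix trans_slot,
                         NumericVector weights, double inv_sigma2) {
  const int n_sent = obs_ids.size();
  const int N = trans_slot.ncol();          // emitting states
  const int G = obs_slot.nrow();            // binding targets
  const int K = weights.size();
  double ll = 0.0;
  NumericVector grad(K);                    // of the negative LL

  // transition weight cache (NEG_INF = forbidden), rows 0..N-1 emitting,
  // row N = start
  std::vector<double> tw((N + 1) * N, NEG_INF);
  for (int i = 0; i <= N; ++i)
    for (int j = 0; j < N; ++j) {
      int k = trans_slot(i, j);
      if (k > 0) tw[i * N + j] = weights[k - 1];
    }

  for (int s = 0; s < n_sent; ++s) {
    List sobs = obs_ids[s];
    IntegerVector gold = gold_states[s];
    const int T = sobs.size();
    if (T == 0) continue;

    // per-target observation scores, then per-state node scores
    std::vector<double> tscore((size_t)G * T, 0.0);
    for (int t = 0; t < T; ++t) {
      IntegerVector ids = sobs[t];
      for (int a = 0; a < ids.size(); ++a) {
        int sym = ids[a] - 1;
        for (int g = 0; g < G; ++g) {
          int k = obs_slot(g, sym);
          if (k > 0) tscore[(size_t)g * T + t] += weights[k - 1];
        }
      }
    }
    std::vector<double> node((size_t)N * T);
    for (int t = 0; t < T; ++t)
      for (int j = 0; j < N; ++j)
        node[(size_t)j * T + t] =
          tscore[(size_t)(target_of_state[j] - 1) * T + t];

    // forward
    std::vector<double> la((size_t)N * T), lb((size_t)N * T);
    for (int j = 0; j < N; ++j)
      la[(size_t)j * T] = tw[N * N + j] + node[(size_t)j * T];
    std::vector<double> buf(N);
    for (int t = 1; t < T; ++t) {
      for (int j = 0; j < N; ++j) {
        for (int i = 0; i < N; ++i)
          buf[i] = la[(size_t)i * T + t - 1] + tw[i * N + j];
        la[(size_t)j * T + t] = log_sum_exp(buf) + node[(size_t)j * T + t];
      }
    }
    for (int j = 0; j < N; ++j) buf[j] = la[(size_t)j * T + T - 1];
    const double logZ = log_sum_exp(buf);
    if (!std::isfinite(logZ))
      stop("infeasible lattice: all paths masked (sentence %d)", s + 1);

    // backward
    for (int j = 0; j < N; ++j) lb[(size_t)j * T + T - 1] = 0.0;
    for (int t = T - 2; t >= 0; --t) {
      for (int i = 0; i < N; ++i) {
        for (int j = 0; j < N; ++j)
          buf[j] = tw[i * N + j] + node[(size_t)j * T + t + 1] +
                   lb[(size_t)j * T + t + 1];
        lb[(size_t)i * T + t] = log_sum_exp(buf);
      }
    }

    // gold path score and empirical counts
    int prev = N;                             // start row
    for (int t = 0; t < T; ++t) {
      int y = gold[t] - 1;
      int kt = trans_slot(prev, y);
      if (kt <= 0)
        stop("gold sequence violates the transition mask (sentence %d, position %d)",
             s + 1, t + 1);
      ll += tw[prev * N + y] + node[(size_t)y * T + t];
      grad[kt - 1] -= 1.0;
      IntegerVector ids = sobs[t];
      int g = target_of_state[y] - 1;
      for (int a = 0; a < ids.size(); ++a) {
        int k = obs_slot(g, ids[a] - 1);
        if (k > 0) grad[k - 1] -= 1.0;
      }
      prev = y;
    }
    ll -= logZ;

    // expected counts: node marginals
    std::vector<double> tmarg((size_t)G * T, 0.0);
    for (int t = 0; t < T; ++t) {
      for (int j = 0; j < N; ++j) {
        double m = std::exp(la[(size_t)j * T + t] +
                            lb[(size_t)j * T + t] - logZ);
        if (m > 0.0)
          tmarg[(size_t)(target_of_state[j] - 1) * T + t] += m;
      }
      IntegerVector ids = sobs[t];
      for (int a = 0; a < ids.size(); ++a) {
        int sym = ids[a] - 1;
        for (int g = 0; g < G; ++g) {
          int k = obs_slot(g, sym);
          if (k > 0) grad[k - 1] += tmarg[(size_t)g * T + t];
        }
      }
    }
    // expected counts: transitions (start, then interior)
    for (int j = 0; j < N; ++j) {
      int k = trans_slot(N, j);
      if (k > 0) {
        double m = std::exp(la[(size_t)j * T] + lb[(size_t)j * T] - logZ);
        grad[k - 1] += m;
      }
    }
    for (int t = 1; t < T; ++t) {
      for (int i = 0; i < N; ++i) {
        double ai = la[(size_t)i * T + t - 1];
        if (ai == NEG_INF) continue;
        for (int j = 0; j < N; ++j) {
          int k = trans_slot(i, j);
          if (k <= 0) continue;
          double m = std::exp(ai + tw[i * N + j] +
                              node[(size_t)j * T + t] +
                              lb[(size_t)j * T + t] - logZ);
          grad[k - 1] += m;
        }
      }
    }
  }

  // l2 penalty: nll = -ll + 0.5 * inv_sigma2 * sum(w^2)
  double pen = 0.0;
  if (inv_sigma2 > 0.0) {
    for (int k = 0; k < K; ++k) {
      pen += 0.5 * inv_sigma2 * weights[k] * weights[k];
      grad[k] += inv_sigma2 * weights[k];
    }
  }
  return List::create(_["nll"] = -ll + pen, _["grad"] = grad);
}
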