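#include <Rcpp.h>
using namespace Rcpp;

// Payoff kinds: 0 constant (p1 = value), 1 gaussian (p1 = mean, p2 = sd),
// 2 two-point (p1 = low, p2 = high, p3 = p_low).
static inline double draw_payoff_kind(int kind, double p1, double p2, double p3) {
  switch (kind) {
  case 0: return p1;
  case 1: return R::rnorm(p1, p2);
  default: return (R::runif(0.0, 1.0) < p3) ? p1 : p2;
  }
}

// stable softmax into prob[]
static inline void softmax_into(const double *q, int K, double beta,
                                double *prob) {
  double m = beta * q[0];
  for (int k = 1; k < K; ++k) m = std::max(m, beta * q[k]);
  double s = 0.0;
  for (int k = 0; k < K; ++k) { prob[k] = std::exp(beta * q[k] - m); s += prob[k]; }
  for (int k = 0; k < K; ++k) prob[k] /= s;
}

// conformity weights from smoothed counts, log-space for large |theta|
static inline void conformity_into(const double *cnt, int K, double theta,
                                   double *w) {
  double m = -1e300;
  for (int k = 0; k < K; ++k) {
    w[k] = theta * std::log(cnt[k] + 0.1);
    if (w[k] > m) m = w[k];
  }
  double s = 0.0;
  for (int k = 0; k < K; ++k) { w[k] = std::exp(w[k] - m); s += w[k]; }
  for (int k = 0; k < K; ++k) w[k] /= s;
}

// Synchronous group bandit sessions. Agents are partitioned into groups by
// `group` (0-based). Choice at trial t uses the counts of choices made at
// t-1 by group members who completed t-1 (own previous choice excluded when
// exclude_self). Variant: 0 asocial, 1 decision-biasing, 2 value-shaping.
// last_trial[i] is the last trial agent i completes (dropout truncation).
// [[Rcpp::export]]
List sim_engine_cpp(IntegerVector opt_kind, NumericVector p1, NumericVector p2,
                    NumericVector p3, int horizon, double payoff_scale,
                    NumericVector alpha, NumericVector beta,
                    NumericVector sigma, NumericVector theta,
                    IntegerVector variant, IntegerVector group, int n_groups,
                    IntegerVector last_trial, bool exclude_self,
                    int target_option, int half_start, bool record) {
  const int K = opt_kind.size();
  const int n = alpha.size();
  const int T = horizon;

  std::vector<double> Q((size_t)n * K, 0.0);
  std::vector<int> prev_choice(n, -1);      // choice at t-1, -1 if none
  std::vector<double> gcnt((size_t)n_groups * K, 0.0); // group counts at t-1
  std::vector<double> prob(K), conf(K), cnt_self(K);

  std::vector<int> target_hits(n, 0), second_n(n, 0);

  IntegerMatrix choice_rec;
  NumericMatrix payoff_rec;
  IntegerMatrix counts_rec;
  if (record) {
    choice_rec = IntegerMatrix(n, T);
    payoff_rec = NumericMatrix(n, T);
    counts_rec = IntegerMatrix((size_t)n * T, K);
    std::fill(choice_rec.begin(), choice_rec.end(), NA_INTEGER);
    std::fill(payoff_rec.begin(), payoff_rec.end(), NA_REAL);
    std::fill(counts_rec.begin(), counts_rec.end(), NA_INTEGER);
  }

  for (int t = 1; t <= T; ++t) {
    // group counts of choices made at t-1 by members who completed t-1
    std::fill(gcnt.begin(), gcnt.end(), 0.0);
    if (t > 1) {
      for (int i = 0; i < n; ++i) {
        if (prev_choice[i] >= 0) gcnt[(size_t)group[i] * K + prev_choice[i]] += 1.0;
      }
    }
    for (int i = 0; i < n; ++i) {
      if (t > last_trial[i]) { prev_choice[i] = -1; continue; }
      const double *qi = &Q[(size_t)i * K];
      softmax_into(qi, K, beta[i], prob.data());

      bool have_social = (t > 1) && sigma[i] > 0.0;
      if (have_social) {
        const double *gc = &gcnt[(size_t)group[i] * K];
        for (int k = 0; k < K; ++k) cnt_self[k] = gc[k];
        if (exclude_self && prev_choice[i] >= 0) cnt_self[prev_choice[i]] -= 1.0;
        conformity_into(cnt_self.data(), K, theta[i], conf.data());
      }
      if (have_social && variant[i] == 1) {
        for (int k = 0; k < K; ++k)
          prob[k] = (1.0 - sigma[i]) * prob[k] + sigma[i] * conf[k];
      }
      // sample the choice
      double u = R::runif(0.0, 1.0), acc = 0.0;
      int ch = K - 1;
      for (int k = 0; k < K; ++k) { acc += prob[k]; if (u < acc) { ch = k; break; } }

      double pay = draw_payoff_kind(opt_kind[ch], p1[ch], p2[ch], p3[ch]);
      double spay = pay * payoff_scale;
      double *qm = &Q[(size_t)i * K];
      qm[ch] = (1.0 - alpha[i]) * qm[ch] + alpha[i] * spay;
      if (have_social && variant[i] == 2) {
        for (int k = 0; k < K; ++k)
          qm[k] += sigma[i] * (conf[k] - 1.0 / K);
      }

      if (record) {
        choice_rec(i, t - 1) = ch + 1;
        payoff_rec(i, t - 1) = pay;
        size_t row = (size_t)i * T + (t - 1);
        if (t == 1) {
          for (int k = 0; k < K; ++k) counts_rec(row, k) = 0;
        } else {
          const double *gc = &gcnt[(size_t)group[i] * K];
          for (int k = 0; k < K; ++k) {
            double c = gc[k];
            if (exclude_self && prev_choice[i] == k) c -= 1.0;
            counts_rec(row, k) = (int)std::lround(c);
          }
        }
      }
      if (t > half_start) {
        second_n[i] += 1;
        if (ch == target_option) target_hits[i] += 1;
      }
      prev_choice[i] = ch;
    }
  }

  NumericVector prop(n);
  IntegerVector nsec(n);
  for (int i = 0; i < n; ++i) {
    nsec[i] = second_n[i];
    prop[i] = second_n[i] > 0 ? (double)target_hits[i] / second_n[i] : NA_REAL;
  }
  List out = List::create(_["prop_target"] = prop, _["n_second_half"] = nsec);
  if (record) {
    out["choices"] = choice_rec;
    out["payoffs"] = payoff_rec;
    out["counts"] = counts_rec;
  }
  return out;
}
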