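#include <Rcpp.h>
using namespace Rcpp;

// Replay a subject's choice record under the learning model and return the
// per-trial log-likelihood. Beliefs are reconstructed from the subject's own
// observed payoffs (already on the learning scale); social counts are the
// displayed (lagged) counts stored with the data. Variant: 0 asocial,
// 1 decision-biasing, 2 value-shaping. Trial 1 is always asocial softmax.
static void subject_pointwise(const int *choices, const double *payoffs,
                              const double *counts, int T, int K,
                              double alpha, double beta, double sigma,
                              double theta, int variant, double *out) {
  std::vector<double> Q(K, 0.0), conf(K);
  for (int t = 0; t < T; ++t) {
    int ch = choices[t] - 1;
    bool social = (t > 0) && sigma > 0.0 && variant != 0;
    if (social) {
      double m = -1e300;
      for (int k = 0; k < K; ++k) {
        conf[k] = theta * std::log(counts[(size_t)t * K + k] + 0.1);
        if (conf[k] > m) m = conf[k];
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) { conf[k] = std::exp(conf[k] - m); s += conf[k]; }
      for (int k = 0; k < K; ++k) conf[k] /= s;
    }
    // stable log softmax
    double m = beta * Q[0];
    for (int k = 1; k < K; ++k) m = std::max(m, beta * Q[k]);
    double lse = 0.0;
    for (int k = 0; k < K; ++k) lse += std::exp(beta * Q[k] - m);
    lse = m + std::log(lse);

    double lp;
    if (social && variant == 1) {
      double a = std::exp(beta * Q[ch] - lse);
      double p = (1.0 - sigma) * a + sigma * conf[ch];
      lp = std::log(p);
    } else {
      lp = beta * Q[ch] - lse;
    }
    out[t] = lp;

    Q[ch] = (1.0 - alpha) * Q[ch] + alpha * payoffs[t];
    if (social && variant == 2) {
      for (int k = 0; k < K; ++k) Q[k] += sigma * (conf[k] - 1.0 / K);
    }
  }
}

// [[Rcpp::export]]
NumericVector subject_pointwise_cpp(IntegerVector choices, NumericVector payoffs,
                                    NumericMatrix counts, double alpha,
                                    double beta, double sigma, double theta,
                                    int variant) {
  int T = choices.size(), K = counts.ncol();
  // counts arrives row-major per trial: flatten as t*K + k
  std::vector<double> cn((size_t)T * K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) cn[(size_t)t * K + k] = counts(t, k);
  NumericVector out(T);
  subject_pointwise(choices.begin(), payoffs.begin(), cn.data(), T, K,
                    alpha, beta, sigma, theta, variant, out.begin());
  for (int t = 0; t < T; ++t) {
    if (!std::isfinite(out[t]))
      stop("non-finite choice log-probability at trial %d", t + 1);
  }
  return out;
}

struct HierData {
  std::vector<int> choices;
  std::vector<double> payoffs;
  std::vector<double> counts; // total_T x K, row-major per trial
  std::vector<int> offset;    // n_subj + 1
  std::vector<int> sub_variant;
  std::vector<int> social;    // per subject: 1 if sigma/theta apply
  int K;
};

static double subject_ll(const HierData &d, int i, double alpha, double beta,
                         double sigma, double theta) {
  int a = d.offset[i], b = d.offset[i + 1], T = b - a;
  std::vector<double> pw(T);
  subject_pointwise(&d.choices[a], &d.payoffs[a], &d.counts[(size_t)a * d.K],
                    T, d.K, alpha, beta, sigma, theta, d.sub_variant[i],
                    pw.data());
  double s = 0.0;
  for (int t = 0; t < T; ++t) s += pw[t];
  return std::isfinite(s) ? s : -1e300;
}

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// half-Student-t(4, 0, 1) log density for scale parameters (unnormalised)
static inline double lp_half_t(double v) {
  if (v <= 0) return -1e300;
  return -2.5 * std::log1p(v * v / 4.0);
}

// Adaptive random-walk Metropolis-within-Gibbs for the non-centred
// hierarchical model:
//   alpha_i = logistic(mu_a + v_a z_ai), beta_i = exp(mu_b + v_b z_bi),
//   sigma_i = logistic(mu_s + v_s z_si), theta_i = mu_t + v_t z_ti,
//   z ~ N(0,1), mu ~ N(0, prior_mu_sd), v ~ half-t(4,0,1).
// Social blocks (sigma, theta) are dropped when social = 0 for all subjects.
// Returns draws of globals and z, plus the pointwise log-lik matrix.
// [[Rcpp::export]]
List fit_hier_chain_cpp(IntegerVector choices, NumericVector payoffs,
                        NumericMatrix counts, IntegerVector offset,
                        IntegerVector sub_variant, IntegerVector social,
                        int n_warmup, int n_draws, double prior_mu_sd,
                        NumericVector init_mu, NumericVector init_logv,
                        bool store_pointwise) {
  const int n_subj = offset.size() - 1;
  const int K = counts.ncol();
  const int total_T = choices.size();
  const bool any_social = *std::max_element(social.begin(), social.end()) > 0;
  const int np = any_social ? 4 : 2; // parameter blocks in play

  HierData d;
  d.K = K;
  d.choices.assign(choices.begin(), choices.end());
  d.payoffs.assign(payoffs.begin(), payoffs.end());
  d.counts.resize((size_t)total_T * K);
  for (int t = 0; t < total_T; ++t)
    for (int k = 0; k < K; ++k) d.counts[(size_t)t * K + k] = counts(t, k);
  d.offset.assign(offset.begin(), offset.end());
  d.sub_variant.assign(sub_variant.begin(), sub_variant.end());
  d.social.assign(social.begin(), social.end());

  // state: mu[4], logv[4], z[n_subj][4]; unused blocks stay at 0
  std::vector<double> mu(4, 0.0), logv(4, std::log(0.5));
  for (int p = 0; p < 4; ++p) { mu[p] = init_mu[p]; logv[p] = init_logv[p]; }
  std::vector<double> z((size_t)n_subj * 4, 0.0);

  auto transform = [&](int i, double *out4) {
    double va = std::exp(logv[0]), vb = std::exp(logv[1]);
    double vs = std::exp(logv[2]), vt = std::exp(logv[3]);
    out4[0] = logistic(mu[0] + va * z[(size_t)i * 4 + 0]);
    out4[1] = std::exp(mu[1] + vb * z[(size_t)i * 4 + 1]);
    if (d.social[i]) {
      out4[2] = logistic(mu[2] + vs * z[(size_t)i * 4 + 2]);
      out4[3] = mu[3] + vt * z[(size_t)i * 4 + 3];
    } else {
      out4[2] = 0.0;
      out4[3] = 0.0;
    }
  };

  std::vector<double> ll(n_subj);
  auto refresh_ll = [&](int i) {
    double th[4];
    transform(i, th);
    ll[i] = subject_ll(d, i, th[0], th[1], th[2], th[3]);
  };
  for (int i = 0; i < n_subj; ++i) refresh_ll(i);

  // proposal scales
  std::vector<double> sc_z((size_t)n_subj * 4, 0.5);
  std::vector<double> sc_mu(4, 0.1), sc_lv(4, 0.2);
  std::vector<double> acc_z((size_t)n_subj * 4, 0.0);
  std::vector<double> acc_mu(4, 0.0), acc_lv(4, 0.0);
  const int batch = 50;

  const int n_iter = n_warmup + n_draws;
  NumericMatrix draws_glob(n_draws, 8);
  NumericMatrix draws_z(n_draws, n_subj * 4);
  NumericMatrix pw_ll;
  if (store_pointwise) pw_ll = NumericMatrix(n_draws, total_T);

  // which parameter blocks apply to subject i
  auto blocks_for = [&](int i) { return d.social[i] ? 4 : 2; };

  for (int iter = 0; iter < n_iter; ++iter) {
    // --- subject-level z updates (component-wise, two sweeps per
    //     iteration: subject blocks are the mixing bottleneck) ---
    for (int sweep = 0; sweep < 2; ++sweep)
    for (int i = 0; i < n_subj; ++i) {
      int nb = blocks_for(i);
      for (int p = 0; p < nb; ++p) {
        size_t idx = (size_t)i * 4 + p;
        double z0 = z[idx];
        double zp = z0 + sc_z[idx] * R::norm_rand();
        double th[4];
        z[idx] = zp;
        transform(i, th);
        double ll_new = subject_ll(d, i, th[0], th[1], th[2], th[3]);
        double lr = ll_new - ll[i] - 0.5 * (zp * zp - z0 * z0);
        if (std::log(R::unif_rand()) < lr) {
          ll[i] = ll_new;
          acc_z[idx] += 1.0;
        } else {
          z[idx] = z0;
        }
      }
    }
    // --- global updates: mu_p and log v_p ---
    for (int p = 0; p < np; ++p) {
      // mu_p
      {
        double m0 = mu[p];
        double mp = m0 + sc_mu[p] * R::norm_rand();
        mu[p] = mp;
        double ll_new_tot = 0.0, ll_old_tot = 0.0;
        std::vector<double> ll_new(n_subj);
        for (int i = 0; i < n_subj; ++i) {
          if (p >= 2 && !d.social[i]) { ll_new[i] = ll[i]; }
          else {
            double th[4]; transform(i, th);
            ll_new[i] = subject_ll(d, i, th[0], th[1], th[2], th[3]);
          }
          ll_new_tot += ll_new[i];
          ll_old_tot += ll[i];
        }
        double lr = ll_new_tot - ll_old_tot
          - 0.5 * (mp * mp - m0 * m0) / (prior_mu_sd * prior_mu_sd);
        if (std::log(R::unif_rand()) < lr) {
          ll = ll_new;
          acc_mu[p] += 1.0;
        } else {
          mu[p] = m0;
        }
      }
      // log v_p (half-t prior with log-scale Jacobian)
      {
        double l0 = logv[p];
        double lp_ = l0 + sc_lv[p] * R::norm_rand();
        logv[p] = lp_;
        double ll_new_tot = 0.0, ll_old_tot = 0.0;
        std::vector<double> ll_new(n_subj);
        for (int i = 0; i < n_subj; ++i) {
          if (p >= 2 && !d.social[i]) { ll_new[i] = ll[i]; }
          else {
            double th[4]; transform(i, th);
            ll_new[i] = subject_ll(d, i, th[0], th[1], th[2], th[3]);
          }
          ll_new_tot += ll_new[i];
          ll_old_tot += ll[i];
        }
        double lr = ll_new_tot - ll_old_tot
          + lp_half_t(std::exp(lp_)) + lp_
          - lp_half_t(std::exp(l0)) - l0;
        if (std::log(R::unif_rand()) < lr) {
          ll = ll_new;
          acc_lv[p] += 1.0;
        } else {
          logv[p] = l0;
        }
      }
    }

    // --- interweaved centred-parameterisation update of (mu_p, v_p) ---
    // Holding the individual transformed effects x_i = mu_p + v_p z_i fixed
    // (so the likelihood is unchanged), mu_p has a conjugate normal
    // conditional and v_p is updated by MH on the log scale against
    // N(x | mu, v^2) * half-t(v); z is then refreshed as (x - mu)/v.
    // This interweaving decorrelates the globals from the subject effects.
    for (int p = 0; p < np; ++p) {
      std::vector<double> x;
      std::vector<int> who;
      for (int i = 0; i < n_subj; ++i) {
        if (p >= 2 && !d.social[i]) continue;
        who.push_back(i);
        x.push_back(mu[p] + std::exp(logv[p]) * z[(size_t)i * 4 + p]);
      }
      int m = (int)x.size();
      if (m == 0) continue;
      double v = std::exp(logv[p]);
      double v2 = v * v;
      // mu | x, v  (prior N(0, prior_mu_sd^2))
      double prec = m / v2 + 1.0 / (prior_mu_sd * prior_mu_sd);
      double sx = 0.0;
      for (double xi : x) sx += xi;
      double mu_new = sx / v2 / prec + R::norm_rand() / std::sqrt(prec);
      mu[p] = mu_new;
      // v | x, mu via 3 MH steps on log v
      double ss = 0.0;
      for (double xi : x) ss += (xi - mu_new) * (xi - mu_new);
      auto lp_v = [&](double lv) {
        double vv = std::exp(lv);
        return -m * lv - 0.5 * ss / (vv * vv) + lp_half_t(vv) + lv;
      };
      double lv_cur = logv[p];
      double lp_cur = lp_v(lv_cur);
      for (int s = 0; s < 3; ++s) {
        double lv_prop = lv_cur + 0.3 * R::norm_rand();
        double lp_prop = lp_v(lv_prop);
        if (std::log(R::unif_rand()) < lp_prop - lp_cur) {
          lv_cur = lv_prop;
          lp_cur = lp_prop;
        }
      }
      logv[p] = std::max(lv_cur, -10.0);
      double v_new = std::exp(logv[p]);
      for (int j = 0; j < m; ++j) {
        z[(size_t)who[j] * 4 + p] = (x[j] - mu_new) / v_new;
      }
    }

    // --- warmup adaptation (Robbins-Monro toward 0.44 acceptance) ---
    if (iter < n_warmup && (iter + 1) % batch == 0) {
      double step = std::min(0.25, 2.0 / std::sqrt((double)(iter + 1)));
      for (size_t j = 0; j < sc_z.size(); ++j) {
        sc_z[j] *= std::exp(step * (acc_z[j] / (2.0 * batch) - 0.44));
        acc_z[j] = 0.0;
      }
      for (int p = 0; p < 4; ++p) {
        sc_mu[p] *= std::exp(step * (acc_mu[p] / batch - 0.44));
        sc_lv[p] *= std::exp(step * (acc_lv[p] / batch - 0.44));
        acc_mu[p] = acc_lv[p] = 0.0;
      }
    }

    // --- store ---
    if (iter >= n_warmup) {
      int s = iter - n_warmup;
      for (int p = 0; p < 4; ++p) {
        draws_glob(s, p) = mu[p];
        draws_glob(s, 4 + p) = std::exp(logv[p]);
      }
      for (size_t j = 0; j < z.size(); ++j) draws_z(s, j) = z[j];
      if (store_pointwise) {
        for (int i = 0; i < n_subj; ++i) {
          double th[4];
          transform(i, th);
          int a = d.offset[i], b = d.offset[i + 1];
          std::vector<double> pw(b - a);
          subject_pointwise(&d.choices[a], &d.payoffs[a],
                            &d.counts[(size_t)a * K], b - a, K,
                            th[0], th[1], th[2], th[3], d.sub_variant[i],
                            pw.data());
          for (int t = a; t < b; ++t) pw_ll(s, t) = pw[t - a];
        }
      }
    }
    if ((iter + 1) % 200 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(_["globals"] = draws_glob, _["z"] = draws_z);
  if (store_pointwise) out["pointwise"] = pw_ll;
  return out;
}
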