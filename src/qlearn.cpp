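#include <Rcpp.h>
using namespace Rcpp;

// Sequential Q-learning log-likelihood for one subject's trial list.
// chosen/unchosen are 0-based stimulus indices, reward is 0/1.
// Probabilities are floored at 1e-12 before the log.
static double seq_loglik(const int *chosen, const int *unchosen,
                         const int *reward, int n_trials, int n_stim,
                         double alpha_high, double alpha_low, double beta,
                         double q_init, double *qbuf) {
  for (int s = 0; s < n_stim; ++s) qbuf[s] = q_init;
  double ll = 0.0;
  for (int t = 0; t < n_trials; ++t) {
    const int ch = chosen[t], un = unchosen[t];
    // stable softmax on the (chosen - unchosen) value difference
    const double d = beta * (qbuf[ch] - qbuf[un]);
    double p;
    if (d > 0) p = 1.0 / (1.0 + std::exp(-d));
    else {
      const double e = std::exp(d);
      p = e / (1.0 + e);
    }
    if (p < 1e-12) p = 1e-12;
    ll += std::log(p);
    const double alpha = reward[t] == 1 ? alpha_high : alpha_low;
    qbuf[ch] += alpha * (reward[t] - qbuf[ch]);
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_seq_loglik(IntegerVector chosen, IntegerVector unchosen,
                      IntegerVector reward, int n_stim,
                      double alpha_high, double alpha_low, double beta,
                      double q_init) {
  std::vector<double> q(n_stim);
  return seq_loglik(chosen.begin(), unchosen.begin(), reward.begin(),
                    chosen.size(), n_stim, alpha_high, alpha_low, beta,
                    q_init, q.data());
}

struct SubjData {
  const int *chosen, *unchosen, *reward;
  int n;
};

// loglik of subject `sd` under probit-scale parameters z (length P).
// P == 3: (z_aH, z_aL, z_beta); P == 2: (z_alpha, z_beta).
static double subj_ll(const SubjData &sd, const double *z, int P,
                      int n_stim, double q_init, double *qbuf) {
  double aH, aL, beta;
  if (P == 3) {
    aH = R::pnorm(z[0], 0.0, 1.0, 1, 0);
    aL = R::pnorm(z[1], 0.0, 1.0, 1, 0);
    beta = 100.0 * R::pnorm(z[2], 0.0, 1.0, 1, 0);
  } else {
    aH = aL = R::pnorm(z[0], 0.0, 1.0, 1, 0);
    beta = 100.0 * R::pnorm(z[1], 0.0, 1.0, 1, 0);
  }
  return seq_loglik(sd.chosen, sd.unchosen, sd.reward, sd.n, n_stim,
                    aH, aL, beta, q_init, qbuf);
}

// One MCMC chain for the hierarchical probit model.
//
// Metropolis-within-Gibbs sweep:
//   - each subject-level z[i][p]: random-walk Metropolis against
//     subject likelihood + N(mu_p, delta_p) group density;
//   - group means mu_p: conjugate Gibbs draw (normal prior
//     N(prior_mu, prior_mu_sd));
//   - group SDs delta_p: reflected random-walk Metropolis on the
//     uniform support (sd_lower, sd_upper).
// Proposal scales adapt toward ~0.44 acceptance during warmup only.
// Uses R's RNG, so set.seed() in R makes chains reproducible.
//
// Returns a matrix with n_keep rows and 2P + N*P columns:
// mu[1..P], delta[1..P], then z by subject (subject-major).
// [[Rcpp::export]]
NumericMatrix cpp_mcmc_chain(IntegerVector subj_offsets, IntegerVector chosen,
                             IntegerVector unchosen, IntegerVector reward,
                             int n_stim, int n_params, double q_init,
                             double prior_mu, double prior_mu_sd,
                             double sd_lower, double sd_upper,
                             int n_warmup, int n_keep, int thin) {
  const int N = subj_offsets.size() - 1;
  const int P = n_params;
  std::vector<SubjData> subj(N);
  for (int i = 0; i < N; ++i) {
    subj[i].chosen = chosen.begin() + subj_offsets[i];
    subj[i].unchosen = unchosen.begin() + subj_offsets[i];
    subj[i].reward = reward.begin() + subj_offsets[i];
    subj[i].n = subj_offsets[i + 1] - subj_offsets[i];
  }
  std::vector<double> qbuf(n_stim);

  // state
  std::vector<double> z(N * P), mu(P), delta(P, 0.5 * (sd_lower + sd_upper));
  for (int p = 0; p < P; ++p) mu[p] = 0.1 * norm_rand();
  for (int i = 0; i < N; ++i)
    for (int p = 0; p < P; ++p) z[i * P + p] = 0.1 * norm_rand();

  std::vector<double> cur_ll(N);
  for (int i = 0; i < N; ++i)
    cur_ll[i] = subj_ll(subj[i], &z[i * P], P, n_stim, q_init, qbuf.data());

  std::vector<double> z_scale(N * P, 0.3), t_scale(P, 0.1), r_scale(P, 0.3),
    prop_ll(N);
  const double target = 0.44;

  // per-subject running moments for joint adaptive-Metropolis proposals
  std::vector<double> am_mean(N * P, 0.0), am_cov(N * P * P, 0.0);
  std::vector<double> am_scale(N, 1.0);
  double am_n = 0.0;

  const int n_iter = n_warmup + n_keep * thin;
  NumericMatrix out(n_keep, 2 * P + N * P);
  int kept = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    const bool adapting = iter < n_warmup;
    const double gamma = adapting ? std::min(0.25, 2.0 / std::sqrt(iter + 1.0)) : 0.0;

    // subject-level updates, componentwise
    for (int i = 0; i < N; ++i) {
      for (int p = 0; p < P; ++p) {
        const double zold = z[i * P + p];
        const double zprop = zold + z_scale[i * P + p] * norm_rand();
        z[i * P + p] = zprop;
        const double ll_prop =
          subj_ll(subj[i], &z[i * P], P, n_stim, q_init, qbuf.data());
        const double logr = (ll_prop - cur_ll[i]) +
          R::dnorm(zprop, mu[p], delta[p], 1) -
          R::dnorm(zold, mu[p], delta[p], 1);
        const bool accept = std::log(unif_rand()) < logr;
        if (accept) cur_ll[i] = ll_prop; else z[i * P + p] = zold;
        if (adapting)
          z_scale[i * P + p] *= std::exp(gamma * ((accept ? 1.0 : 0.0) - target));
      }
    }

    // joint subject-level update along the adapted covariance (helps with
    // the alpha-beta likelihood ridge that componentwise moves cross slowly)
    if (adapting) am_n += 1.0;
    for (int i = 0; i < N; ++i) {
      double *m = &am_mean[i * P], *C = &am_cov[i * P * P];
      if (adapting) {
        const double *zi = &z[i * P];
        const double w = 1.0 / am_n;
        for (int p = 0; p < P; ++p) {
          const double dlt = zi[p] - m[p];
          m[p] += w * dlt;
          for (int q = 0; q <= p; ++q)
            C[p * P + q] += w * (dlt * (zi[q] - m[q]) - C[p * P + q]);
        }
      }
      if (am_n < 50) continue;
      // Cholesky of scale^2 * (C + eps I), lower triangle
      double L[9];
      const double s2 = am_scale[i] * am_scale[i] * 2.38 * 2.38 / P;
      bool ok = true;
      for (int p = 0; p < P && ok; ++p) {
        for (int q = 0; q <= p && ok; ++q) {
          double sum = s2 * (C[p * P + q] + (p == q ? 1e-8 : 0.0));
          for (int r2 = 0; r2 < q; ++r2) sum -= L[p * P + r2] * L[q * P + r2];
          if (p == q) {
            if (sum <= 0) { ok = false; break; }
            L[p * P + p] = std::sqrt(sum);
          } else L[p * P + q] = sum / L[q * P + q];
        }
      }
      if (!ok) continue;
      double zprop[3], eps[3];
      for (int p = 0; p < P; ++p) eps[p] = norm_rand();
      for (int p = 0; p < P; ++p) {
        double step = 0.0;
        for (int q = 0; q <= p; ++q) step += L[p * P + q] * eps[q];
        zprop[p] = z[i * P + p] + step;
      }
      const double ll_prop = subj_ll(subj[i], zprop, P, n_stim, q_init, qbuf.data());
      double logr = ll_prop - cur_ll[i];
      for (int p = 0; p < P; ++p)
        logr += R::dnorm(zprop[p], mu[p], delta[p], 1) -
          R::dnorm(z[i * P + p], mu[p], delta[p], 1);
      const bool accept = std::log(unif_rand()) < logr;
      if (accept) {
        for (int p = 0; p < P; ++p) z[i * P + p] = zprop[p];
        cur_ll[i] = ll_prop;
      }
      if (adapting)
        am_scale[i] *= std::exp(gamma * ((accept ? 1.0 : 0.0) - 0.28));
    }

    // group means: conjugate normal draw
    for (int p = 0; p < P; ++p) {
      double sum = 0.0;
      for (int i = 0; i < N; ++i) sum += z[i * P + p];
      const double prec = N / (delta[p] * delta[p]) +
        1.0 / (prior_mu_sd * prior_mu_sd);
      const double mean = (sum / (delta[p] * delta[p]) +
                           prior_mu / (prior_mu_sd * prior_mu_sd)) / prec;
      mu[p] = mean + norm_rand() / std::sqrt(prec);
    }

    // group translation move: shift mu_p and every z_ip by the same
    // amount. The group-level densities are invariant, so the ratio is
    // the likelihood change plus the group-mean prior; this moves the
    // whole hierarchy along its slowest direction when pooling is tight.
    for (int p = 0; p < P; ++p) {
      const double eps = t_scale[p] * norm_rand();
      double logr = R::dnorm(mu[p] + eps, prior_mu, prior_mu_sd, 1) -
        R::dnorm(mu[p], prior_mu, prior_mu_sd, 1);
      double zi[3];
      for (int i = 0; i < N; ++i) {
        for (int q = 0; q < P; ++q) zi[q] = z[i * P + q];
        zi[p] += eps;
        prop_ll[i] = subj_ll(subj[i], zi, P, n_stim, q_init, qbuf.data());
        logr += prop_ll[i] - cur_ll[i];
      }
      const bool accept = std::log(unif_rand()) < logr;
      if (accept) {
        mu[p] += eps;
        for (int i = 0; i < N; ++i) {
          z[i * P + p] += eps;
          cur_ll[i] = prop_ll[i];
        }
      }
      if (adapting)
        t_scale[p] *= std::exp(gamma * ((accept ? 1.0 : 0.0) - target));
    }

    // group SDs: slice sampling on the bounded uniform support, with
    // shrinkage from the full interval (robust near the lower boundary)
    for (int p = 0; p < P; ++p) {
      double logf_cur = 0.0;
      for (int i = 0; i < N; ++i)
        logf_cur += R::dnorm(z[i * P + p], mu[p], delta[p], 1);
      const double slice_y = logf_cur - R::exp_rand();
      double lo = sd_lower, hi = sd_upper;
      for (int s = 0; s < 100; ++s) {
        const double dprop = lo + unif_rand() * (hi - lo);
        double logf_prop = 0.0;
        for (int i = 0; i < N; ++i)
          logf_prop += R::dnorm(z[i * P + p], mu[p], dprop, 1);
        if (logf_prop > slice_y) { delta[p] = dprop; break; }
        if (dprop < delta[p]) lo = dprop; else hi = dprop;
      }
    }

    // group rescale move: propose delta' on the log scale and move every
    // z_ip with it, holding the standardized offsets (z - mu)/delta
    // fixed. Complements the translation move by decoupling the group SD
    // from the subject parameters when pooling is tight.
    for (int p = 0; p < P; ++p) {
      const double dprop = delta[p] * std::exp(r_scale[p] * norm_rand());
      if (dprop < sd_lower || dprop > sd_upper) {
        if (adapting) r_scale[p] *= std::exp(gamma * (0.0 - target));
        continue;
      }
      const double ratio = dprop / delta[p];
      double logr = std::log(ratio); // log-RW Jacobian on delta
      double zi[3];
      for (int i = 0; i < N; ++i) {
        for (int q = 0; q < P; ++q) zi[q] = z[i * P + q];
        zi[p] = mu[p] + ratio * (z[i * P + p] - mu[p]);
        prop_ll[i] = subj_ll(subj[i], zi, P, n_stim, q_init, qbuf.data());
        logr += prop_ll[i] - cur_ll[i];
      }
      const bool accept = std::log(unif_rand()) < logr;
      if (accept) {
        for (int i = 0; i < N; ++i) {
          z[i * P + p] = mu[p] + ratio * (z[i * P + p] - mu[p]);
          cur_ll[i] = prop_ll[i];
        }
        delta[p] = dprop;
      }
      if (adapting)
        r_scale[p] *= std::exp(gamma * ((accept ? 1.0 : 0.0) - target));
    }

    if (!adapting && (iter - n_warmup + 1) % thin == 0) {
      for (int p = 0; p < P; ++p) {
        out(kept, p) = mu[p];
        out(kept, P + p) = delta[p];
      }
      for (int j = 0; j < N * P; ++j) out(kept, 2 * P + j) = z[j];
      ++kept;
      if (kept == n_keep) break;
    }
  }
  return out;
}
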