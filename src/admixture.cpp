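// Gibbs sampler for the admixture model with correlated allele frequencies
// (the F-model): each individual i carries ancestry proportions q_i over K
// clusters; each cluster k holds allele frequencies p_kl at locus l drawn
// around ancestral frequencies pa_l with drift parameter f_k,
//   p_kl ~ Dirichlet( pa_l * (1 - f_k) / f_k ).
// Allele copies x_{ilc} are assigned latent cluster origins z ~ q_i p_k(x);
// q_i ~ Dirichlet(alpha + counts); alpha, f_k and pa_l move by Metropolis
// steps. All randomness flows through R's RNG so set.seed() fixes a run.

#include <Rcpp.h>
using namespace Rcpp;

static double rgamma_safe(double shape) {
  // shape can drift small; R handles shape<1 correctly
  return R::rgamma(shape, 1.0);
}

static void rdirichlet_into(std::vector<double> &out,
                            const std::vector<double> &par) {
  double s = 0.0;
  for (size_t a = 0; a < par.size(); ++a) {
    double g = rgamma_safe(par[a]);
    if (g < 1e-300) g = 1e-300;
    out[a] = g;
    s += g;
  }
  for (size_t a = 0; a < par.size(); ++a) out[a] /= s;
}

static double ddirichlet_log(const std::vector<double> &x,
                             const std::vector<double> &par) {
  double s = 0.0, lg = 0.0;
  for (size_t a = 0; a < x.size(); ++a) {
    s += par[a];
    lg += (par[a] - 1.0) * std::log(std::max(x[a], 1e-300)) -
          R::lgammafn(par[a]);
  }
  return lg + R::lgammafn(s);
}

// [[Rcpp::export(name = ".admixture_gibbs")]]
List admixture_gibbs(IntegerMatrix a1, IntegerMatrix a2, IntegerVector ncat,
                     int K, int burnin, int reps,
                     double lambda, double alpha_init, double alpha_max,
                     double alpha_prop_sd, double f_init,
                     double f_prior_mean, double f_prior_sd) {
  const int N = a1.nrow();
  const int L = a1.ncol();
  if (reps < 1) stop("number of recorded sweeps must be >= 1");

  // state ------------------------------------------------------------------
  std::vector<std::vector<std::vector<double> > > P(K), prior(K);
  std::vector<std::vector<double> > PA(L);
  std::vector<double> F(K, f_init);
  NumericMatrix Q(N, K);
  double alpha = alpha_init;

  for (int l = 0; l < L; ++l) {
    PA[l].assign(ncat[l], 1.0 / ncat[l]);
  }
  for (int k = 0; k < K; ++k) {
    P[k].resize(L);
    prior[k].resize(L);
    for (int l = 0; l < L; ++l) {
      P[k][l].assign(ncat[l], 1.0 / ncat[l]);
      prior[k][l].assign(ncat[l], 0.0);
    }
  }
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) Q(i, k) = 1.0 / K;

  // accumulators -----------------------------------------------------------
  NumericMatrix Qsum(N, K);
  std::vector<std::vector<std::vector<double> > > Psum(K);
  for (int k = 0; k < K; ++k) {
    Psum[k].resize(L);
    for (int l = 0; l < L; ++l) Psum[k][l].assign(ncat[l], 0.0);
  }
  NumericVector loglik_trace(reps), alpha_trace(reps);

  std::vector<double> probs(K), qpar(K);
  std::vector<std::vector<double> > ccounts; // per locus: K x ncat flattened
  ccounts.resize(L);
  for (int l = 0; l < L; ++l) ccounts[l].assign((size_t)K * ncat[l], 0.0);
  std::vector<std::vector<double> > zcount(N, std::vector<double>(K, 0.0));

  const int total = burnin + reps;
  // gamma prior on f_k with given mean and sd (shape/rate parameterization)
  const double f_shape = (f_prior_mean * f_prior_mean) / (f_prior_sd * f_prior_sd);
  const double f_rate = f_prior_mean / (f_prior_sd * f_prior_sd);

  for (int sweep = 0; sweep < total; ++sweep) {
    // --- sample allele-copy origins Z and accumulate counts ---------------
    for (int l = 0; l < L; ++l)
      std::fill(ccounts[l].begin(), ccounts[l].end(), 0.0);
    for (int i = 0; i < N; ++i) std::fill(zcount[i].begin(), zcount[i].end(), 0.0);
    double loglik = 0.0;
    for (int i = 0; i < N; ++i) {
      for (int l = 0; l < L; ++l) {
        int alleles[2] = {a1(i, l), a2(i, l)};
        if (alleles[0] <= 0) continue; // missing call: drop the locus
        for (int c = 0; c < 2; ++c) {
          const int a = alleles[c] - 1;
          double s = 0.0;
          for (int k = 0; k < K; ++k) {
            probs[k] = Q(i, k) * P[k][l][a];
            s += probs[k];
          }
          loglik += std::log(std::max(s, 1e-300));
          double u = unif_rand() * s, acc = 0.0;
          int z = K - 1;
          for (int k = 0; k < K; ++k) {
            acc += probs[k];
            if (u <= acc) { z = k; break; }
          }
          ccounts[l][(size_t)z * ncat[l] + a] += 1.0;
          zcount[i][z] += 1.0;
        }
      }
    }

    // --- update P from Dirichlet posteriors under the F-model prior -------
    for (int k = 0; k < K; ++k) {
      const double scale = (1.0 - F[k]) / F[k];
      for (int l = 0; l < L; ++l) {
        std::vector<double> &par = prior[k][l];
        for (int a = 0; a < ncat[l]; ++a)
          par[a] = lambda * PA[l][a] * scale + ccounts[l][(size_t)k * ncat[l] + a];
        rdirichlet_into(P[k][l], par);
      }
    }

    // --- Metropolis update of ancestral frequencies PA --------------------
    // move a small mass between two random alleles (kept symmetric)
    for (int l = 0; l < L; ++l) {
      if (ncat[l] < 2) continue;
      int a = (int)(unif_rand() * ncat[l]);
      int b = (int)(unif_rand() * ncat[l]);
      if (a == b || a >= ncat[l] || b >= ncat[l]) continue;
      double delta = unif_rand() * 0.05;
      if (PA[l][a] - delta <= 1e-6 || PA[l][b] + delta >= 1.0 - 1e-6) continue;
      std::vector<double> pa_new = PA[l];
      pa_new[a] -= delta;
      pa_new[b] += delta;
      double lr = 0.0; // uniform prior over the simplex
      for (int k = 0; k < K; ++k) {
        const double scale = lambda * (1.0 - F[k]) / F[k];
        std::vector<double> old_par(ncat[l]), new_par(ncat[l]);
        for (int c = 0; c < ncat[l]; ++c) {
          old_par[c] = PA[l][c] * scale;
          new_par[c] = pa_new[c] * scale;
        }
        lr += ddirichlet_log(P[k][l], new_par) - ddirichlet_log(P[k][l], old_par);
      }
      if (lr >= 0.0 || unif_rand() < std::exp(lr)) PA[l] = pa_new;
    }

    // --- Metropolis update of drift parameters F (log-normal proposal) ----
    for (int k = 0; k < K; ++k) {
      double f_new = F[k] * std::exp(R::norm_rand() * 0.05);
      if (f_new <= 1e-6 || f_new >= 1.0 - 1e-6) continue;
      double lr = (f_shape - 1.0) * (std::log(f_new) - std::log(F[k])) -
                  f_rate * (f_new - F[k]) +
                  (std::log(f_new) - std::log(F[k])); // proposal asymmetry
      for (int l = 0; l < L; ++l) {
        std::vector<double> old_par(ncat[l]), new_par(ncat[l]);
        const double so = lambda * (1.0 - F[k]) / F[k];
        const double sn = lambda * (1.0 - f_new) / f_new;
        for (int c = 0; c < ncat[l]; ++c) {
          old_par[c] = PA[l][c] * so;
          new_par[c] = PA[l][c] * sn;
        }
        lr += ddirichlet_log(P[k][l], new_par) - ddirichlet_log(P[k][l], old_par);
      }
      if (lr >= 0.0 || unif_rand() < std::exp(lr)) F[k] = f_new;
    }

    // --- update Q ----------------------------------------------------------
    for (int i = 0; i < N; ++i) {
      for (int k = 0; k < K; ++k) qpar[k] = alpha + zcount[i][k];
      std::vector<double> qi(K);
      rdirichlet_into(qi, qpar);
      for (int k = 0; k < K; ++k) Q(i, k) = qi[k];
    }

    // --- Metropolis update of alpha (symmetric normal walk, U(0, max)) ----
    if (K > 1) {
      double alpha_new = alpha + R::norm_rand() * alpha_prop_sd;
      if (alpha_new > 1e-4 && alpha_new < alpha_max) {
        double lr = N * (R::lgammafn(K * alpha_new) - K * R::lgammafn(alpha_new) -
                         R::lgammafn(K * alpha) + K * R::lgammafn(alpha));
        for (int i = 0; i < N; ++i)
          for (int k = 0; k < K; ++k)
            lr += (alpha_new - alpha) * std::log(std::max(Q(i, k), 1e-300));
        if (lr >= 0.0 || unif_rand() < std::exp(lr)) alpha = alpha_new;
      }
    }

    // --- record ------------------------------------------------------------
    if (sweep >= burnin) {
      const int r = sweep - burnin;
      loglik_trace[r] = loglik;
      alpha_trace[r] = alpha;
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l)
          for (int a = 0; a < ncat[l]; ++a) Psum[k][l][a] += P[k][l][a];
    }
  }

  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= reps;
  List Pout(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix pl(K, ncat[l]);
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int a = 0; a < ncat[l]; ++a) s += Psum[k][l][a];
      for (int a = 0; a < ncat[l]; ++a) pl(k, a) = Psum[k][l][a] / s;
    }
    Pout[l] = pl;
  }
  return List::create(
    _["Q"] = Qsum, _["P"] = Pout, _["loglik"] = loglik_trace,
    _["alpha"] = alpha_trace, _["F"] = NumericVector(F.begin(), F.end()));
}
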