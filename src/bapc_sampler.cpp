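#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Binomial log-likelihood contribution of one cell, up to the lchoose
// constant: d*eta - n*log(1 + exp(eta)) for logit(q) = eta.
static inline double cell_ll(double d, double n, double eta) {
  return d * eta - n * R::log1pexp(eta);
}

// Sum of squared order-`ord` differences of x (the random-walk prior
// quadratic form).
static double rw_quadform(const std::vector<double> &x, int ord) {
  const int n = (int) x.size();
  double q = 0.0;
  if (ord == 1) {
    for (int t = 1; t < n; ++t) { double d = x[t] - x[t - 1]; q += d * d; }
  } else {
    for (int t = 2; t < n; ++t) {
      double d = x[t] - 2.0 * x[t - 1] + x[t - 2]; q += d * d;
    }
  }
  return q;
}

// Part of the RW quadratic form involving position m only.
static double rw_local(const std::vector<double> &x, int m, int ord) {
  const int n = (int) x.size();
  double q = 0.0;
  if (ord == 1) {
    if (m >= 1)     { double d = x[m] - x[m - 1];     q += d * d; }
    if (m + 1 < n)  { double d = x[m + 1] - x[m];     q += d * d; }
  } else {
    for (int t = m; t <= m + 2; ++t) {
      if (t >= 2 && t < n) {
        double d = x[t] - 2.0 * x[t - 1] + x[t - 2]; q += d * d;
      }
    }
  }
  return q;
}

struct Adapt {
  std::vector<double> lstep;   // log step size per parameter
  std::vector<int> acc, tries;
  void init(int n, double s0) {
    lstep.assign(n, std::log(s0)); acc.assign(n, 0); tries.assign(n, 0);
  }
  void tally(int m, bool a) { tries[m]++; if (a) acc[m]++; }
  void adapt(int batch) {
    double delta = std::min(0.05, 1.0 / std::sqrt((double) batch));
    for (size_t m = 0; m < lstep.size(); ++m) {
      if (tries[m] > 0) {
        double rate = (double) acc[m] / tries[m];
        lstep[m] += (rate > 0.44 ? delta : -delta);
      }
      acc[m] = 0; tries[m] = 0;
    }
  }
};

// One MCMC chain for the Bayesian age-period-cohort model on the logit of
// the death probability: D[i,j] ~ Binomial(N[i,j], plogis(eta[i,j])) with
// eta = mu + theta_i + phi_j + psi_k (+ z_ij), k = C*(I-i)+j (1-based).
// Metropolis-within-Gibbs: adaptive single-site Gaussian random-walk updates
// for mu and the effect blocks, conjugate Gamma updates for the block
// precisions. Effect-block levels are recentred into mu every iteration
// (measure-preserving: the RW priors only involve differences and mu has a
// flat prior). Uses R's RNG so chains are reproducible from set.seed().
// [[Rcpp::export]]
List bapc_chain(NumericMatrix D, NumericMatrix N, int C,
                int ord_age, int ord_per, int ord_coh, bool het,
                NumericVector prior_shape, NumericVector prior_rate,
                NumericVector fixed_prec,
                int n_iter, int n_burn, int thin) {
  const int I = D.nrow(), J = D.ncol();
  const int K = C * (I - 1) + J;
  const int ncell = I * J;

  // cells supporting each cohort parameter
  std::vector< std::vector< std::pair<int,int> > > coh_cells(K);
  for (int i = 0; i < I; ++i)
    for (int j = 0; j < J; ++j)
      coh_cells[C * (I - 1 - i) + j].push_back(std::make_pair(i, j));

  // empirical initialisation from cell logits: mu = grand mean,
  // theta/phi = row/column margins; cohort and heterogeneity start at zero
  NumericMatrix elogit(I, J);
  double mu = 0.0;
  for (int i = 0; i < I; ++i)
    for (int j = 0; j < J; ++j) {
      double p = (D(i, j) + 0.5) / (N(i, j) + 1.0);
      elogit(i, j) = std::log(p / (1.0 - p));
      mu += elogit(i, j);
    }
  mu /= ncell;
  std::vector<double> theta(I, 0.0), phi(J, 0.0), psi(K, 0.0), z;
  for (int i = 0; i < I; ++i) {
    for (int j = 0; j < J; ++j) theta[i] += elogit(i, j) - mu;
    theta[i] /= J;
  }
  for (int j = 0; j < J; ++j) {
    for (int i = 0; i < I; ++i) phi[j] += elogit(i, j) - mu;
    phi[j] /= I;
  }
  if (het) z.assign(ncell, 0.0);
  // precisions: 0=age 1=period 2=cohort 3=heterogeneity
  double tau[4];
  for (int b = 0; b < 4; ++b)
    tau[b] = R_finite(fixed_prec[b]) ? fixed_prec[b] : 100.0;

  NumericMatrix eta(I, J);
  for (int i = 0; i < I; ++i)
    for (int j = 0; j < J; ++j)
      eta(i, j) = mu + theta[i] + phi[j];

  Adapt ad_mu, ad_th, ad_ph, ad_ps, ad_z;
  ad_mu.init(1, 0.05); ad_th.init(I, 0.1); ad_ph.init(J, 0.1);
  ad_ps.init(K, 0.2);
  if (het) ad_z.init(ncell, 0.3);

  const int n_keep = (n_iter - n_burn) / thin;
  NumericVector mu_out(n_keep), dev_out(n_keep);
  NumericMatrix th_out(n_keep, I), ph_out(n_keep, J), ps_out(n_keep, K);
  NumericMatrix z_out(het ? n_keep : 1, het ? ncell : 1);
  NumericMatrix tau_out(n_keep, 4);

  // post-burn-in acceptance accounting per block
  double acc_cnt[5] = {0, 0, 0, 0, 0}, try_cnt[5] = {0, 0, 0, 0, 0};

  double lconst = 0.0;
  for (int c = 0; c < ncell; ++c) lconst += R::lchoose(N[c], D[c]);

  int keep = 0, batch = 0;
  for (int it = 0; it < n_iter; ++it) {
    const bool burn = it < n_burn;

    // --- mu (flat prior, all cells) ---
    {
      double s = std::exp(ad_mu.lstep[0]);
      double prop = mu + s * norm_rand();
      double dll = 0.0;
      for (int i = 0; i < I; ++i)
        for (int j = 0; j < J; ++j)
          dll += cell_ll(D(i, j), N(i, j), eta(i, j) + (prop - mu))
               - cell_ll(D(i, j), N(i, j), eta(i, j));
      bool a = std::log(unif_rand()) < dll;
      if (a) {
        double d = prop - mu; mu = prop;
        for (int c = 0; c < ncell; ++c) eta[c] += d;
      }
      if (burn) ad_mu.tally(0, a); else { try_cnt[0]++; if (a) acc_cnt[0]++; }
    }

    // --- age effects ---
    for (int m = 0; m < I; ++m) {
      double s = std::exp(ad_th.lstep[m]);
      double cur = theta[m], prop = cur + s * norm_rand();
      double dll = 0.0;
      for (int j = 0; j < J; ++j)
        dll += cell_ll(D(m, j), N(m, j), eta(m, j) + (prop - cur))
             - cell_ll(D(m, j), N(m, j), eta(m, j));
      double q0 = rw_local(theta, m, ord_age);
      theta[m] = prop;
      double q1 = rw_local(theta, m, ord_age);
      theta[m] = cur;
      double lr = dll - 0.5 * tau[0] * (q1 - q0);
      bool a = std::log(unif_rand()) < lr;
      if (a) {
        theta[m] = prop;
        for (int j = 0; j < J; ++j) eta(m, j) += prop - cur;
      }
      if (burn) ad_th.tally(m, a); else { try_cnt[1]++; if (a) acc_cnt[1]++; }
    }

    // --- period effects ---
    for (int m = 0; m < J; ++m) {
      double s = std::exp(ad_ph.lstep[m]);
      double cur = phi[m], prop = cur + s * norm_rand();
      double dll = 0.0;
      for (int i = 0; i < I; ++i)
        dll += cell_ll(D(i, m), N(i, m), eta(i, m) + (prop - cur))
             - cell_ll(D(i, m), N(i, m), eta(i, m));
      double q0 = rw_local(phi, m, ord_per);
      phi[m] = prop;
      double q1 = rw_local(phi, m, ord_per);
      phi[m] = cur;
      double lr = dll - 0.5 * tau[1] * (q1 - q0);
      bool a = std::log(unif_rand()) < lr;
      if (a) {
        phi[m] = prop;
        for (int i = 0; i < I; ++i) eta(i, m) += prop - cur;
      }
      if (burn) ad_ph.tally(m, a); else { try_cnt[2]++; if (a) acc_cnt[2]++; }
    }

    // --- cohort effects ---
    for (int m = 0; m < K; ++m) {
      double s = std::exp(ad_ps.lstep[m]);
      double cur = psi[m], prop = cur + s * norm_rand();
      double dll = 0.0;
      const std::vector< std::pair<int,int> > &cc = coh_cells[m];
      for (size_t c = 0; c < cc.size(); ++c) {
        int i = cc[c].first, j = cc[c].second;
        dll += cell_ll(D(i, j), N(i, j), eta(i, j) + (prop - cur))
             - cell_ll(D(i, j), N(i, j), eta(i, j));
      }
      double q0 = rw_local(psi, m, ord_coh);
      psi[m] = prop;
      double q1 = rw_local(psi, m, ord_coh);
      psi[m] = cur;
      double lr = dll - 0.5 * tau[2] * (q1 - q0);
      bool a = std::log(unif_rand()) < lr;
      if (a) {
        psi[m] = prop;
        for (size_t c = 0; c < cc.size(); ++c)
          eta(cc[c].first, cc[c].second) += prop - cur;
      }
      if (burn) ad_ps.tally(m, a); else { try_cnt[3]++; if (a) acc_cnt[3]++; }
    }

    // --- heterogeneity ---
    if (het) {
      for (int c = 0; c < ncell; ++c) {
        double s = std::exp(ad_z.lstep[c]);
        double cur = z[c], prop = cur + s * norm_rand();
        double dll = cell_ll(D[c], N[c], eta[c] + (prop - cur))
                   - cell_ll(D[c], N[c], eta[c]);
        double lr = dll - 0.5 * tau[3] * (prop * prop - cur * cur);
        bool a = std::log(unif_rand()) < lr;
        if (a) { z[c] = prop; eta[c] += prop - cur; }
        if (burn) ad_z.tally(c, a); else { try_cnt[4]++; if (a) acc_cnt[4]++; }
      }
    }

    // --- project out the APC linear confound (all-RW2 case only) ---
    // A trend gamma*k in the cohort block equals gamma*C*(I-i) + gamma*j in
    // the age and period blocks, so moving it is likelihood-invariant; RW2
    // priors are invariant to linear shifts, making the projection
    // measure-preserving. With any RW1 block the trend direction is pinned
    // by that block's prior and no projection is applied.
    if (ord_age == 2 && ord_per == 2 && ord_coh == 2) {
      double kbar = 0.5 * (K + 1), skk = 0.0, skp = 0.0;
      for (int k = 0; k < K; ++k) {
        double kc = (k + 1) - kbar;
        skk += kc * kc; skp += kc * psi[k];
      }
      double gam = skp / skk;
      for (int k = 0; k < K; ++k) psi[k] -= gam * (k + 1);
      for (int j = 0; j < J; ++j) phi[j] += gam * (j + 1);
      for (int i = 0; i < I; ++i) theta[i] += gam * C * (I - 1 - i);
      // eta unchanged: gam*k = gam*C*(I-i) + gam*j cell-by-cell
    }

    // --- recentre block levels into mu ---
    {
      double mth = 0, mph = 0, mps = 0;
      for (int i = 0; i < I; ++i) mth += theta[i];
      mth /= I;
      for (int j = 0; j < J; ++j) mph += phi[j];
      mph /= J;
      for (int k = 0; k < K; ++k) mps += psi[k];
      mps /= K;
      for (int i = 0; i < I; ++i) theta[i] -= mth;
      for (int j = 0; j < J; ++j) phi[j] -= mph;
      for (int k = 0; k < K; ++k) psi[k] -= mps;
      mu += mth + mph + mps;
      // eta unchanged
    }

    // --- precisions (conjugate Gamma) ---
    if (!R_finite(fixed_prec[0]))
      tau[0] = R::rgamma(prior_shape[0] + 0.5 * (I - ord_age),
                         1.0 / (prior_rate[0] + 0.5 * rw_quadform(theta, ord_age)));
    if (!R_finite(fixed_prec[1]))
      tau[1] = R::rgamma(prior_shape[1] + 0.5 * (J - ord_per),
                         1.0 / (prior_rate[1] + 0.5 * rw_quadform(phi, ord_per)));
    if (!R_finite(fixed_prec[2]))
      tau[2] = R::rgamma(prior_shape[2] + 0.5 * (K - ord_coh),
                         1.0 / (prior_rate[2] + 0.5 * rw_quadform(psi, ord_coh)));
    if (het && !R_finite(fixed_prec[3])) {
      double ss = 0.0;
      for (int c = 0; c < ncell; ++c) ss += z[c] * z[c];
      tau[3] = R::rgamma(prior_shape[3] + 0.5 * ncell,
                         1.0 / (prior_rate[3] + 0.5 * ss));
    }

    if (burn && ++batch % 50 == 0) {
      int bno = batch / 50;
      ad_mu.adapt(bno); ad_th.adapt(bno); ad_ph.adapt(bno); ad_ps.adapt(bno);
      if (het) ad_z.adapt(bno);
    }

    if (!burn && (it - n_burn) % thin == thin - 1) {
      mu_out[keep] = mu;
      for (int i = 0; i < I; ++i) th_out(keep, i) = theta[i];
      for (int j = 0; j < J; ++j) ph_out(keep, j) = phi[j];
      for (int k = 0; k < K; ++k) ps_out(keep, k) = psi[k];
      if (het) for (int c = 0; c < ncell; ++c) z_out(keep, c) = z[c];
      for (int b = 0; b < 4; ++b) tau_out(keep, b) = tau[b];
      double ll = lconst;
      for (int c = 0; c < ncell; ++c) ll += cell_ll(D[c], N[c], eta[c]);
      dev_out[keep] = -2.0 * ll;
      ++keep;
    }
  }

  NumericVector acc(5);
  for (int b = 0; b < 5; ++b)
    acc[b] = try_cnt[b] > 0 ? acc_cnt[b] / try_cnt[b] : NA_REAL;
  acc.names() = CharacterVector::create("mu", "age", "period", "cohort",
                                        "heterogeneity");
  return List::create(
    _["mu"] = mu_out, _["theta"] = th_out, _["phi"] = ph_out,
    _["psi"] = ps_out, _["z"] = z_out, _["tau"] = tau_out,
    _["deviance"] = dev_out, _["accept"] = acc);
}
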