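// Blocked Gibbs sampler for the two-level Bayesian VAR(1) with latent
// person-mean centering:
//
//   within person i, grid cell t:
//     y_it = mu_i + w_it
//     w_it = Phi_i w_{i,t-1} + gamma * hour_it + eps_it,  eps ~ N(0, Sigma_w)
//   between persons:
//     [mu_i; vec_row(Phi_i); schemas_i] ~ N(b0 + gender_i * bg, Omega)
//
// Missing grid cells (empty hours, nights) are latent and handled inside
// the chain. The person-level updates are collapsed over the missing
// cells: consecutive observed cells t and t+L satisfy
//   y_{t+L} = mu + Phi^L (y_t - mu) + sum_j Phi^j gamma h_{t+L-j} + e_L,
//   e_L ~ N(0, C_L),  C_L = sum_{j<L} Phi^j Sigma_w Phi'^j,
// which is linear in mu (exact conjugate update) and gives the marginal
// likelihood used by a Metropolis step for Phi_i (proposal = the conjugate
// full conditional under the current imputation). Missing cells are then
// redrawn by forward-filter backward-sampling, and the remaining blocks
// (hour slope, residual covariance, fixed effects, between covariance)
// use conjugate complete-data updates. Collapsing Phi_i over the imputed
// cells is what keeps heavily missing series (a night is 11+ empty cells)
// from locking the chain into self-confirming imputations.
//
// Conventions: the person effect vector stacks the K means followed by
// the K^2 lag coefficients in outcome-major (row-major) order of Phi.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat sym(const arma::mat& m) { return 0.5 * (m + m.t()); }

// Strict SPD inverse with a jittered retry for numerically borderline draws.
static arma::mat inv_spd(const arma::mat& m) {
  arma::mat out;
  double jitter = 0.0;
  for (int k = 0; k < 6; ++k) {
    if (arma::inv_sympd(out, sym(m) + jitter * arma::eye(m.n_rows, m.n_rows)))
      return out;
    jitter = (jitter == 0.0) ? 1e-10 * (1.0 + arma::trace(m) / m.n_rows) : jitter * 100;
  }
  Rcpp::stop("SPD inversion failed in a conjugate update (singular scale matrix).");
}

static arma::mat chol_safe(const arma::mat& p) {
  arma::mat u;
  double jitter = 0.0;
  for (int k = 0; k < 6; ++k) {
    if (arma::chol(u, sym(p) + jitter * arma::eye(p.n_rows, p.n_rows))) return u;
    jitter = (jitter == 0.0) ? 1e-10 * (1.0 + arma::trace(p) / p.n_rows) : jitter * 100;
  }
  Rcpp::stop("Cholesky factorization failed in a conjugate update (singular scale matrix).");
}

// Draw from N(P^{-1} b, P^{-1}) given precision P and linear term b.
static arma::vec mvn_prec(const arma::mat& p, const arma::vec& b) {
  arma::mat u = chol_safe(p);            // p = u' u, u upper
  arma::vec mean = arma::solve(arma::trimatu(u),
                               arma::solve(arma::trimatl(u.t()), b));
  arma::vec z(b.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = R::norm_rand();
  return mean + arma::solve(arma::trimatu(u), z);
}

// Spectral radius of a K x K lag matrix.
static double spec_radius(const arma::mat& m) {
  arma::cx_vec ev;
  if (!arma::eig_gen(ev, m)) return arma::datum::inf;
  return arma::abs(ev).max();
}

// Support of the person-level lag prior: interior of the stationary region
// (spectral radius < 0.98 keeps the person mean identified) with bounded
// coefficients (|phi| < 1.5 excludes wildly non-normal transients). The
// synthetic-truth generator draws person dynamics from the same region.
static bool phi_ok(const arma::vec& p, int K) {
  if (arma::abs(p).max() >= 1.5) return false;
  arma::mat phi = arma::reshape(p, K, K).t();
  return spec_radius(phi) < 0.98;
}

// Inverse-Wishart draw with degrees of freedom df and scale S, via Bartlett.
static arma::mat rinvwish(double df, const arma::mat& s) {
  arma::uword d = s.n_rows;
  arma::mat sinv = inv_spd(sym(s));
  arma::mat l = arma::chol(sym(sinv), "lower");
  arma::mat a(d, d, arma::fill::zeros);
  for (arma::uword i = 0; i < d; ++i) {
    a(i, i) = std::sqrt(R::rchisq(df - (double)i));
    for (arma::uword j = 0; j < i; ++j) a(i, j) = R::norm_rand();
  }
  arma::mat la = l * a;
  return inv_spd(sym(la * la.t()));
}

// Powers Phi^j (j = 0..lmax) and gap covariances C_j = sum_{l<j} Phi^l S Phi'^l.
static void gap_moments(const arma::mat& phi, const arma::mat& sigma, int lmax,
                        std::vector<arma::mat>& pw, std::vector<arma::mat>& cv) {
  int K = phi.n_rows;
  pw.assign(lmax + 1, arma::mat());
  cv.assign(lmax + 1, arma::mat());
  pw[0] = arma::eye(K, K);
  cv[0] = arma::zeros(K, K);
  for (int j = 1; j <= lmax; ++j) {
    pw[j] = phi * pw[j - 1];
    cv[j] = sym(cv[j - 1] + pw[j - 1] * sigma * pw[j - 1].t());
  }
}

// Log-likelihood of the observed consecutive pairs of one person under
// (phi, mu, gamma, sigma), with the missing cells integrated out. Takes
// precomputed powers/gap covariances for this phi; Cholesky factors are
// cached by gap length. Additive constants common to all phi are dropped.
static double pair_loglik(const arma::mat& ymat, const arma::umat& pairs,
                          const arma::vec& hvec,
                          const std::vector<arma::mat>& pw,
                          const std::vector<arma::mat>& cv,
                          const arma::vec& mu_i, const arma::vec& gam,
                          bool use_hour) {
  double ll = 0.0;
  const int K = mu_i.n_elem;
  std::vector<arma::mat> ul(cv.size());
  std::vector<double> ld(cv.size(), 0.0);
  for (arma::uword k = 0; k < pairs.n_cols; ++k) {
    int t0 = pairs(0, k), t1 = pairs(1, k), L = t1 - t0;
    if (ul[L].n_elem == 0) {
      if (!arma::chol(ul[L], cv[L] + 1e-12 * arma::eye(K, K)))
        return -arma::datum::inf;
      ld[L] = 2.0 * arma::accu(arma::log(ul[L].diag()));
    }
    arma::vec r = ymat.row(t1).t() - mu_i - pw[L] * (ymat.row(t0).t() - mu_i);
    if (use_hour) {
      for (int j = 0; j < L; ++j) r -= pw[j] * (gam * hvec(t1 - j));
    }
    arma::vec sv = arma::solve(arma::trimatl(ul[L].t()), r, arma::solve_opts::fast);
    ll += -0.5 * (ld[L] + arma::dot(sv, sv));
    if (!std::isfinite(ll)) return -arma::datum::inf;
  }
  return ll;
}

// [[Rcpp::export(name = ".gibbs_dsem")]]
List gibbs_dsem(const List& y_list, const List& hour_list,
                const arma::mat& schemas, const arma::vec& gender,
                bool random_effects, bool include_hour, bool use_gender,
                int n_iter, int burn, int thin,
                double beta_prior_var, double sigma_df_add, double omega_df_add) {
  const int n = y_list.size();
  std::vector<arma::mat> y(n);
  std::vector<arma::vec> hour(n);
  std::vector<arma::uvec> miss(n);
  std::vector<arma::umat> pairs(n);
  std::vector<int> lmax(n, 1), maxrun(n, 0);
  for (int i = 0; i < n; ++i) {
    arma::mat yi = as<arma::mat>(y_list[i]);
    hour[i] = as<arma::vec>(hour_list[i]);
    miss[i] = arma::find_nonfinite(yi.col(0));
    arma::uvec obs = arma::find_finite(yi.col(0));
    arma::umat pr(2, obs.n_elem - 1);
    for (arma::uword k = 0; k + 1 < obs.n_elem; ++k) {
      pr(0, k) = obs(k);
      pr(1, k) = obs(k + 1);
      lmax[i] = std::max(lmax[i], (int)(obs(k + 1) - obs(k)));
    }
    pairs[i] = pr;
    for (arma::uword k = 0; k + 1 < obs.n_elem; ++k)
      maxrun[i] = std::max(maxrun[i], (int)(obs(k + 1) - obs(k)) - 1);
    y[i] = yi;
  }
  const int K = y[0].n_cols;
  // Imputation guard: per person/variable plausibility window (observed
  // range +/- 6 within-person SD); inert under stationary dynamics.
  std::vector<arma::vec> ylo(n), yhi(n);
  const int de = K + K * K;
  const int ns = schemas.n_cols;
  const int d = random_effects ? de + ns : de;

  // --- initialization ---------------------------------------------------
  arma::mat mu(K, n), phiflat(K * K, n);      // per-person state (columns)
  std::vector<arma::mat> phi(n);
  for (int i = 0; i < n; ++i) {
    arma::uvec obs = arma::find_finite(y[i].col(0));
    arma::rowvec m = arma::mean(y[i].rows(obs), 0);
    arma::rowvec sdv = arma::stddev(y[i].rows(obs), 0, 0);
    ylo[i] = (arma::min(y[i].rows(obs), 0) - 6.0 * sdv).t();
    yhi[i] = (arma::max(y[i].rows(obs), 0) + 6.0 * sdv).t();
    mu.col(i) = m.t();
    for (arma::uword t = 0; t < miss[i].n_elem; ++t) y[i].row(miss[i](t)) = m;
    phi[i] = 0.2 * arma::eye(K, K);
    phiflat.col(i) = arma::vectorise(phi[i].t());
  }
  arma::vec b0(d, arma::fill::zeros);
  b0.subvec(0, K - 1) = arma::mean(mu, 1);
  for (int k = 0; k < K; ++k) b0(K + k * K + k) = 0.2;
  arma::vec bg(de, arma::fill::zeros);
  arma::mat omega = arma::eye(d, d);
  omega.submat(0, 0, K - 1, K - 1) *= 0.5;        // person means
  omega.submat(K, K, de - 1, de - 1) *= 0.02;     // lag coefficients
  arma::mat sigma = arma::eye(K, K);
  arma::vec gam(K, arma::fill::zeros);

  arma::uvec ia = arma::regspace<arma::uvec>(0, K - 1);            // mean block
  arma::uvec ip = arma::regspace<arma::uvec>(K, de - 1);           // lag block
  arma::uvec rest_mu(d - K), rest_p(d - K * K);
  { int c = 0; for (int j = K; j < d; ++j) rest_mu(c++) = j;
    c = 0; for (int j = 0; j < K; ++j) rest_p(c++) = j;
    for (int j = de; j < d; ++j) rest_p(c++) = j; }

  const int n_keep = (n_iter > burn) ? (n_iter - burn) / thin : 0;
  arma::mat keep_eta(n_keep, de), keep_gam(n_keep, K),
    keep_sigma(n_keep, K * K), keep_omega(n_keep, d * d),
    keep_bg(n_keep, use_gender ? de : 0),
    keep_person(n_keep, random_effects ? n * de : 0);
  int stored = 0;
  double mh_prop = 0.0, mh_acc = 0.0;

  for (int it = 0; it < n_iter; ++it) {
    arma::mat sinv = inv_spd(sym(sigma));

    // Conditional-prior pieces for the mu and Phi person updates.
    arma::mat cb_mu, prec_mu, cb_p, prec_p;
    if (random_effects) {
      arma::mat obb = omega.submat(rest_mu, rest_mu);
      arma::mat oab = omega.submat(ia, rest_mu);
      cb_mu = arma::solve(sym(obb), oab.t()).t();          // K x (d-K)
      prec_mu = inv_spd(sym(omega.submat(ia, ia) - cb_mu * oab.t()));
      arma::mat obb2 = omega.submat(rest_p, rest_p);
      arma::mat oab2 = omega.submat(ip, rest_p);
      cb_p = arma::solve(sym(obb2), oab2.t()).t();         // K^2 x (d-K^2)
      prec_p = inv_spd(sym(omega.submat(ip, ip) - cb_p * oab2.t()));
    }

    // Accumulators for gamma and Sigma_w (single pass over persons).
    double sh2 = 0.0;
    arma::vec shu(K, arma::fill::zeros);
    arma::mat suu(K, K, arma::fill::zeros);
    double n_trans = 0.0;
    // Pooled accumulators for the fixed-effects-only mode.
    arma::mat pool_lik_mu(K, K, arma::fill::zeros);
    arma::vec pool_rhs_mu(K, arma::fill::zeros);
    arma::mat pool_sxx(K, K, arma::fill::zeros), pool_sxz(K, K, arma::fill::zeros);

    for (int i = 0; i < n; ++i) {
      const int T = y[i].n_rows;
      arma::vec mu_i;
      arma::mat phi_i;
      if (random_effects) {
        mu_i = mu.col(i);
        phi_i = phi[i];
      } else {
        mu_i = b0.subvec(0, K - 1);
        phi_i = arma::reshape(arma::vec(b0.subvec(K, de - 1)), K, K).t();
      }

      if (random_effects) {
        arma::vec m_i = b0;
        if (use_gender) m_i.subvec(0, de - 1) += gender(i) * bg;
        std::vector<arma::mat> pw_cur, cv_cur;   // moments of the current phi

        // (a) mu_i from the collapsed observed-pair likelihood (conjugate)
        {
          arma::vec r_i(d - K);                     // [p_i; s_i] current
          r_i.subvec(0, K * K - 1) = phiflat.col(i);
          if (ns > 0) r_i.subvec(K * K, d - K - 1) = schemas.row(i).t();
          arma::vec pm = m_i.elem(ia) + cb_mu * (r_i - m_i.elem(rest_mu));
          gap_moments(phi_i, sigma, lmax[i], pw_cur, cv_cur);
          const std::vector<arma::mat>& pw = pw_cur;
          const std::vector<arma::mat>& cv = cv_cur;
          std::vector<arma::mat> clinv_by(lmax[i] + 1);
          arma::mat lik_prec(K, K, arma::fill::zeros);
          arma::vec lik_rhs(K, arma::fill::zeros);
          for (arma::uword k = 0; k < pairs[i].n_cols; ++k) {
            int t0 = pairs[i](0, k), t1 = pairs[i](1, k), L = t1 - t0;
            if (clinv_by[L].n_elem == 0) clinv_by[L] = inv_spd(cv[L]);
            const arma::mat& clinv = clinv_by[L];
            arma::mat a = arma::eye(K, K) - pw[L];
            arma::vec r = y[i].row(t1).t() - pw[L] * y[i].row(t0).t();
            if (include_hour) {
              arma::vec tr(K, arma::fill::zeros);
              for (int j = 0; j < L; ++j) tr += pw[j] * (gam * hour[i](t1 - j));
              r -= tr;
            }
            lik_prec += a.t() * clinv * a;
            lik_rhs += a.t() * clinv * r;
          }
          mu_i = mvn_prec(prec_mu + lik_prec, prec_mu * pm + lik_rhs);
          mu.col(i) = mu_i;
        }

        // (b) Phi_i: Metropolis on the collapsed likelihood with the
        // complete-data conjugate conditional as proposal
        {
          arma::vec r2(d - K * K);                  // [mu_i; s_i]
          r2.subvec(0, K - 1) = mu_i;
          if (ns > 0) r2.subvec(K, d - K * K - 1) = schemas.row(i).t();
          arma::vec pmp = m_i.elem(ip) + cb_p * (r2 - m_i.elem(rest_p));

          // proposal from the observed lag-1 pairs only (bridge-free)
          arma::mat sxx1(K, K, arma::fill::zeros), sxz1(K, K, arma::fill::zeros);
          for (arma::uword k = 0; k < pairs[i].n_cols; ++k) {
            if (pairs[i](1, k) - pairs[i](0, k) != 1) continue;
            int t0 = pairs[i](0, k), t1 = pairs[i](1, k);
            arma::vec w0 = y[i].row(t0).t() - mu_i;
            arma::vec z1 = y[i].row(t1).t() - mu_i - gam * hour[i](t1);
            sxx1 += w0 * w0.t();
            sxz1 += w0 * z1.t();
          }
          arma::mat pc = prec_p + arma::kron(sinv, sxx1);
          arma::vec rc = prec_p * pmp + arma::vectorise(sxz1 * sinv);
          arma::mat u = chol_safe(pc);
          arma::vec mc = arma::solve(arma::trimatu(u),
                                     arma::solve(arma::trimatl(u.t()), rc));
          arma::vec cand;
          bool have = false;
          for (int tries = 0; tries < 50 && !have; ++tries) {
            arma::vec zr(de - K);
            for (arma::uword q = 0; q < zr.n_elem; ++q) zr(q) = R::norm_rand();
            cand = mc + arma::solve(arma::trimatu(u), zr);
            have = phi_ok(cand, K);
          }
          mh_prop += 1.0;
          if (have) {
            arma::vec cur = phiflat.col(i);
            arma::mat phic = arma::reshape(cand, K, K).t();
            std::vector<arma::mat> pw_c, cv_c;
            gap_moments(phic, sigma, lmax[i], pw_c, cv_c);
            double lt_cand = pair_loglik(y[i], pairs[i], hour[i], pw_c, cv_c,
                                         mu_i, gam, include_hour)
              - 0.5 * arma::as_scalar((cand - pmp).t() * prec_p * (cand - pmp));
            double lt_cur = pair_loglik(y[i], pairs[i], hour[i], pw_cur, cv_cur,
                                        mu_i, gam, include_hour)
              - 0.5 * arma::as_scalar((cur - pmp).t() * prec_p * (cur - pmp));
            double lq_cand = -0.5 * arma::as_scalar((cand - mc).t() * pc * (cand - mc));
            double lq_cur = -0.5 * arma::as_scalar((cur - mc).t() * pc * (cur - mc));
            double alpha = lt_cand - lt_cur + lq_cur - lq_cand;
            if (std::log(R::unif_rand()) < alpha) {
              phi_i = phic;
              phi[i] = phic;
              phiflat.col(i) = cand;
              mh_acc += 1.0;
            }
          }
        }
      }

      // (c) impute missing cells by forward-filter backward-sampling over
      // each maximal missing run, under the updated person parameters
      arma::vec c_i = (arma::eye(K, K) - phi_i) * mu_i;
      arma::mat ptsinv = phi_i.t() * sinv;
      arma::mat ptsp = ptsinv * phi_i;
      if (maxrun[i] > 0) {
        // The filter covariance at offset j of a missing run depends only
        // on j (every run starts from an observed point mass), so the
        // per-offset precisions and their Cholesky factors are shared by
        // all runs of this person in this sweep.
        std::vector<arma::mat> fpinv(maxrun[i]), uprec(maxrun[i]);
        {
          arma::mat pprev(K, K, arma::fill::zeros);
          for (int j = 0; j < maxrun[i]; ++j) {
            arma::mat fp = sym(phi_i * pprev * phi_i.t() + sigma);
            pprev = fp;
            fpinv[j] = inv_spd(fp);
            uprec[j] = chol_safe(fpinv[j] + ptsp);
          }
        }
        auto draw_cell = [&](int j, const arma::vec& rhs) {
          const arma::mat& u = uprec[j];
          arma::vec mean = arma::solve(arma::trimatu(u),
                                       arma::solve(arma::trimatl(u.t()), rhs));
          arma::vec z(K);
          for (int q = 0; q < K; ++q) z(q) = R::norm_rand();
          return arma::vec(mean + arma::solve(arma::trimatu(u), z));
        };
        arma::uword mi = 0;
        std::vector<arma::vec> fm;
        while (mi < miss[i].n_elem) {
          int a = miss[i](mi);
          arma::uword mj = mi;
          while (mj + 1 < miss[i].n_elem && miss[i](mj + 1) == miss[i](mj) + 1) ++mj;
          int b = miss[i](mj);
          int len = b - a + 1;
          fm.assign(len, arma::vec());
          arma::vec mprev = y[i].row(a - 1).t();
          for (int t = a; t <= b; ++t) {
            fm[t - a] = phi_i * mprev + c_i + gam * hour[i](t);
            mprev = fm[t - a];
          }
          {
            arma::vec nxt = y[i].row(b + 1).t() - c_i - gam * hour[i](b + 1);
            arma::vec rhs = fpinv[len - 1] * fm[len - 1] + ptsinv * nxt;
            arma::rowvec drawb = draw_cell(len - 1, rhs).t();
            y[i].row(b) = arma::max(arma::min(drawb, yhi[i].t()), ylo[i].t());
          }
          for (int t = b - 1; t >= a; --t) {
            arma::vec nxt = y[i].row(t + 1).t() - c_i - gam * hour[i](t + 1);
            arma::vec rhs = fpinv[t - a] * fm[t - a] + ptsinv * nxt;
            arma::rowvec draw = draw_cell(t - a, rhs).t();
            y[i].row(t) = arma::max(arma::min(draw, yhi[i].t()), ylo[i].t());
          }
          mi = mj + 1;
        }
      }

      // (d) accumulate complete-data statistics for gamma and Sigma_w
      arma::mat ylag = y[i].rows(0, T - 2);
      arma::mat ycur = y[i].rows(1, T - 1);
      arma::vec h = hour[i].subvec(1, T - 1);
      arma::mat w_lag = ylag.each_row() - mu_i.t();
      arma::mat w_cur = ycur.each_row() - mu_i.t();
      arma::mat ures = w_cur - w_lag * phi_i.t();    // = gamma h + eps
      sh2 += arma::dot(h, h);
      shu += ures.t() * h;
      suu += ures.t() * ures;
      n_trans += T - 1;

      if (!random_effects) {
        // pooled sufficient statistics; shared parameters updated below
        arma::mat a = arma::eye(K, K) - phi_i;
        arma::vec rs = arma::sum(ycur - ylag * phi_i.t(), 0).t() - gam * arma::accu(h);
        pool_lik_mu += (T - 1) * a.t() * sinv * a;
        pool_rhs_mu += a.t() * sinv * rs;
        arma::mat z = w_cur - h * gam.t();
        pool_sxx += w_lag.t() * w_lag;
        pool_sxz += w_lag.t() * z;
      }
    }

    if (!random_effects) {
      // shared mu then shared Phi (conjugate, diffuse normal priors)
      arma::mat prior = arma::eye(K, K) / beta_prior_var;
      arma::vec mu_s = mvn_prec(prior + pool_lik_mu, pool_rhs_mu);
      b0.subvec(0, K - 1) = mu_s;
      // rebuild pooled lag statistics with the new mu
      arma::mat sxx(K, K, arma::fill::zeros), sxz(K, K, arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        const int T = y[i].n_rows;
        arma::mat w_lag = y[i].rows(0, T - 2).each_row() - mu_s.t();
        arma::mat z = y[i].rows(1, T - 1).each_row() - mu_s.t();
        arma::vec h = hour[i].subvec(1, T - 1);
        arma::mat zg = z - h * gam.t();
        sxx += w_lag.t() * w_lag;
        sxz += w_lag.t() * zg;
      }
      arma::mat prior_p = arma::eye(K * K, K * K) / beta_prior_var;
      arma::mat pc = prior_p + arma::kron(sinv, sxx);
      arma::vec rc = arma::vectorise(sxz * sinv);
      arma::mat u = chol_safe(pc);
      arma::vec mc = arma::solve(arma::trimatu(u),
                                 arma::solve(arma::trimatl(u.t()), rc));
      arma::vec p_s = b0.subvec(K, de - 1);
      for (int tries = 0; tries < 50; ++tries) {
        arma::vec zr(de - K);
        for (arma::uword q = 0; q < zr.n_elem; ++q) zr(q) = R::norm_rand();
        arma::vec candp = mc + arma::solve(arma::trimatu(u), zr);
        if (phi_ok(candp, K)) { p_s = candp; break; }
      }
      b0.subvec(K, de - 1) = p_s;
      // refresh residual statistics under the new (mu, Phi)
      arma::mat phi_s = arma::reshape(p_s, K, K).t();
      sh2 = 0.0; shu.zeros(); suu.zeros(); n_trans = 0.0;
      for (int i = 0; i < n; ++i) {
        const int T = y[i].n_rows;
        arma::mat w_lag = y[i].rows(0, T - 2).each_row() - mu_s.t();
        arma::mat w_cur = y[i].rows(1, T - 1).each_row() - mu_s.t();
        arma::vec h = hour[i].subvec(1, T - 1);
        arma::mat ures = w_cur - w_lag * phi_s.t();
        sh2 += arma::dot(h, h); shu += ures.t() * h; suu += ures.t() * ures;
        n_trans += T - 1;
      }
    }

    // gamma (hour-of-measurement slope)
    if (include_hour && sh2 > 0) {
      arma::mat prec = sh2 * sinv + arma::eye(K, K) / beta_prior_var;
      gam = mvn_prec(prec, sinv * shu);
    }

    // Sigma_w
    arma::mat sse = suu - gam * shu.t() - shu * gam.t() + sh2 * gam * gam.t();
    sigma = rinvwish(K + sigma_df_add + n_trans, arma::eye(K, K) + sym(sse));

    // between level: fixed effects and Omega
    if (random_effects) {
      arma::mat eta(d, n);
      eta.rows(0, K - 1) = mu;
      eta.rows(K, de - 1) = phiflat;
      if (ns > 0) eta.rows(de, d - 1) = schemas.t();
      arma::mat oinv = inv_spd(sym(omega));
      if (use_gender) {
        double sg = arma::accu(gender), sg2 = arma::dot(gender, gender);
        arma::mat oe = oinv.cols(0, de - 1);            // Oinv * E
        arma::mat ee = oinv.submat(0, 0, de - 1, de - 1);
        arma::mat prec(d + de, d + de, arma::fill::zeros);
        prec.submat(0, 0, d - 1, d - 1) = n * oinv;
        prec.submat(0, d, d - 1, d + de - 1) = sg * oe;
        prec.submat(d, 0, d + de - 1, d - 1) = sg * oe.t();
        prec.submat(d, d, d + de - 1, d + de - 1) = sg2 * ee;
        prec += arma::eye(d + de, d + de) / beta_prior_var;
        arma::vec rhs(d + de);
        rhs.subvec(0, d - 1) = oinv * arma::sum(eta, 1);
        rhs.subvec(d, d + de - 1) = oe.t() * (eta * gender);
        arma::vec beta = mvn_prec(prec, rhs);
        b0 = beta.subvec(0, d - 1);
        bg = beta.subvec(d, d + de - 1);
      } else {
        arma::mat prec = n * oinv + arma::eye(d, d) / beta_prior_var;
        b0 = mvn_prec(prec, oinv * arma::sum(eta, 1));
      }
      arma::mat resid = eta.each_col() - b0;
      if (use_gender) resid.rows(0, de - 1) -= bg * gender.t();
      omega = rinvwish(d + omega_df_add + n, arma::eye(d, d) + sym(resid * resid.t()));
    }

    // store
    if (it >= burn && ((it - burn) % thin == (thin - 1)) && stored < n_keep) {
      keep_eta.row(stored) = b0.subvec(0, de - 1).t();
      keep_gam.row(stored) = gam.t();
      keep_sigma.row(stored) = arma::vectorise(sigma).t();
      keep_omega.row(stored) = arma::vectorise(omega).t();
      if (use_gender) keep_bg.row(stored) = bg.t();
      if (random_effects) {
        arma::mat pe(de, n);
        pe.rows(0, K - 1) = mu;
        pe.rows(K, de - 1) = phiflat;
        keep_person.row(stored) = arma::vectorise(pe).t();
      }
      ++stored;
    }
  }

  return List::create(
    _["eta_bar"] = keep_eta, _["gamma"] = keep_gam,
    _["sigma_w"] = keep_sigma, _["omega"] = keep_omega,
    _["beta_gender"] = keep_bg, _["person"] = keep_person,
    _["n_kept"] = stored,
    _["mh_accept"] = (mh_prop > 0) ? mh_acc / mh_prop : NA_REAL);
}
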