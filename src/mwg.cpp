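// Adaptive Metropolis-within-Gibbs sampler for the hierarchical binomial
// logit PIKE model with Bayesian LASSO shrinkage and in-chain imputation of
// missing covariate cells.
//
// The chain maintains the linear predictor eta, its log(1+exp(eta)) cache,
// and the total binomial log-likelihood incrementally; every update draws
// exactly one normal and one uniform variate from R's RNG stream, so chains
// are reproducible under set.seed() regardless of acceptance history.
// Random-walk scales adapt toward the target acceptance rate during burn-in
// only (Robbins-Monro on the log scale); after burn-in the kernel is fixed.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double l1pe(double x) {
  if (x > 33.0) return x;
  if (x < -33.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double ldnorm(double x, double m, double s) {
  double z = (x - m) / s;
  return -0.91893853320467274178 - std::log(s) - 0.5 * z * z;
}

struct Adapt {
  double target;
  int n_burn;
  void step(double &ls, double alpha, int iter) const {
    if (iter > n_burn) return;
    double g = 3.0 / std::sqrt((double)iter + 1.0);
    if (g > 0.25) g = 0.25;
    ls += g * (alpha - target);
    if (ls < -15.0) ls = -15.0;
    if (ls > 5.0) ls = 5.0;
  }
};

// [[Rcpp::export]]
List mwg_chain(List frame, List cfg, List init) {
  // --- unpack frame -------------------------------------------------------
  NumericVector y = frame["y"], ntot = frame["ntot"];
  const int n = y.size();
  NumericMatrix X = clone(as<NumericMatrix>(frame["X"]));
  NumericVector gov = clone(as<NumericVector>(frame["gov"]));
  IntegerVector site = frame["site"], year = frame["year"], country = frame["country"];
  const int S = as<int>(frame["S"]), Y = as<int>(frame["Y"]), C = as<int>(frame["C"]);
  NumericMatrix Z = clone(as<NumericMatrix>(frame["Z"]));
  NumericVector price = clone(as<NumericVector>(frame["price"]));
  const bool use_site = frame["use_site"], use_year = frame["use_year"],
             use_sy = frame["use_sy"], use_country = frame["use_country"],
             use_gov = frame["use_gov"], use_price = frame["use_price"];
  const int K = X.ncol(), P = Z.ncol();
  List misX = frame["misX"], misGov = frame["misGov"], misZ = frame["misZ"];
  IntegerVector misPrice = frame["misPrice"];
  const bool impute = frame["impute"];
  const double beta0_sd = frame["beta0_sd"];
  const double lam_shape = frame["lam_shape"], lam_rate = frame["lam_rate"];
  const double sig_shape = frame["sig_shape"], sig_rate = frame["sig_rate"];
  const double ll_const = frame["ll_const"];

  // --- unpack config / init ----------------------------------------------
  const int n_iter = as<int>(cfg["n_iter"]), n_burn = as<int>(cfg["n_burn"]);
  IntegerVector keep = cfg["keep"]; // 1-based iteration numbers, ascending
  Adapt ad{as<double>(cfg["target"]), n_burn};

  double beta0 = init["beta0"];
  std::vector<double> beta = as<std::vector<double>>(init["beta"]);
  double bgov = init["bgov"];
  std::vector<double> gam = as<std::vector<double>>(init["gamma"]);
  double bprice = init["bprice"];
  std::vector<double> usite = as<std::vector<double>>(init["usite"]);
  std::vector<double> uyear = as<std::vector<double>>(init["uyear"]);
  std::vector<double> ucountry = as<std::vector<double>>(init["ucountry"]);
  std::vector<double> usy = as<std::vector<double>>(init["usy"]);
  NumericVector sig0 = init["sig"]; // site, year, siteyear, country
  double sig_site = sig0[0], sig_year = sig0[1], sig_sy = sig0[2], sig_cty = sig0[3];
  double lam = init["lam"];

  // --- derived state ------------------------------------------------------
  std::vector<double> mu_site(S > 0 ? S : 0, 0.0), mu_year(Y > 0 ? Y : 0, 0.0);
  for (int s = 0; s < S; ++s) {
    double m = 0.0;
    for (int p = 0; p < P; ++p) m += Z(s, p) * gam[p];
    mu_site[s] = m;
  }
  if (use_price) for (int t = 0; t < Y; ++t) mu_year[t] = bprice * price[t];

  std::vector<double> eta(n), lpe(n);
  for (int i = 0; i < n; ++i) {
    double e = beta0;
    for (int k = 0; k < K; ++k) e += X(i, k) * beta[k];
    if (use_gov) e += bgov * gov[i];
    if (use_site) e += usite[site[i]];
    if (use_year) e += uyear[year[i]];
    if (use_sy) e += usy[i];
    if (use_country) e += ucountry[country[i]];
    eta[i] = e;
    lpe[i] = l1pe(e);
  }
  double cur_ll = 0.0;
  for (int i = 0; i < n; ++i) cur_ll += y[i] * eta[i] - ntot[i] * lpe[i];
  if (!std::isfinite(cur_ll)) stop("non-finite log-likelihood at initialization");

  // --- proposal scales ----------------------------------------------------
  const double LS0 = std::log(0.5), LSV = std::log(0.3);
  double ls_beta0 = LS0, ls_bgov = LS0, ls_bprice = LS0;
  double ls_sig[4] = {LSV, LSV, LSV, LSV};
  double ls_shift[4] = {LSV, LSV, LSV, LSV};
  double ls_lam = LSV;
  std::vector<double> ls_beta(K, LS0), ls_gam(P, LS0);
  std::vector<double> ls_usite(S, LS0), ls_uyear(Y, LS0), ls_ucty(C, LS0), ls_usy(n, LS0);
  int nImpX = 0; for (int k = 0; k < K; ++k) nImpX += as<IntegerVector>(misX[k]).size();
  const int nImpGov = misGov.size();
  int nImpZ = 0; for (int p = 0; p < P; ++p) nImpZ += as<IntegerVector>(misZ[p]).size();
  const int nImpPrice = misPrice.size();
  std::vector<double> ls_impX(nImpX, LS0), ls_impGov(nImpGov, LS0),
                      ls_impZ(nImpZ, LS0), ls_impPrice(nImpPrice, LS0);

  // scratch
  std::vector<double> eta_p(n), lpe_p(n), dS(S), dY(Y), dC(C), dll(std::max(std::max(S, Y), std::max(C, 1)));
  std::vector<int> accf(std::max(std::max(S, Y), std::max(C, 1)));

  // --- output layout ------------------------------------------------------
  const int n_coef = K + (use_gov ? 1 : 0) + P + (use_price ? 1 : 0);
  int npar = 1 + n_coef +
             (use_site ? 1 : 0) + (use_year ? 1 : 0) + (use_sy ? 1 : 0) + (use_country ? 1 : 0) +
             1 +
             (use_site ? S : 0) + (use_year ? Y : 0) + (use_country ? C : 0) + (use_sy ? n : 0) +
             nImpX + nImpGov + nImpZ + nImpPrice + 1;
  NumericMatrix draws(keep.size(), npar);

  // acceptance bookkeeping
  std::map<std::string, std::pair<double, double>> acc; // sum alpha, count
  auto track = [&](const char *b, double alpha) {
    auto &e = acc[b]; e.first += alpha; e.second += 1.0;
  };

  auto full_lprior = [&]() {
    double lp = ldnorm(beta0, 0.0, beta0_sd);
    double llam2 = std::log(lam / 2.0);
    for (int k = 0; k < K; ++k) lp += llam2 - lam * std::fabs(beta[k]);
    if (use_gov) lp += llam2 - lam * std::fabs(bgov);
    for (int p = 0; p < P; ++p) lp += llam2 - lam * std::fabs(gam[p]);
    if (use_price) lp += llam2 - lam * std::fabs(bprice);
    lp += R::dgamma(lam, lam_shape, 1.0 / lam_rate, 1);
    if (use_site) {
      lp += R::dgamma(sig_site, sig_shape, 1.0 / sig_rate, 1);
      for (int s = 0; s < S; ++s) lp += ldnorm(usite[s], mu_site[s], sig_site);
    }
    if (use_year) {
      lp += R::dgamma(sig_year, sig_shape, 1.0 / sig_rate, 1);
      for (int t = 0; t < Y; ++t) lp += ldnorm(uyear[t], mu_year[t], sig_year);
    }
    if (use_sy) {
      lp += R::dgamma(sig_sy, sig_shape, 1.0 / sig_rate, 1);
      for (int i = 0; i < n; ++i) lp += ldnorm(usy[i], 0.0, sig_sy);
    }
    if (use_country) {
      lp += R::dgamma(sig_cty, sig_shape, 1.0 / sig_rate, 1);
      for (int c = 0; c < C; ++c) lp += ldnorm(ucountry[c], 0.0, sig_cty);
    }
    if (impute) {
      for (int k = 0; k < K; ++k) {
        IntegerVector id = misX[k];
        for (int j = 0; j < id.size(); ++j) lp += ldnorm(X(id[j], k), 0.0, 1.0);
      }
      for (int g = 0; g < nImpGov; ++g) {
        IntegerVector grp = misGov[g];
        lp += ldnorm(gov[grp[0]], 0.0, 1.0);
      }
      for (int p = 0; p < P; ++p) {
        IntegerVector id = misZ[p];
        for (int j = 0; j < id.size(); ++j) lp += ldnorm(Z(id[j], p), 0.0, 1.0);
      }
      for (int j = 0; j < nImpPrice; ++j) lp += ldnorm(price[misPrice[j]], 0.0, 1.0);
    }
    return lp;
  };

  // scalar coefficient update against the full likelihood; dir == nullptr
  // means a constant direction of 1 (the intercept).
  auto coef_update = [&](double &coef, double &ls, const double *dir,
                         double prior_rate /*lam for Laplace, <0 for normal(beta0_sd)*/,
                         const char *blk, int iter) {
    double d = std::exp(ls) * norm_rand();
    double u = unif_rand();
    double pll = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = eta[i] + (dir ? d * dir[i] : d);
      eta_p[i] = e;
      lpe_p[i] = l1pe(e);
      pll += y[i] * e - ntot[i] * lpe_p[i];
    }
    double dpri = (prior_rate < 0)
      ? -0.5 * ((coef + d) * (coef + d) - coef * coef) / (beta0_sd * beta0_sd)
      : -prior_rate * (std::fabs(coef + d) - std::fabs(coef));
    double lr = pll - cur_ll + dpri;
    double alpha = lr >= 0 ? 1.0 : std::exp(lr);
    if (u < alpha) {
      coef += d;
      eta.swap(eta_p);
      lpe.swap(lpe_p);
      cur_ll = pll;
    }
    ad.step(ls, alpha, iter);
    track(blk, alpha);
  };

  // grouped random-intercept update: each group's records are disjoint, so
  // per-group Metropolis decisions are exact.
  auto group_update = [&](std::vector<double> &u, std::vector<double> &lsv,
                          const IntegerVector &gidx, int G,
                          const std::vector<double> *mu, double sigma,
                          const char *blk, int iter) {
    for (int g = 0; g < G; ++g) dS[g] = std::exp(lsv[g]) * norm_rand();
    std::fill(dll.begin(), dll.begin() + G, 0.0);
    for (int i = 0; i < n; ++i) {
      int g = gidx[i];
      double e = eta[i] + dS[g];
      eta_p[i] = e;
      lpe_p[i] = l1pe(e);
      dll[g] += y[i] * dS[g] - ntot[i] * (lpe_p[i] - lpe[i]);
    }
    for (int g = 0; g < G; ++g) {
      double m = mu ? (*mu)[g] : 0.0;
      double lr = dll[g] + ldnorm(u[g] + dS[g], m, sigma) - ldnorm(u[g], m, sigma);
      double alpha = lr >= 0 ? 1.0 : std::exp(lr);
      accf[g] = (unif_rand() < alpha);
      if (accf[g]) {
        u[g] += dS[g];
        cur_ll += dll[g];
      }
      ad.step(lsv[g], alpha, iter);
      track(blk, alpha);
    }
    for (int i = 0; i < n; ++i) {
      int g = gidx[i];
      if (accf[g]) { eta[i] = eta_p[i]; lpe[i] = lpe_p[i]; }
    }
  };

  // translation move along the intercept ridge: beta0 += d while an entire
  // random-intercept level shifts by -d. The linear predictor (hence the
  // likelihood) is unchanged, so the ratio involves only the priors; this
  // decorrelates beta0 from the level means, which plain component-wise
  // updates mix slowly.
  auto shift_update = [&](std::vector<double> &u, const std::vector<double> *mu,
                          double sigma, double &ls, int iter) {
    double d = std::exp(ls) * norm_rand();
    double u01 = unif_rand();
    double lr = -0.5 * ((beta0 + d) * (beta0 + d) - beta0 * beta0) /
                (beta0_sd * beta0_sd);
    const int G = (int)u.size();
    for (int g = 0; g < G; ++g) {
      double m = mu ? (*mu)[g] : 0.0;
      lr += ldnorm(u[g] - d, m, sigma) - ldnorm(u[g], m, sigma);
    }
    double alpha = lr >= 0 ? 1.0 : std::exp(lr);
    if (u01 < alpha) {
      beta0 += d;
      for (int g = 0; g < G; ++g) u[g] -= d;
    }
    ad.step(ls, alpha, iter);
    track("shift", alpha);
  };

  // prior-only update of a sd on the log scale (gamma prior, Jacobian folded:
  // target in log sigma is shape*log(sigma) - rate*sigma + normal terms).
  auto sigma_update = [&](double &sg, double &ls, const std::vector<double> &u,
                          const std::vector<double> *mu, int G,
                          const char *blk, int iter) {
    double d = std::exp(ls) * norm_rand();
    double u01 = unif_rand();
    double sn = sg * std::exp(d);
    double lr = sig_shape * d - sig_rate * (sn - sg);
    for (int g = 0; g < G; ++g) {
      double m = mu ? (*mu)[g] : 0.0;
      lr += ldnorm(u[g], m, sn) - ldnorm(u[g], m, sg);
    }
    double alpha = lr >= 0 ? 1.0 : std::exp(lr);
    if (u01 < alpha) sg = sn;
    ad.step(ls, alpha, iter);
    track(blk, alpha);
  };

  int keep_pos = 0;
  for (int iter = 1; iter <= n_iter; ++iter) {
    if (iter % 256 == 0) Rcpp::checkUserInterrupt();

    coef_update(beta0, ls_beta0, nullptr, -1.0, "beta0", iter);
    for (int k = 0; k < K; ++k) coef_update(beta[k], ls_beta[k], &X(0, k), lam, "beta", iter);
    if (use_gov) coef_update(bgov, ls_bgov, &gov[0], lam, "beta", iter);

    // latent missing cells against prior x likelihood
    if (impute) {
      int cx = 0;
      for (int k = 0; k < K; ++k) {
        IntegerVector id = misX[k];
        for (int j = 0; j < id.size(); ++j, ++cx) {
          int i = id[j];
          double v = X(i, k);
          double d = std::exp(ls_impX[cx]) * norm_rand();
          double u01 = unif_rand();
          double e = eta[i] + beta[k] * d;
          double le = l1pe(e);
          double dl = y[i] * beta[k] * d - ntot[i] * (le - lpe[i]);
          double lr = dl - 0.5 * ((v + d) * (v + d) - v * v);
          double alpha = lr >= 0 ? 1.0 : std::exp(lr);
          if (u01 < alpha) { X(i, k) = v + d; eta[i] = e; lpe[i] = le; cur_ll += dl; }
          ad.step(ls_impX[cx], alpha, iter);
          track("impute", alpha);
        }
      }
      for (int g = 0; g < nImpGov; ++g) {
        IntegerVector grp = misGov[g];
        double v = gov[grp[0]];
        double d = std::exp(ls_impGov[g]) * norm_rand();
        double u01 = unif_rand();
        double dl = 0.0;
        for (int j = 0; j < grp.size(); ++j) {
          int i = grp[j];
          double e = eta[i] + bgov * d;
          eta_p[i] = e; lpe_p[i] = l1pe(e);
          dl += y[i] * bgov * d - ntot[i] * (lpe_p[i] - lpe[i]);
        }
        double lr = dl - 0.5 * ((v + d) * (v + d) - v * v);
        double alpha = lr >= 0 ? 1.0 : std::exp(lr);
        if (u01 < alpha) {
          for (int j = 0; j < grp.size(); ++j) {
            int i = grp[j];
            gov[i] = v + d; eta[i] = eta_p[i]; lpe[i] = lpe_p[i];
          }
          cur_ll += dl;
        }
        ad.step(ls_impGov[g], alpha, iter);
        track("impute", alpha);
      }
      int cz = 0;
      for (int p = 0; p < P; ++p) {
        IntegerVector id = misZ[p];
        for (int j = 0; j < id.size(); ++j, ++cz) {
          int s = id[j];
          double v = Z(s, p);
          double d = std::exp(ls_impZ[cz]) * norm_rand();
          double u01 = unif_rand();
          double lr = ldnorm(usite[s], mu_site[s] + gam[p] * d, sig_site) -
                      ldnorm(usite[s], mu_site[s], sig_site) -
                      0.5 * ((v + d) * (v + d) - v * v);
          double alpha = lr >= 0 ? 1.0 : std::exp(lr);
          if (u01 < alpha) { Z(s, p) = v + d; mu_site[s] += gam[p] * d; }
          ad.step(ls_impZ[cz], alpha, iter);
          track("impute", alpha);
        }
      }
      for (int j = 0; j < nImpPrice; ++j) {
        int t = misPrice[j];
        double v = price[t];
        double d = std::exp(ls_impPrice[j]) * norm_rand();
        double u01 = unif_rand();
        double lr = ldnorm(uyear[t], mu_year[t] + bprice * d, sig_year) -
                    ldnorm(uyear[t], mu_year[t], sig_year) -
                    0.5 * ((v + d) * (v + d) - v * v);
        double alpha = lr >= 0 ? 1.0 : std::exp(lr);
        if (u01 < alpha) { price[t] = v + d; mu_year[t] += bprice * d; }
        ad.step(ls_impPrice[j], alpha, iter);
        track("impute", alpha);
      }
    }

    // random intercepts
    if (use_sy) {
      for (int i = 0; i < n; ++i) {
        double d = std::exp(ls_usy[i]) * norm_rand();
        double u01 = unif_rand();
        double e = eta[i] + d;
        double le = l1pe(e);
        double dl = y[i] * d - ntot[i] * (le - lpe[i]);
        double lr = dl + ldnorm(usy[i] + d, 0.0, sig_sy) - ldnorm(usy[i], 0.0, sig_sy);
        double alpha = lr >= 0 ? 1.0 : std::exp(lr);
        if (u01 < alpha) { usy[i] += d; eta[i] = e; lpe[i] = le; cur_ll += dl; }
        ad.step(ls_usy[i], alpha, iter);
        track("u_siteyear", alpha);
      }
    }
    if (use_site) group_update(usite, ls_usite, site, S, &mu_site, sig_site, "u_site", iter);
    if (use_year) group_update(uyear, ls_uyear, year, Y, &mu_year, sig_year, "u_year", iter);
    if (use_country) group_update(ucountry, ls_ucty, country, C, nullptr, sig_cty, "u_country", iter);

    // intercept-ridge translations (one per enabled level)
    if (use_site) shift_update(usite, &mu_site, sig_site, ls_shift[0], iter);
    if (use_year) shift_update(uyear, &mu_year, sig_year, ls_shift[1], iter);
    if (use_sy) shift_update(usy, nullptr, sig_sy, ls_shift[2], iter);
    if (use_country) shift_update(ucountry, nullptr, sig_cty, ls_shift[3], iter);

    // hierarchical mean regressions (prior-only likelihood for the intercepts)
    if (use_site) {
      for (int p = 0; p < P; ++p) {
        double d = std::exp(ls_gam[p]) * norm_rand();
        double u01 = unif_rand();
        double lr = -lam * (std::fabs(gam[p] + d) - std::fabs(gam[p]));
        for (int s = 0; s < S; ++s) {
          lr += ldnorm(usite[s], mu_site[s] + d * Z(s, p), sig_site) -
                ldnorm(usite[s], mu_site[s], sig_site);
        }
        double alpha = lr >= 0 ? 1.0 : std::exp(lr);
        if (u01 < alpha) {
          gam[p] += d;
          for (int s = 0; s < S; ++s) mu_site[s] += d * Z(s, p);
        }
        ad.step(ls_gam[p], alpha, iter);
        track("gamma", alpha);
      }
    }
    if (use_price) {
      double d = std::exp(ls_bprice) * norm_rand();
      double u01 = unif_rand();
      double lr = -lam * (std::fabs(bprice + d) - std::fabs(bprice));
      for (int t = 0; t < Y; ++t) {
        lr += ldnorm(uyear[t], mu_year[t] + d * price[t], sig_year) -
              ldnorm(uyear[t], mu_year[t], sig_year);
      }
      double alpha = lr >= 0 ? 1.0 : std::exp(lr);
      if (u01 < alpha) {
        bprice += d;
        for (int t = 0; t < Y; ++t) mu_year[t] += d * price[t];
      }
      ad.step(ls_bprice, alpha, iter);
      track("beta_price", alpha);
    }

    // variance components and the LASSO rate
    if (use_site) sigma_update(sig_site, ls_sig[0], usite, &mu_site, S, "sigma", iter);
    if (use_year) sigma_update(sig_year, ls_sig[1], uyear, &mu_year, Y, "sigma", iter);
    if (use_sy) sigma_update(sig_sy, ls_sig[2], usy, nullptr, n, "sigma", iter);
    if (use_country) sigma_update(sig_cty, ls_sig[3], ucountry, nullptr, C, "sigma", iter);
    {
      double d = std::exp(ls_lam) * norm_rand();
      double u01 = unif_rand();
      double ln = lam * std::exp(d);
      double sumabs = 0.0;
      for (int k = 0; k < K; ++k) sumabs += std::fabs(beta[k]);
      if (use_gov) sumabs += std::fabs(bgov);
      for (int p = 0; p < P; ++p) sumabs += std::fabs(gam[p]);
      if (use_price) sumabs += std::fabs(bprice);
      double lr = n_coef * d - (ln - lam) * sumabs + lam_shape * d - lam_rate * (ln - lam);
      double alpha = lr >= 0 ? 1.0 : std::exp(lr);
      if (u01 < alpha) lam = ln;
      ad.step(ls_lam, alpha, iter);
      track("lambda", alpha);
    }

    // record retained draw
    if (keep_pos < keep.size() && iter == keep[keep_pos]) {
      int c = 0;
      draws(keep_pos, c++) = beta0;
      for (int k = 0; k < K; ++k) draws(keep_pos, c++) = beta[k];
      if (use_gov) draws(keep_pos, c++) = bgov;
      for (int p = 0; p < P; ++p) draws(keep_pos, c++) = gam[p];
      if (use_price) draws(keep_pos, c++) = bprice;
      if (use_site) draws(keep_pos, c++) = sig_site;
      if (use_year) draws(keep_pos, c++) = sig_year;
      if (use_sy) draws(keep_pos, c++) = sig_sy;
      if (use_country) draws(keep_pos, c++) = sig_cty;
      draws(keep_pos, c++) = lam;
      if (use_site) for (int s = 0; s < S; ++s) draws(keep_pos, c++) = usite[s];
      if (use_year) for (int t = 0; t < Y; ++t) draws(keep_pos, c++) = uyear[t];
      if (use_country) for (int cc = 0; cc < C; ++cc) draws(keep_pos, c++) = ucountry[cc];
      if (use_sy) for (int i = 0; i < n; ++i) draws(keep_pos, c++) = usy[i];
      for (int k = 0; k < K; ++k) {
        IntegerVector id = misX[k];
        for (int j = 0; j < id.size(); ++j) draws(keep_pos, c++) = X(id[j], k);
      }
      for (int g = 0; g < nImpGov; ++g) {
        IntegerVector grp = misGov[g];
        draws(keep_pos, c++) = gov[grp[0]];
      }
      for (int p = 0; p < P; ++p) {
        IntegerVector id = misZ[p];
        for (int j = 0; j < id.size(); ++j) draws(keep_pos, c++) = Z(id[j], p);
      }
      for (int j = 0; j < nImpPrice; ++j) draws(keep_pos, c++) = price[misPrice[j]];
      draws(keep_pos, c++) = ll_const + cur_ll + full_lprior();
      ++keep_pos;
    }
  }

  NumericVector acc_rate(acc.size());
  CharacterVector acc_names(acc.size());
  int j = 0;
  for (auto &kv : acc) {
    acc_names[j] = kv.first;
    acc_rate[j] = kv.second.first / kv.second.second;
    ++j;
  }
  acc_rate.attr("names") = acc_names;

  return List::create(_["draws"] = draws, _["accept"] = acc_rate,
                      _["final_lp"] = ll_const + cur_ll + full_lprior());
}
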