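# Model specification, parameter states and the exact posterior density
# components. These R implementations are the reference path for the model's
# mathematics; the MCMC engine (src/mwg.cpp) maintains the same quantities
# incrementally and is cross-checked against them in the tests.

#' Specify the hierarchical PIKE model
#'
#' The model treats the illegal-carcass count of each site-year record as
#' binomial with the total detected carcasses as trials, and regresses
#' logit(PIKE) on site-by-year covariates, country-by-year governance and
#' four levels of normal random intercepts (site, year, site-year, country).
#' The site intercept mean is itself a regression on site covariates (area,
#' law-enforcement capacity, travel time, species) and the year intercept
#' mean a regression on the global ivory-price trend. All covariate
#' coefficients receive Laplace (double-exponential) priors with a common
#' rate lambda — the Bayesian LASSO — and lambda a gamma hyperprior; random
#' effect standard deviations receive gamma(1, 1) priors.
#'
#' @param site_year_covariates character vector of record-level covariate
#'   names (may be empty).
#' @param country_year_covariate name of the country-by-year covariate
#'   (`NULL` to drop).
#' @param site_covariates covariates for the site-intercept mean regression
#'   (requires the `site` random effect).
#' @param year_covariate covariate for the year-intercept mean regression
#'   (requires the `year` random effect).
#' @param random_effects subset of `c("site", "year", "siteyear", "country")`.
#' @param priors list with elements `lambda_shape`, `lambda_rate` (gamma
#'   hyperprior on the LASSO rate), `beta0_sd` (normal prior sd of the
#'   intercept), `sigma_shape`, `sigma_rate` (gamma prior on random-effect
#'   sds; 1, 1 as in the model this package implements).
#' @return An object of class `pike_model_spec`.
#' @export
model_spec <- function(site_year_covariates = c("conflict_lag2", "elephant_density",
                                                "wealth", "health",
                                                "precip_anomaly", "ndvi"),
                       country_year_covariate = "governance",
                       site_covariates = c("area_km2", "law_enforcement",
                                           "travel_time", "species"),
                       year_covariate = "ivory_price",
                       random_effects = c("site", "year", "siteyear", "country"),
                       priors = list()) {
  defaults <- list(lambda_shape = 1, lambda_rate = 1, beta0_sd = 10,
                   sigma_shape = 1, sigma_rate = 1)
  priors <- utils::modifyList(defaults, priors)
  random_effects <- as.character(random_effects %||% character())
  bad <- setdiff(random_effects, c("site", "year", "siteyear", "country"))
  if (length(bad)) {
    stop_validation("unknown random effect level(s): %s", paste(bad, collapse = ", "))
  }
  site_year_covariates <- as.character(site_year_covariates %||% character())
  site_covariates <- as.character(site_covariates %||% character())
  if (length(site_covariates) && !"site" %in% random_effects) {
    stop_validation("site covariates require the site random effect")
  }
  if (!is.null(year_covariate) && !"year" %in% random_effects) {
    stop_validation("the year covariate requires the year random effect")
  }
  structure(list(site_year_covariates = site_year_covariates,
                 country_year_covariate = country_year_covariate,
                 site_covariates = site_covariates,
                 year_covariate = year_covariate,
                 random_effects = random_effects,
                 priors = priors),
            class = "pike_model_spec")
}

#' Random-effects-only companion of a model specification
#'
#' Drops every covariate term but keeps the intercept and the random-effect
#' structure; used as the baseline for the proportional change in variance
#' analysis ([pcv()]).
#'
#' @param spec a `pike_model_spec`.
#' @return A `pike_model_spec` with all covariate lists empty.
#' @export
re_only_spec <- function(spec) {
  model_spec(site_year_covariates = character(),
             country_year_covariate = NULL,
             site_covariates = character(),
             year_covariate = NULL,
             random_effects = spec$random_effects,
             priors = spec$priors)
}

#' MCMC settings
#'
#' Defaults follow the full-length analysis this model class was built for:
#' 100000 iterations with a 50000 burn-in per chain, 3 chains, and 5000
#' retained posterior draws in total (even-stride thinning after burn-in).
#' Random-walk scales adapt toward a 0.44 acceptance rate during burn-in
#' only, so the post-burn-in kernel satisfies detailed balance.
#'
#' @param n_iterations iterations per chain.
#' @param n_burnin burn-in iterations per chain (discarded).
#' @param n_chains number of chains.
#' @param n_retained total retained draws across chains.
#' @param seed master seed; each chain uses a deterministic sub-seed.
#' @param adapt_target target acceptance rate for scale adaptation.
#' @param init_spread sd of the normal used to overdisperse chain starting
#'   values for coefficients.
#' @return An object of class `pike_mcmc_config`.
#' @export
mcmc_config <- function(n_iterations = 100000L, n_burnin = 50000L,
                        n_chains = 3L, n_retained = 5000L, seed = 1L,
                        adapt_target = 0.44, init_spread = 1) {
  n_iterations <- as.integer(n_iterations); n_burnin <- as.integer(n_burnin)
  n_chains <- as.integer(n_chains); n_retained <- as.integer(n_retained)
  if (n_burnin >= n_iterations) stop_validation("n_burnin must be < n_iterations")
  if (n_chains < 1) stop_validation("need at least one chain")
  if (n_retained > (n_iterations - n_burnin) * n_chains) {
    stop_validation("n_retained exceeds post-burn-in draws")
  }
  structure(list(n_iterations = n_iterations, n_burnin = n_burnin,
                 n_chains = n_chains, n_retained = n_retained,
                 seed = as.integer(seed), adapt_target = adapt_target,
                 init_spread = init_spread),
            class = "pike_mcmc_config")
}

# ---------------------------------------------------------------------------
# Model frame: the panel resolved against a spec into index vectors and
# design matrices, with missing-cell bookkeeping. All indices 1-based here;
# converted to 0-based at the C++ boundary.
build_frame <- function(panel, spec) {
  stopifnot(inherits(panel, "carcass_panel"), inherits(spec, "pike_model_spec"))
  rec <- panel$records[panel$records$n_total >= 1, , drop = FALSE]
  if (nrow(rec) == 0) stop_validation("no modelled records (all n_total = 0)")

  st <- panel$sites
  site_ids <- st$site_id[st$site_id %in% rec$site_id]
  years_u <- sort(unique(rec$year))
  country_ids <- unique(st$country_id[match(site_ids, st$site_id)])

  miss_cov <- setdiff(c(spec$site_year_covariates, spec$site_covariates),
                      c(panel$covariates,
                        setdiff(names(st), c("site_id", "country_id"))))
  if (length(miss_cov)) {
    stop_validation("covariate(s) not found in panel: %s",
                    paste(miss_cov, collapse = ", "))
  }

  n <- nrow(rec)
  K <- length(spec$site_year_covariates)
  X <- if (K) as.matrix(rec[spec$site_year_covariates]) else matrix(0, n, 0)
  storage.mode(X) <- "double"

  use_gov <- !is.null(spec$country_year_covariate)
  gov <- numeric(n)
  gov_cell_of_rec <- integer(n)
  gov_cells <- data.frame(country_id = character(), year = integer())
  if (use_gov) {
    cy <- panel$country_years
    if (!spec$country_year_covariate %in% names(cy)) {
      stop_validation("country-year covariate '%s' not found", spec$country_year_covariate)
    }
    m <- match(paste(rec$country_id, rec$year), paste(cy$country_id, cy$year))
    gov <- cy[[spec$country_year_covariate]][m]
    na_cells <- unique(m[is.na(gov)])
    gov_cells <- cy[na_cells, c("country_id", "year"), drop = FALSE]
    gov_cell_of_rec <- match(m, na_cells) # NA where observed
  }

  use_site <- "site" %in% spec$random_effects
  use_year <- "year" %in% spec$random_effects
  use_sy <- "siteyear" %in% spec$random_effects
  use_country <- "country" %in% spec$random_effects

  P <- length(spec$site_covariates)
  S <- length(site_ids)
  Z <- if (P) as.matrix(st[match(site_ids, st$site_id), spec$site_covariates, drop = FALSE])
       else matrix(0, S, 0)
  storage.mode(Z) <- "double"

  use_price <- !is.null(spec$year_covariate)
  price <- numeric(length(years_u))
  if (use_price) {
    if (!spec$year_covariate %in% names(panel$years)) {
      stop_validation("year covariate '%s' not found", spec$year_covariate)
    }
    price <- panel$years[[spec$year_covariate]][match(years_u, panel$years$year)]
  }

  list(
    n = n, y = as.numeric(rec$n_illegal), ntot = as.numeric(rec$n_total),
    rec = rec,
    site = match(rec$site_id, site_ids),
    year = match(rec$year, years_u),
    country = match(st$country_id[match(rec$site_id, st$site_id)], country_ids),
    site_ids = site_ids, years = years_u, country_ids = country_ids,
    S = S, Y = length(years_u), C = length(country_ids),
    X = X, K = K, gov = gov, use_gov = use_gov,
    gov_cells = gov_cells, gov_cell_of_rec = gov_cell_of_rec,
    Z = Z, P = P, price = price, use_price = use_price,
    use_site = use_site, use_year = use_year, use_sy = use_sy,
    use_country = use_country,
    mis_X = lapply(seq_len(K), function(k) which(is.na(X[, k]))),
    mis_gov = if (nrow(gov_cells)) lapply(seq_len(nrow(gov_cells)),
                                          function(g) which(gov_cell_of_rec == g))
              else list(),
    mis_Z = lapply(seq_len(P), function(p) which(is.na(Z[, p]))),
    mis_price = if (use_price) which(is.na(price)) else integer(),
    spec = spec
  )
}

n_missing_cells <- function(fr) {
  sum(lengths(fr$mis_X)) + length(fr$mis_gov) + sum(lengths(fr$mis_Z)) +
    length(fr$mis_price)
}

# Inject a state's imputed values into a frame's design objects; error on any
# unresolved missing cell.
fill_frame <- function(fr, state) {
  imp <- state$imputed %||% list()
  if (any(lengths(fr$mis_X) > 0)) {
    tab <- imp$records
    for (k in seq_len(fr$K)) {
      for (i in fr$mis_X[[k]]) {
        cv <- fr$spec$site_year_covariates[k]
        v <- if (!is.null(tab)) tab$value[tab$site_id == fr$rec$site_id[i] &
                                            tab$year == fr$rec$year[i] &
                                            tab$covariate == cv]
        if (is.null(v) || length(v) != 1) {
          stop_validation("unresolved missing cell: %s at %s:%d",
                          cv, fr$rec$site_id[i], fr$rec$year[i])
        }
        fr$X[i, k] <- v
      }
    }
  }
  if (length(fr$mis_gov)) {
    tab <- imp$country_years
    for (g in seq_along(fr$mis_gov)) {
      v <- if (!is.null(tab)) tab$value[tab$country_id == fr$gov_cells$country_id[g] &
                                          tab$year == fr$gov_cells$year[g]]
      if (is.null(v) || length(v) != 1) {
        stop_validation("unresolved missing governance cell %s:%d",
                        fr$gov_cells$country_id[g], fr$gov_cells$year[g])
      }
      fr$gov[fr$mis_gov[[g]]] <- v
    }
  }
  if (any(lengths(fr$mis_Z) > 0)) {
    tab <- imp$sites
    for (p in seq_len(fr$P)) {
      for (s in fr$mis_Z[[p]]) {
        cv <- fr$spec$site_covariates[p]
        v <- if (!is.null(tab)) tab$value[tab$site_id == fr$site_ids[s] &
                                            tab$covariate == cv]
        if (is.null(v) || length(v) != 1) {
          stop_validation("unresolved missing site covariate %s at %s", cv, fr$site_ids[s])
        }
        fr$Z[s, p] <- v
      }
    }
  }
  if (length(fr$mis_price)) {
    tab <- imp$years
    for (t in fr$mis_price) {
      v <- if (!is.null(tab)) tab$value[tab$year == fr$years[t]]
      if (is.null(v) || length(v) != 1) {
        stop_validation("unresolved missing ivory price for year %d", fr$years[t])
      }
      fr$price[t] <- v
    }
  }
  fr
}

state_mu_site <- function(fr, state) {
  if (fr$P) drop(fr$Z %*% state$gamma[fr$spec$site_covariates]) else numeric(fr$S)
}

state_mu_year <- function(fr, state) {
  if (fr$use_price) state$beta_price * fr$price else numeric(fr$Y)
}

#' Linear predictor of the PIKE model
#'
#' Assembles, for every modelled record, eta = beta0 + X beta + governance
#' effect + site + year + site-year + country intercepts. PIKE for the
#' record is `plogis(eta)`. Missing covariate cells must have imputed values
#' in `state$imputed`.
#'
#' @param state a parameter state: a named list with `beta0`, `beta` (named
#'   by site-year covariate), `beta_gov`, `gamma` (named by site covariate),
#'   `beta_price`, `u_site`, `u_year`, `u_siteyear`, `u_country`,
#'   `sigma_site`, `sigma_year`, `sigma_siteyear`, `sigma_country`, `lambda`,
#'   and optionally `imputed`.
#' @param panel a `carcass_panel`.
#' @param spec a `pike_model_spec`.
#' @return Numeric vector eta, one element per modelled record.
#' @export
linear_predictor <- function(state, panel, spec = model_spec()) {
  fr <- fill_frame(build_frame(panel, spec), state)
  eta <- rep(state$beta0, fr$n)
  if (fr$K) eta <- eta + drop(fr$X %*% state$beta[fr$spec$site_year_covariates])
  if (fr$use_gov) eta <- eta + state$beta_gov * fr$gov
  if (fr$use_site) eta <- eta + state$u_site[fr$site]
  if (fr$use_year) eta <- eta + state$u_year[fr$year]
  if (fr$use_sy) eta <- eta + state$u_siteyear
  if (fr$use_country) eta <- eta + state$u_country[fr$country]
  if (any(!is.finite(eta))) stop_validation("non-finite linear predictor")
  unname(eta)
}

#' Binomial log-likelihood of the PIKE model
#'
#' Sum over modelled records of the binomial log pmf of the illegal-carcass
#' count given `plogis(eta)`. Computed as
#' `lchoose(n, y) + y * eta - n * log(1 + exp(eta))` which stays finite for
#' arbitrarily large |eta|.
#'
#' @inheritParams linear_predictor
#' @return A single number.
#' @export
log_likelihood <- function(state, panel, spec = model_spec()) {
  fr <- build_frame(panel, spec)
  eta <- linear_predictor(state, panel, spec)
  sum(lchoose(fr$ntot, fr$y) + fr$y * eta - fr$ntot * log1pexp(eta))
}

#' Log prior density of a parameter state
#'
#' Sum of: Laplace(rate lambda) terms for every covariate coefficient
#' (site-year, governance, site-mean, price), the gamma hyperprior on
#' lambda, normal(0, beta0_sd) on the intercept, gamma(shape, rate) terms on
#' each enabled random-effect sd, the normal random-intercept densities (site
#' intercepts around their site-covariate mean, year intercepts around the
#' price-trend mean, site-year and country intercepts around zero), and a
#' standard-normal term for every imputed missing cell. Returns `-Inf` for
#' non-positive sds or lambda.
#'
#' @inheritParams linear_predictor
#' @return A single number.
#' @export
log_prior <- function(state, panel, spec = model_spec()) {
  fr <- fill_frame(build_frame(panel, spec), state)
  pr <- spec$priors
  sig <- c(site = state$sigma_site, year = state$sigma_year,
           siteyear = state$sigma_siteyear, country = state$sigma_country)
  used <- spec$random_effects
  if (any(!is.finite(sig[used])) || any(sig[used] <= 0) ||
      !is.finite(state$lambda) || state$lambda <= 0) {
    return(-Inf)
  }
  coefs <- c(if (fr$K) state$beta[fr$spec$site_year_covariates],
             if (fr$use_gov) state$beta_gov,
             if (fr$P) state$gamma[fr$spec$site_covariates],
             if (fr$use_price) state$beta_price)
  lp <- stats::dnorm(state$beta0, 0, pr$beta0_sd, log = TRUE) +
    sum(dlaplace_log(coefs, state$lambda)) +
    stats::dgamma(state$lambda, pr$lambda_shape, rate = pr$lambda_rate, log = TRUE) +
    sum(stats::dgamma(sig[used], pr$sigma_shape, rate = pr$sigma_rate, log = TRUE))
  if (fr$use_site) {
    lp <- lp + sum(stats::dnorm(state$u_site, state_mu_site(fr, state),
                                state$sigma_site, log = TRUE))
  }
  if (fr$use_year) {
    lp <- lp + sum(stats::dnorm(state$u_year, state_mu_year(fr, state),
                                state$sigma_year, log = TRUE))
  }
  if (fr$use_sy) lp <- lp + sum(stats::dnorm(state$u_siteyear, 0, state$sigma_siteyear, log = TRUE))
  if (fr$use_country) lp <- lp + sum(stats::dnorm(state$u_country, 0, state$sigma_country, log = TRUE))
  imp <- state$imputed %||% list()
  for (tab in imp) if (!is.null(tab) && nrow(tab)) {
    lp <- lp + sum(stats::dnorm(tab$value, 0, 1, log = TRUE))
  }
  lp
}

#' Log posterior density (unnormalized)
#'
#' Exactly `log_likelihood(state, ...) + log_prior(state, ...)` — one code
#' path, no separate implementation.
#'
#' @inheritParams linear_predictor
#' @return A single number.
#' @export
log_posterior <- function(state, panel, spec = model_spec()) {
  log_likelihood(state, panel, spec) + log_prior(state, panel, spec)
}
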