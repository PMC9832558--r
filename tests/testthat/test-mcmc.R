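# The Metropolis-within-Gibbs engine: determinism, exactness against
# quadrature, consistency with the R-side posterior density, imputation
# semantics, shrinkage behaviour.

test_that("identical seeds give identical retained draws", {
  d <- simulate_panel(fast_sim_config(seed = 2))
  f1 <- pike_glmm(d$panel, d$spec, fast_mcmc())
  f2 <- pike_glmm(d$panel, d$spec, fast_mcmc())
  expect_identical(f1$draws, f2$draws)
  f3 <- pike_glmm(d$panel, d$spec, fast_mcmc(seed = 8))
  expect_false(identical(f1$draws[[1]], f3$draws[[1]]))
})

test_that("intercept-only posterior matches 1-D grid quadrature", {
  panel <- one_record_panel(7L, 10L)
  spec <- intercept_only_spec()
  fit <- pike_glmm(panel, spec,
                   mcmc_config(n_iterations = 20000, n_burnin = 4000,
                               n_chains = 2, n_retained = 8000, seed = 5))
  # exact 1-D posterior: N(beta0; 0, 10) x Binom(7; 10, plogis(beta0))
  g <- seq(-8, 8, length.out = 20001)
  w <- stats::dnorm(g, 0, 10) * stats::dbinom(7, 10, stats::plogis(g))
  w <- w / sum(w)
  exact_mean_pike <- sum(stats::plogis(g) * w)
  dr <- draws_matrix(fit)
  pike_draws <- stats::plogis(dr[, "beta0"])
  se <- mcse(pike_draws)
  expect_lt(abs(mean(pike_draws) - exact_mean_pike), 3 * se + 1e-4)
  # quantiles agree too
  cdf <- cumsum(w)
  exact_q50 <- stats::plogis(g[which.min(abs(cdf - 0.5))])
  expect_lt(abs(stats::median(pike_draws) - exact_q50), 0.02)
})

test_that("the sampler's log posterior agrees with the R density path", {
  # reconstruct the state at a retained draw and evaluate the pure-R
  # log_likelihood + log_prior; must match the chain's recorded lp__
  d <- simulate_panel(fast_sim_config(seed = 6,
                                      missing_rates = c(wealth = 0.1,
                                                        governance = 0.1,
                                                        ivory_price = 0.2)))
  fit <- pike_glmm(d$panel, d$spec, fast_mcmc())
  fr <- fit$frame
  D <- draws_matrix(fit)
  for (row in c(1L, nrow(D))) {
    dr <- D[row, ]
    spec <- fit$spec
    imp <- list()
    mis <- names(dr)[startsWith(names(dr), "imp[")]
    if (length(mis)) {
      parts <- sub("^imp\\[(.*)\\]$", "\\1", mis)
      recs <- NULL; cys <- NULL; yrs <- NULL; sts <- NULL
      for (i in seq_along(parts)) {
        f <- strsplit(parts[i], ":", fixed = TRUE)[[1]]
        if (f[1] %in% spec$site_year_covariates) {
          recs <- rbind(recs, data.frame(site_id = f[2], year = as.integer(f[3]),
                                         covariate = f[1], value = dr[mis[i]]))
        } else if (identical(f[1], spec$country_year_covariate)) {
          cys <- rbind(cys, data.frame(country_id = f[2], year = as.integer(f[3]),
                                       value = dr[mis[i]]))
        } else if (identical(f[1], spec$year_covariate)) {
          yrs <- rbind(yrs, data.frame(year = as.integer(f[2]), value = dr[mis[i]]))
        } else {
          sts <- rbind(sts, data.frame(site_id = f[2], covariate = f[1],
                                       value = dr[mis[i]]))
        }
      }
      imp <- list(records = recs, country_years = cys, years = yrs, sites = sts)
    }
    st <- list(beta0 = dr[["beta0"]],
               beta = dr[spec$site_year_covariates],
               beta_gov = dr[[spec$country_year_covariate]],
               gamma = dr[spec$site_covariates],
               beta_price = dr[[spec$year_covariate]],
               u_site = stats::setNames(dr[sprintf("u_site[%s]", fr$site_ids)], fr$site_ids),
               u_year = stats::setNames(dr[sprintf("u_year[%d]", fr$years)], as.character(fr$years)),
               u_siteyear = unname(dr[sprintf("u_siteyear[%s:%d]", fr$rec$site_id, fr$rec$year)]),
               u_country = stats::setNames(dr[sprintf("u_country[%s]", fr$country_ids)], fr$country_ids),
               sigma_site = dr[["sigma_site"]], sigma_year = dr[["sigma_year"]],
               sigma_siteyear = dr[["sigma_siteyear"]],
               sigma_country = dr[["sigma_country"]],
               lambda = dr[["lambda"]], imputed = imp)
    names(st$beta) <- spec$site_year_covariates
    names(st$gamma) <- spec$site_covariates
    expect_equal(log_posterior(st, d$panel, spec), dr[["lp__"]], tolerance = 1e-8)
  }
})

test_that("with no missing cells, the imputation machinery is inert", {
  d <- simulate_panel(fast_sim_config(seed = 9))
  f_mcmc <- pike_glmm(d$panel, d$spec, fast_mcmc(), impute = "mcmc")
  f_off <- pike_glmm(d$panel, d$spec, fast_mcmc(), impute = "none")
  expect_identical(f_mcmc$draws, f_off$draws)
  f_once <- pike_glmm(d$panel, d$spec, fast_mcmc(), impute = "oneshot")
  expect_identical(f_mcmc$draws, f_once$draws)
})

test_that("impute = 'none' refuses panels with missing cells", {
  d <- simulate_panel(fast_sim_config(seed = 10, missing_rates = c(wealth = 0.2)))
  expect_error(pike_glmm(d$panel, d$spec, fast_mcmc(), impute = "none"),
               "missing covariate cell", class = "pike_validation_error")
})

test_that("a strong single signal is recovered and nulls are shrunk", {
  cfg <- simulation_config(
    n_sites = 20, n_countries = 6, n_years = 8, presence_prob = 1,
    total_carcass_law = list(family = "nbinom", mean = 200, dispersion = 2, min = 1),
    true_beta0 = 0,
    true_beta = c(conflict_lag2 = 0, elephant_density = 0, wealth = 1,
                  health = 0, precip_anomaly = 0, ndvi = 0, governance = 0),
    true_gamma = c(area_km2 = 0, law_enforcement = 0, travel_time = 0, species = 0),
    true_beta_price = 0,
    sigmas = c(site = 0.2, year = 0.2, siteyear = 0.2, country = 0.2), seed = 14)
  d <- simulate_panel(cfg)
  fit <- pike_glmm(d$panel, d$spec,
                   mcmc_config(n_iterations = 4000, n_burnin = 2000, n_chains = 2,
                               n_retained = 1500, seed = 2))
  cs <- coefficient_summary(fit)
  active <- cs[cs$name == "wealth", ]
  expect_true(active$ci_low <= 1 && 1 <= active$ci_high)
  expect_true(active$supported)
  nulls <- cs[cs$name %in% c("conflict_lag2", "elephant_density", "health",
                             "precip_anomaly", "ndvi"), ]
  expect_true(all(abs(nulls$mean) < abs(active$mean)))
})

test_that("stronger lambda hyperpriors shrink a null coefficient harder", {
  d <- simulate_panel(fast_sim_config(seed = 20))
  mean_abs_null <- function(lam0) {
    spec <- model_spec(priors = list(lambda_shape = 400, lambda_rate = 400 / lam0))
    fit <- pike_glmm(d$panel, spec, fast_mcmc(n_chains = 1, n_retained = 400))
    mean(abs(draws_matrix(fit)[, "elephant_density"]))
  }
  shrink_weak <- mean_abs_null(0.5)
  shrink_strong <- mean_abs_null(20)
  expect_lt(shrink_strong, shrink_weak)
})

test_that("acceptance rates adapt toward the configured target", {
  d <- simulate_panel(fast_sim_config(seed = 23))
  fit <- pike_glmm(d$panel, d$spec,
                   mcmc_config(n_iterations = 3000, n_burnin = 1500, n_chains = 1,
                               n_retained = 500, seed = 4))
  acc <- fit$accept[[1]]
  expect_true(all(acc > 0.2 & acc < 0.7))
})
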