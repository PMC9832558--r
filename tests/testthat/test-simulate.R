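# Synthetic panel generator: counting, determinism, generative correctness.

test_that("simulate_panel produces the configured panel dimensions", {
  cfg <- simulation_config(n_sites = 4, n_countries = 2, n_years = 3,
                           presence_prob = 1, seed = 5)
  d <- simulate_panel(cfg)
  expect_s3_class(d$panel, "carcass_panel")
  expect_equal(nrow(d$panel$records), 12)
  expect_equal(nrow(d$panel$sites), 4)
  expect_equal(nrow(d$panel$years), 3)
  expect_equal(nrow(d$panel$country_years), 6)
  expect_true(d$panel$standardized)
  expect_true(all(d$panel$records$n_total >= 1))
})

test_that("identical configurations give identical datasets", {
  cfg <- fast_sim_config(seed = 99)
  d1 <- simulate_panel(cfg)
  d2 <- simulate_panel(cfg)
  expect_identical(d1$panel, d2$panel)
  expect_identical(d1$truth, d2$truth)
})

test_that("the truth state reproduces the realized linear predictor", {
  cfg <- fast_sim_config(seed = 3, missing_rates = c(wealth = 0.2, ndvi = 0.1,
                                                     governance = 0.15,
                                                     ivory_price = 0.3,
                                                     law_enforcement = 0.2))
  d <- simulate_panel(cfg)
  expect_gt(pikeglmm:::n_missing_cells(pikeglmm:::build_frame(d$panel, d$spec)), 0)
  # the punched cells' true values are carried in truth$imputed, so the truth
  # state still evaluates to the eta that generated the counts
  eta <- linear_predictor(d$truth, d$panel, d$spec)
  expect_equal(eta, d$truth$eta, tolerance = 1e-12)
})

test_that("a null model with huge totals gives PIKE near one half", {
  cfg <- simulation_config(n_sites = 1, n_countries = 1, n_years = 1,
                           presence_prob = 1,
                           total_carcass_law = list(family = "fixed", mean = 1e6),
                           true_beta0 = 0,
                           true_beta = c(conflict_lag2 = 0, elephant_density = 0,
                                         wealth = 0, health = 0,
                                         precip_anomaly = 0, ndvi = 0,
                                         governance = 0),
                           true_gamma = c(area_km2 = 0, law_enforcement = 0,
                                          travel_time = 0, species = 0),
                           true_beta_price = 0,
                           sigmas = c(site = 0, year = 0, siteyear = 0, country = 0),
                           seed = 21)
  d <- simulate_panel(cfg)
  pike <- d$panel$records$n_illegal / d$panel$records$n_total
  expect_equal(pike, 0.5, tolerance = 0.002) # 3 binomial SEs ~ 0.0015
})

test_that("simulate_counts saturates at extreme eta and is calibrated at eta = 0", {
  expect_equal(simulate_counts(20, 50, seed = 1), 50)
  expect_equal(simulate_counts(-20, 50, seed = 1), 0)
  x <- simulate_counts(0, 1e6, seed = 2)
  expect_true(x / 1e6 > 0.4985 && x / 1e6 < 0.5015)
  expect_error(simulate_counts(0, 0), "n_total", class = "pike_validation_error")
})

test_that("punched missingness rates match their configuration", {
  cfg <- simulation_config(n_sites = 40, n_countries = 10, n_years = 12,
                           presence_prob = 1,
                           missing_rates = c(wealth = 0.2), seed = 8)
  d <- simulate_panel(cfg)
  n <- nrow(d$panel$records)
  rate <- mean(is.na(d$panel$records$wealth))
  expect_lt(abs(rate - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("realized site intercepts follow the site-covariate mean regression", {
  cfg <- simulation_config(n_sites = 150, n_countries = 10, n_years = 2,
                           presence_prob = 1,
                           true_gamma = c(area_km2 = 0.8, law_enforcement = -0.5,
                                          travel_time = 0, species = 0.5),
                           sigmas = c(site = 0.3, year = 0.2, siteyear = 0.3,
                                      country = 0.3),
                           seed = 17)
  d <- simulate_panel(cfg)
  Z <- as.matrix(d$panel$sites[c("area_km2", "law_enforcement", "travel_time", "species")])
  f <- stats::lm(d$truth$u_site ~ Z - 1)
  est <- stats::coef(summary(f))
  for (p in seq_len(4)) {
    truth <- c(0.8, -0.5, 0, 0.5)[p]
    expect_lt(abs(est[p, "Estimate"] - truth), 2.5 * est[p, "Std. Error"])
  }
})

test_that("mean simulated PIKE matches the logit-normal expectation", {
  # all covariate effects zero, intercept -0.5, total intercept variance
  # tau^2 = sum of the four sigma^2; E[plogis(eta)] from 1-D quadrature
  sig <- c(site = 0.4, year = 0.2, siteyear = 0.4, country = 0.3)
  cfg <- simulation_config(n_sites = 60, n_countries = 20, n_years = 16,
                           presence_prob = 1,
                           total_carcass_law = list(family = "fixed", mean = 200),
                           true_beta0 = -0.5,
                           true_beta = c(conflict_lag2 = 0, elephant_density = 0,
                                         wealth = 0, health = 0,
                                         precip_anomaly = 0, ndvi = 0,
                                         governance = 0),
                           true_gamma = c(area_km2 = 0, law_enforcement = 0,
                                          travel_time = 0, species = 0),
                           true_beta_price = 0, sigmas = sig, seed = 30)
  d <- simulate_panel(cfg)
  tau <- sqrt(sum(sig^2))
  analytic <- stats::integrate(function(u) stats::plogis(-0.5 + tau * u) * stats::dnorm(u),
                               -10, 10)$value
  pike <- mean(d$panel$records$n_illegal / d$panel$records$n_total)
  # MC error dominated by shared year/country effects; allow a generous band
  expect_lt(abs(pike - analytic), 0.05)
})

test_that("raw-scale mode exercises z_transform back to the model scale", {
  cfg <- fast_sim_config(seed = 12, raw_scale = TRUE)
  d <- simulate_panel(cfg)
  expect_false(d$panel$standardized)
  expect_gt(abs(mean(d$panel$records$wealth)), 1) # affine-shifted scale
  z <- z_transform(d$panel)
  expect_equal(mean(z$records$wealth), 0, tolerance = 1e-10)
  expect_equal(stats::sd(z$records$health), 1, tolerance = 1e-10)
})

test_that("write_dataset emits the CSV schema plus a truth file", {
  dir <- withr::local_tempdir()
  d <- simulate_panel(simulation_config(n_sites = 4, n_countries = 2, n_years = 3,
                                        presence_prob = 1, seed = 2))
  write_dataset(d, dir)
  p <- read_panel(file.path(dir, "records.csv"), file.path(dir, "sites.csv"),
                  file.path(dir, "country_years.csv"), file.path(dir, "years.csv"))
  expect_equal(nrow(p$records), nrow(d$panel$records))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$beta0, d$truth$beta0)
})
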