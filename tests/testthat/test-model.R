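# Posterior density components: linear predictor, likelihood, priors.

test_that("linear_predictor assembles eta from all model terms", {
  p <- z_transform(tiny_panel())
  spec <- tiny_spec()
  st <- zero_state(p, spec, imputed = zero_imputed(p, spec))
  expect_equal(linear_predictor(st, p, spec), rep(0, 5))
  st$beta0 <- 1
  expect_equal(linear_predictor(st, p, spec), rep(1, 5))
  expect_equal(stats::plogis(linear_predictor(st, p, spec))[1], 0.7311,
               tolerance = 1e-4)
  # single-covariate arithmetic: x = 2 with beta = 0.5 gives eta = 1
  p1 <- carcass_panel(
    data.frame(site_id = "A", country_id = "K1", year = 2002L,
               n_illegal = 1L, n_total = 2L, wealth = 2),
    data.frame(site_id = "A", country_id = "K1"),
    data.frame(country_id = "K1", year = 2002L),
    data.frame(year = 2002L), standardized = TRUE, standardization = list())
  spec1 <- model_spec(site_year_covariates = "wealth", country_year_covariate = NULL,
                      site_covariates = character(), year_covariate = NULL)
  st1 <- zero_state(p1, spec1)
  st1$beta <- c(wealth = 0.5)
  expect_equal(linear_predictor(st1, p1, spec1), 1)
  # group intercepts enter through their index maps
  st2 <- zero_state(p, spec, imputed = zero_imputed(p, spec))
  st2$u_site <- stats::setNames(c(10, 20, 30), c("A", "B", "C"))
  eta <- linear_predictor(st2, p, spec)
  expect_equal(eta, c(10, 10, 20, 20, 30))
  # unresolved missing cell errors
  st3 <- zero_state(p, spec)
  expect_error(linear_predictor(st3, p, spec), "unresolved",
               class = "pike_validation_error")
})

test_that("log_likelihood matches a naive product-of-binomial-PMFs oracle", {
  # closed form: one record (1 of 2) at eta = 0 has likelihood 1/2
  p1 <- one_record_panel(1L, 2L)
  spec <- intercept_only_spec()
  st <- zero_state(p1, spec)
  expect_equal(log_likelihood(st, p1, spec), log(0.5), tolerance = 1e-12)
  # additivity: duplicating the record doubles the log-likelihood
  p2 <- carcass_panel(
    data.frame(site_id = c("A", "A"), country_id = "K1", year = c(2002L, 2003L),
               n_illegal = 1L, n_total = 2L),
    data.frame(site_id = "A", country_id = "K1"),
    data.frame(country_id = "K1", year = 2002:2003),
    data.frame(year = 2002:2003), standardized = TRUE, standardization = list())
  expect_equal(log_likelihood(st, p2, spec), 2 * log(0.5), tolerance = 1e-12)
  # random small panels against dbinom directly
  set.seed(42)
  for (rep in 1:5) {
    d <- simulate_panel(fast_sim_config(seed = rep))
    st <- d$truth
    eta <- linear_predictor(st, d$panel, d$spec)
    rec <- d$panel$records
    naive <- sum(stats::dbinom(rec$n_illegal, rec$n_total, stats::plogis(eta),
                               log = TRUE))
    expect_equal(log_likelihood(st, d$panel, d$spec), naive, tolerance = 1e-10)
  }
  # stability at extreme eta: finite where dbinom's p saturates
  stx <- zero_state(p1, spec)
  stx$beta0 <- 800
  expect_true(is.finite(log_likelihood(stx, p1, spec)))
})

test_that("log_prior sums Laplace, gamma, normal and imputation terms", {
  p <- z_transform(tiny_panel())
  spec <- tiny_spec()
  st <- zero_state(p, spec, imputed = zero_imputed(p, spec))
  st$lambda <- 2
  # Laplace at beta = 0 with rate 2: log(2/2) = 0 per coefficient
  expect_equal(sum(dlnorm <- pikeglmm:::dlaplace_log(0, 2)), 0)
  # gamma(1,1) at sigma = 1: log density -1
  expect_equal(stats::dgamma(1, 1, 1, log = TRUE), -1)
  # normal at its mean with sd 1: -log(sqrt(2*pi))
  expect_equal(stats::dnorm(0, 0, 1, log = TRUE), -0.918939, tolerance = 1e-6)
  # full decomposition for the zero state
  n_coef <- length(spec$site_year_covariates) + 1 + length(spec$site_covariates) + 1
  fr <- pikeglmm:::build_frame(p, spec)
  n_imp <- pikeglmm:::n_missing_cells(fr)
  expected <- stats::dnorm(0, 0, 10, log = TRUE) +           # beta0
    n_coef * log(2 / 2) +                                    # Laplace terms
    stats::dgamma(2, 1, 1, log = TRUE) +                     # lambda hyperprior
    4 * stats::dgamma(1, 1, 1, log = TRUE) +                 # sigma priors
    (fr$S + fr$Y + fr$n + fr$C) * stats::dnorm(0, log = TRUE) + # intercepts
    n_imp * stats::dnorm(0, log = TRUE)                      # imputed cells
  expect_equal(log_prior(st, p, spec), expected, tolerance = 1e-12)
  # degenerate states are rejected with -Inf
  st_bad <- st; st_bad$sigma_site <- 0
  expect_identical(log_prior(st_bad, p, spec), -Inf)
  st_bad <- st; st_bad$lambda <- -1
  expect_identical(log_prior(st_bad, p, spec), -Inf)
})

test_that("log posterior is exactly likelihood plus prior", {
  d <- simulate_panel(fast_sim_config(seed = 4))
  expect_identical(log_posterior(d$truth, d$panel, d$spec),
                   log_likelihood(d$truth, d$panel, d$spec) +
                     log_prior(d$truth, d$panel, d$spec))
})

test_that("records with zero detected carcasses are excluded from the likelihood", {
  p <- tiny_panel(function(r) { r$n_total[5] <- 0L; r$n_illegal[5] <- 0L; r })
  fr <- pikeglmm:::build_frame(z_transform(p), tiny_spec())
  expect_equal(fr$n, 4)
  expect_equal(length(observed_pike(p)), 4)
})
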