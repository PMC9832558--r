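# Coefficient summaries, conditional effects, covariate-group PIKE tables.

test_that("coefficient_summary matches the order-statistic oracle", {
  set.seed(51)
  x <- matrix(stats::rnorm(5000), dimnames = list(NULL, "b"))
  cs <- coefficient_summary(x, level = 0.90)
  sorted <- sort(x[, 1])
  # equal-tailed 5%/95% bounds sit at the 250th/4750th order statistics up to
  # the interpolation convention
  expect_lt(abs(cs$ci_low - sorted[250]), sorted[252] - sorted[249])
  expect_lt(abs(cs$ci_high - sorted[4750]), sorted[4752] - sorted[4749])
  expect_false(cs$supported)
  expect_equal(cs$sign, "none")
  # degenerate draws
  cs2 <- coefficient_summary(matrix(0.7, 100, 1, dimnames = list(NULL, "b")))
  expect_equal(cs2$mean, 0.7)
  expect_equal(cs2$ci_low, 0.7)
  expect_true(cs2$supported)
  expect_equal(cs2$sign, "positive")
})

test_that("credible intervals are nested across decreasing levels and level 1 spans the draws", {
  set.seed(52)
  x <- matrix(stats::rgamma(2000, 2), dimnames = list(NULL, "b"))
  prev <- coefficient_summary(x, level = 1)
  expect_equal(prev$ci_low, min(x))
  expect_equal(prev$ci_high, max(x))
  for (lv in c(0.95, 0.9, 0.5, 0.1)) {
    cur <- coefficient_summary(x, level = lv)
    expect_gte(cur$ci_low, prev$ci_low - 1e-12)
    expect_lte(cur$ci_high, prev$ci_high + 1e-12)
    prev <- cur
  }
  expect_error(coefficient_summary(x, level = 0), "level",
               class = "pike_validation_error")
})

test_that("conditional effects reduce to closed forms for degenerate draws", {
  d <- simulate_panel(fast_sim_config(seed = 53))
  fit <- pike_glmm(d$panel, d$spec, fast_mcmc())
  # beta_j == 0 draws: flat curve at plogis(beta0_hat)
  fit0 <- fit
  fit0$draws <- lapply(fit$draws, function(m) { m[, "wealth"] <- 0; m })
  ce <- conditional_effect(fit0, "wealth", n_grid = 21)
  b0 <- mean(draws_matrix(fit0)[, "beta0"])
  expect_equal(ce$curve$fit, rep(stats::plogis(b0), 21), tolerance = 1e-12)
  # beta_j == 1, beta0 == 0: curve is plogis(grid) exactly
  fit1 <- fit
  fit1$draws <- lapply(fit$draws, function(m) {
    m[, "wealth"] <- 1; m[, "beta0"] <- 0; m
  })
  ce1 <- conditional_effect(fit1, "wealth", n_grid = 21)
  expect_equal(ce1$curve$fit, stats::plogis(ce1$curve$x), tolerance = 1e-12)
  # curve passes through (0, plogis(beta0_hat)) when the grid includes 0
  ce2 <- conditional_effect(fit, "wealth", n_grid = 201)
  i0 <- which.min(abs(ce2$curve$x))
  b0h <- mean(draws_matrix(fit)[, "beta0"])
  bjh <- mean(draws_matrix(fit)[, "wealth"])
  expect_equal(ce2$curve$fit[i0], stats::plogis(b0h + bjh * ce2$curve$x[i0]),
               tolerance = 1e-12)
  expect_error(conditional_effect(fit, "nonexistent"), "not in the fitted",
               class = "pike_validation_error")
})

test_that("conditional-effect curves are monotone when all draws share a sign", {
  d <- simulate_panel(fast_sim_config(seed = 54))
  fit <- pike_glmm(d$panel, d$spec, fast_mcmc())
  fitp <- fit
  fitp$draws <- lapply(fit$draws, function(m) {
    m[, "wealth"] <- abs(m[, "wealth"]) + 0.01; m
  })
  ce <- conditional_effect(fitp, "wealth", n_grid = 50)
  expect_true(all(diff(ce$curve$fit) > 0))
  expect_true(all(diff(ce$curve$lwr) >= 0))
  expect_true(all(diff(ce$curve$upr) >= 0))
})

test_that("partial residuals carry the record's misfit on the response scale", {
  d <- simulate_panel(fast_sim_config(seed = 55))
  fit <- pike_glmm(d$panel, d$spec, fast_mcmc())
  ce <- conditional_effect(fit, "wealth")
  expect_equal(nrow(ce$residuals), fit$frame$n)
  expect_true(all(ce$residuals$partial_residual >= 0 &
                    ce$residuals$partial_residual <= 1))
  ce_anchor <- conditional_effect(fit, "wealth", mode = "anchored")
  expect_false(identical(ce$residuals$partial_residual,
                         ce_anchor$residuals$partial_residual))
})

test_that("group_pike_summary builds 15/34/15 extremes over 64 sites", {
  d <- simulate_panel(simulation_config(presence_prob = 1, seed = 56))
  g <- group_pike_summary(d$panel, "law_enforcement", n_extreme = 15)
  expect_equal(g$n_sites, c(15L, 34L, 15L))
  expect_equal(sum(g$n_sites), 64)
  expect_equal(sum(g$n_records), nrow(d$panel$records))
  # medians agree with a naive sort-based oracle
  vals <- attr(g, "values")
  for (grp in g$group) {
    v <- sort(vals[[grp]])
    n <- length(v)
    med <- if (n %% 2) v[(n + 1) / 2] else mean(v[n / 2 + 0:1])
    expect_equal(g$median[g$group == grp], med)
  }
  # site-year covariates are averaged per site before ranking
  g2 <- group_pike_summary(d$panel, "wealth", n_extreme = 15)
  expect_equal(sum(g2$n_sites), 64)
  # ties warn and break deterministically by site id
  p <- d$panel
  p$sites$law_enforcement <- 0
  expect_warning(gt <- group_pike_summary(p, "law_enforcement", n_extreme = 15),
                 "ties")
  sites <- attr(gt, "sites")
  expect_equal(sites$group[order(sites$site_id)][1:15], rep("low", 15))
  expect_error(group_pike_summary(d$panel, "law_enforcement", n_extreme = 32),
               "at least", class = "pike_validation_error")
})
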