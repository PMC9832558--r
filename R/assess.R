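# Model criticism and validation: posterior-predictive goodness of fit,
# train/test prediction, and the proportional change in variance analysis.

#' Split a panel into training and testing sets
#'
#' `mode = "random"` partitions the site-year records at random (default 75%
#' train / 25% test). `mode = "site_holdout"` removes every record of
#' `n_holdout_sites` randomly selected sites (default 15), the spatially
#' blocked validation design. Partitions are disjoint, exhaustive and
#' seed-reproducible; this is asserted on every call.
#'
#' @param panel a `carcass_panel`.
#' @param mode `"random"` or `"site_holdout"`.
#' @param test_fraction test proportion for random mode, in (0, 1).
#' @param n_holdout_sites number of held-out sites for site-holdout mode.
#' @param seed optional seed.
#' @return A list with `carcass_panel` elements `train` and `test` (lookup
#'   tables are shared so held-out group covariates stay available).
#' @export
split_panel <- function(panel, mode = c("random", "site_holdout"),
                        test_fraction = 0.25, n_holdout_sites = 15L,
                        seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "carcass_panel"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(panel$records)
  if (mode == "random") {
    if (test_fraction <= 0 || test_fraction >= 1) {
      stop_validation("test_fraction must be in (0, 1)")
    }
    n_test <- round(test_fraction * n)
    test_idx <- sort(sample.int(n, n_test))
  } else {
    sids <- unique(panel$records$site_id)
    if (n_holdout_sites < 1 || n_holdout_sites >= length(sids)) {
      stop_validation("n_holdout_sites must be in [1, number of sites - 1]")
    }
    hold <- sample(sids, n_holdout_sites)
    test_idx <- which(panel$records$site_id %in% hold)
  }
  train_idx <- setdiff(seq_len(n), test_idx)
  if (!length(train_idx)) stop_validation("split would empty the training set")
  stopifnot(length(intersect(train_idx, test_idx)) == 0,
            length(train_idx) + length(test_idx) == n)
  list(train = subset_records(panel, train_idx),
       test = subset_records(panel, test_idx))
}

#' Predict PIKE for new records from a fitted model
#'
#' For each retained posterior draw, the linear predictor of every new record
#' is assembled from the draw's coefficients; group intercepts seen during
#' training are reused, while intercepts of unseen groups are drawn fresh
#' from their hierarchical law at that draw (site: normal around the
#' site-covariate mean regression; year: around the price-trend mean;
#' country: around zero). The record-level site-year intercept of a held-out
#' record is never seen in training and is always drawn fresh from
#' N(0, sigma_siteyear).
#'
#' @param object a `pike_glmm` fitted on training data.
#' @param newdata a `carcass_panel` of test records (`NULL` for training
#'   fitted values). Covariate cells must be observed.
#' @param type `"summary"` for a per-record table of observed PIKE and the
#'   posterior-predictive median and 90% band, or `"draws"` for the full
#'   records-by-draws matrix of predicted PIKE.
#' @param seed optional seed for the fresh group-effect draws.
#' @param ... unused.
#' @return A data frame (`type = "summary"`) or matrix (`type = "draws"`).
#' @export
predict.pike_glmm <- function(object, newdata = NULL,
                              type = c("summary", "draws"), seed = NULL, ...) {
  type <- match.arg(type)
  if (!is.null(seed)) set.seed(seed)
  fit <- object
  if (is.null(newdata)) {
    pk <- stats::plogis(eta_draws(fit))
    rec <- fit$frame$rec
  } else {
    stopifnot(inherits(newdata, "carcass_panel"))
    fr <- fit$frame
    spec <- fit$spec
    tfr <- build_frame(newdata, spec)
    if (n_missing_cells(tfr) > 0) {
      stop_validation("test records contain missing covariate cells; no imputation value available")
    }
    rec <- tfr$rec
    D <- draws_matrix(fit)
    nd <- nrow(D)
    nr <- tfr$n
    eta <- matrix(rep(D[, "beta0"], each = nr), nr, nd)
    for (k in seq_len(tfr$K)) {
      cv <- spec$site_year_covariates[k]
      eta <- eta + outer(tfr$X[, k], D[, cv])
    }
    if (tfr$use_gov) eta <- eta + outer(tfr$gov, D[, spec$country_year_covariate])
    gdraw <- function(ids, train_ids, prefix, mu, sigma_col) {
      # group-effect draws for each of the test groups: reuse if seen,
      # fresh from the group law otherwise. Returns length(ids) x nd.
      out <- matrix(0, length(ids), nd)
      seen <- ids %in% train_ids
      if (any(seen)) {
        out[seen, ] <- t(D[, sprintf(prefix, ids[seen]), drop = FALSE])
      }
      if (any(!seen)) {
        ns <- sum(!seen)
        out[!seen, ] <- mu[!seen, , drop = FALSE] +
          matrix(stats::rnorm(ns * nd), ns, nd) *
            matrix(rep(D[, sigma_col], each = ns), ns, nd)
      }
      out
    }
    if (tfr$use_site) {
      mu <- if (tfr$P) tfr$Z %*% t(D[, spec$site_covariates, drop = FALSE])
            else matrix(0, tfr$S, nd)
      us <- gdraw(tfr$site_ids, fr$site_ids, "u_site[%s]", mu, "sigma_site")
      eta <- eta + us[tfr$site, , drop = FALSE]
    }
    if (tfr$use_year) {
      mu <- if (tfr$use_price) outer(tfr$price, D[, spec$year_covariate])
            else matrix(0, tfr$Y, nd)
      uy <- gdraw(tfr$years, fr$years, "u_year[%d]", mu, "sigma_year")
      eta <- eta + uy[tfr$year, , drop = FALSE]
    }
    if (tfr$use_country) {
      uc <- gdraw(tfr$country_ids, fr$country_ids, "u_country[%s]",
                  matrix(0, tfr$C, nd), "sigma_country")
      eta <- eta + uc[tfr$country, , drop = FALSE]
    }
    if (tfr$use_sy) {
      eta <- eta + matrix(stats::rnorm(nr * nd), nr, nd) *
        matrix(rep(D[, "sigma_siteyear"], each = nr), nr, nd)
    }
    pk <- stats::plogis(eta)
  }
  rownames(pk) <- paste(rec$site_id, rec$year, sep = ":")
  if (type == "draws") return(pk)
  data.frame(site_id = rec$site_id, year = rec$year,
             observed = rec$n_illegal / rec$n_total,
             predicted_median = apply(pk, 1, stats::median),
             predicted_q05 = apply(pk, 1, stats::quantile, 0.05),
             predicted_q95 = apply(pk, 1, stats::quantile, 0.95),
             stringsAsFactors = FALSE)
}

#' Median predicted PIKE for a test panel
#'
#' Convenience wrapper around [predict.pike_glmm()] returning the per-record
#' posterior-predictive median only.
#'
#' @param fit a `pike_glmm` fitted on training data.
#' @param test a `carcass_panel` of test records.
#' @param seed optional seed for fresh group-effect draws.
#' @return Named numeric vector of median predicted PIKE.
#' @export
predict_pike <- function(fit, test, seed = NULL) {
  p <- predict(fit, newdata = test, type = "summary", seed = seed)
  stats::setNames(p$predicted_median, paste(p$site_id, p$year, sep = ":"))
}

#' Squared Pearson correlation of observed and predicted PIKE
#'
#' @param observed,predicted numeric vectors of equal length (>= 3),
#'   non-constant.
#' @return R-squared in \[0, 1\].
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 3) {
    stop_validation("need equal-length vectors of length >= 3")
  }
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    stop_validation("R-squared undefined for a constant vector")
  }
  stats::cor(observed, predicted)^2
}

#' Posterior-predictive Bayesian p-value
#'
#' For every retained draw, replicate counts are simulated from the binomial
#' likelihood at that draw's linear predictor, and a discrepancy between data
#' and expectation is computed for the observed and the replicate data. The
#' p-value is the proportion of draws where the replicate discrepancy is at
#' least the observed one; values near 0 or 1 indicate misfit, values near
#' 0.5 adequate fit.
#'
#' @param fit a `pike_glmm`.
#' @param discrepancy `"chi_squared"` (default): sum of
#'   (y - n p)^2 / (n p (1 - p)) with p clipped away from 0 and 1; or
#'   `"freeman_tukey"`: sum of (sqrt(y) - sqrt(n p))^2.
#' @param seed optional seed for the replicate draws.
#' @param clip clipping bound for p in the chi-squared denominator.
#' @return The p-value, with the per-draw observed and replicate
#'   discrepancies as attributes.
#' @export
bayesian_p_value <- function(fit, discrepancy = c("chi_squared", "freeman_tukey"),
                             seed = NULL, clip = 1e-6) {
  discrepancy <- match.arg(discrepancy)
  stopifnot(inherits(fit, "pike_glmm"))
  if (!is.null(seed)) set.seed(seed)
  fr <- fit$frame
  eta <- eta_draws(fit)
  nd <- ncol(eta)
  if (nd == 0) stop_validation("no retained draws")
  p <- stats::plogis(eta)
  p <- pmin(pmax(p, clip), 1 - clip)
  yrep <- matrix(stats::rbinom(fr$n * nd, fr$ntot, p), fr$n, nd)
  mu <- fr$ntot * p
  disc <- function(Yv) {
    if (discrepancy == "chi_squared") {
      colSums((Yv - mu)^2 / (mu * (1 - p)))
    } else {
      colSums((sqrt(Yv) - sqrt(mu))^2)
    }
  }
  d_obs <- disc(matrix(fr$y, fr$n, nd))
  d_rep <- disc(yrep)
  structure(mean(d_rep >= d_obs), d_obs = d_obs, d_rep = d_rep,
            discrepancy = discrepancy)
}

#' Proportional change in variance across random-effect levels
#'
#' Compares the random-effect variance components of the full covariate model
#' with those of its random-effects-only companion fitted to the same panel:
#' for each level, PCV = (V_reonly - V_full) / V_reonly with V the posterior
#' mean of sigma^2. Positive values mean the covariates absorbed that share
#' of the level's variance. A draw-wise PCV distribution (draws paired by
#' retained index) is also reported.
#'
#' @param full_fit the full-model `pike_glmm`.
#' @param re_only_fit the `pike_glmm` fitted with [re_only_spec()] on the
#'   same panel.
#' @return An object of class `pike_pcv`: list with `pcv` (named point
#'   estimates), `V_full`, `V_reonly`, and `quantiles` of the draw-wise
#'   distribution.
#' @export
pcv <- function(full_fit, re_only_fit) {
  stopifnot(inherits(full_fit, "pike_glmm"), inherits(re_only_fit, "pike_glmm"))
  if (full_fit$frame$n != re_only_fit$frame$n) {
    stop_validation("models were not fitted on the same panel")
  }
  levels <- intersect(full_fit$spec$random_effects, re_only_fit$spec$random_effects)
  cols <- paste0("sigma_", levels)
  Df <- draws_matrix(full_fit, cols)
  Dr <- draws_matrix(re_only_fit, cols)
  V_full <- colMeans(Df^2)
  V_re <- colMeans(Dr^2)
  if (any(V_re == 0)) stop_validation("zero variance component in the RE-only model")
  point <- (V_re - V_full) / V_re
  nd <- min(nrow(Df), nrow(Dr))
  drawwise <- (Dr[seq_len(nd), , drop = FALSE]^2 - Df[seq_len(nd), , drop = FALSE]^2) /
    Dr[seq_len(nd), , drop = FALSE]^2
  qs <- apply(drawwise, 2, stats::quantile, c(0.05, 0.5, 0.95))
  names(point) <- levels
  colnames(qs) <- levels
  structure(list(pcv = point, V_full = stats::setNames(V_full, levels),
                 V_reonly = stats::setNames(V_re, levels), quantiles = qs),
            class = "pike_pcv")
}

#' @export
print.pike_pcv <- function(x, ...) {
  cat("Proportional change in variance (covariates vs RE-only):\n")
  print(round(x$pcv, 3))
  invisible(x)
}

#' End-to-end model assessment
#'
#' Convenience orchestration of the full criticism suite on one panel: fits
#' the full model, computes the posterior-predictive Bayesian p-value,
#' refits on a random 75/25 training split and on a site-holdout split and
#' computes holdout R-squared (point value from median predictions, 90%
#' interval from per-draw predictions), refits the random-effects-only model
#' for the PCV analysis, and reports the maximum split R-hat. This runs up
#' to four MCMC fits; size `mcmc` accordingly.
#'
#' @param panel a standardized `carcass_panel`.
#' @param spec a [model_spec()].
#' @param mcmc an [mcmc_config()].
#' @param test_fraction random-split test proportion.
#' @param n_holdout_sites sites held out in the spatial split.
#' @param do_splits,do_pcv toggles for the expensive components.
#' @param seed seed for splits and predictive draws.
#' @return A list of class `pike_assessment` with elements `bayes_p`,
#'   `r2_random`, `r2_site_holdout` (each value + interval), `pcv`,
#'   `psrf_max`, and the fitted full model under `fit`.
#' @export
assessment_report <- function(panel, spec = model_spec(), mcmc = mcmc_config(),
                              test_fraction = 0.25, n_holdout_sites = 15L,
                              do_splits = TRUE, do_pcv = TRUE, seed = 1L) {
  fit <- pike_glmm(panel, spec, mcmc)
  sig <- paste0("sigma_", spec$random_effects)
  rh <- gelman_rubin(fit, pars = c("beta0", fit$coef_names, sig, "lambda"))
  out <- list(fit = fit, bayes_p = bayesian_p_value(fit, seed = seed),
              psrf_max = suppressWarnings(max(rh, na.rm = TRUE)))
  r2_block <- function(split) {
    tr_fit <- pike_glmm(split$train, spec, mcmc)
    pk <- predict(tr_fit, newdata = split$test, type = "draws", seed = seed)
    obs <- observed_pike(split$test)
    keep <- match(names(obs), rownames(pk))
    pk <- pk[keep, , drop = FALSE]
    r2d <- apply(pk, 2, function(pr) stats::cor(obs, pr)^2)
    list(r2 = r_squared(obs, apply(pk, 1, stats::median)),
         ci = stats::quantile(r2d, c(0.05, 0.95)))
  }
  if (do_splits) {
    out$r2_random <- r2_block(split_panel(panel, "random", test_fraction, seed = seed))
    out$r2_site_holdout <- r2_block(split_panel(panel, "site_holdout",
                                                n_holdout_sites = n_holdout_sites,
                                                seed = seed))
  }
  if (do_pcv) {
    re_fit <- pike_glmm(panel, re_only_spec(spec), mcmc)
    out$pcv <- pcv(fit, re_fit)
  }
  class(out) <- "pike_assessment"
  out
}

#' @export
print.pike_assessment <- function(x, ...) {
  cat("Model assessment\n")
  cat(sprintf("  Bayesian p-value (chi-squared): %.3f\n", x$bayes_p))
  if (!is.null(x$r2_random)) {
    cat(sprintf("  R^2, random 75/25 split: %.3f (90%% CI %.3f-%.3f)\n",
                x$r2_random$r2, x$r2_random$ci[1], x$r2_random$ci[2]))
    cat(sprintf("  R^2, site holdout: %.3f (90%% CI %.3f-%.3f)\n",
                x$r2_site_holdout$r2, x$r2_site_holdout$ci[1], x$r2_site_holdout$ci[2]))
  }
  if (!is.null(x$pcv)) print(x$pcv)
  cat(sprintf("  Max split R-hat: %.3f\n", x$psrf_max))
  invisible(x)
}
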