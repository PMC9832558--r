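# Model fitting: the pike_glmm() entry point, chain orchestration, and the
# S3 methods of the fitted-model object.

# Column names of the monitored draw matrix; must mirror the write order in
# src/mwg.cpp exactly.
draw_colnames <- function(fr) {
  spec <- fr$spec
  nm <- "beta0"
  nm <- c(nm, spec$site_year_covariates)
  if (fr$use_gov) nm <- c(nm, spec$country_year_covariate)
  nm <- c(nm, spec$site_covariates)
  if (fr$use_price) nm <- c(nm, spec$year_covariate)
  if (fr$use_site) nm <- c(nm, "sigma_site")
  if (fr$use_year) nm <- c(nm, "sigma_year")
  if (fr$use_sy) nm <- c(nm, "sigma_siteyear")
  if (fr$use_country) nm <- c(nm, "sigma_country")
  nm <- c(nm, "lambda")
  if (fr$use_site) nm <- c(nm, sprintf("u_site[%s]", fr$site_ids))
  if (fr$use_year) nm <- c(nm, sprintf("u_year[%d]", fr$years))
  if (fr$use_country) nm <- c(nm, sprintf("u_country[%s]", fr$country_ids))
  if (fr$use_sy) nm <- c(nm, sprintf("u_siteyear[%s:%d]", fr$rec$site_id, fr$rec$year))
  for (k in seq_len(fr$K)) {
    i <- fr$mis_X[[k]]
    if (length(i)) {
      nm <- c(nm, sprintf("imp[%s:%s:%d]", spec$site_year_covariates[k],
                          fr$rec$site_id[i], fr$rec$year[i]))
    }
  }
  if (length(fr$mis_gov)) {
    nm <- c(nm, sprintf("imp[%s:%s:%d]", spec$country_year_covariate,
                        fr$gov_cells$country_id, fr$gov_cells$year))
  }
  for (p in seq_len(fr$P)) {
    s <- fr$mis_Z[[p]]
    if (length(s)) {
      nm <- c(nm, sprintf("imp[%s:%s]", spec$site_covariates[p], fr$site_ids[s]))
    }
  }
  if (length(fr$mis_price)) {
    nm <- c(nm, sprintf("imp[%s:%d]", spec$year_covariate, fr$years[fr$mis_price]))
  }
  c(nm, "lp__")
}

coef_names_of <- function(spec, fr) {
  c(spec$site_year_covariates,
    if (fr$use_gov) spec$country_year_covariate,
    spec$site_covariates,
    if (fr$use_price) spec$year_covariate)
}

frame_for_cpp <- function(fr, impute) {
  list(y = fr$y, ntot = fr$ntot,
       X = fr$X, gov = ifelse(is.na(fr$gov), 0, fr$gov),
       site = fr$site - 1L, year = fr$year - 1L, country = fr$country - 1L,
       S = fr$S, Y = fr$Y, C = fr$C,
       Z = fr$Z, price = ifelse(is.na(fr$price), 0, fr$price),
       use_site = fr$use_site, use_year = fr$use_year, use_sy = fr$use_sy,
       use_country = fr$use_country, use_gov = fr$use_gov,
       use_price = fr$use_price,
       misX = lapply(fr$mis_X, function(i) as.integer(i - 1L)),
       misGov = lapply(fr$mis_gov, function(i) as.integer(i - 1L)),
       misZ = lapply(fr$mis_Z, function(i) as.integer(i - 1L)),
       misPrice = as.integer(fr$mis_price - 1L),
       impute = impute,
       beta0_sd = fr$spec$priors$beta0_sd,
       lam_shape = fr$spec$priors$lambda_shape,
       lam_rate = fr$spec$priors$lambda_rate,
       sig_shape = fr$spec$priors$sigma_shape,
       sig_rate = fr$spec$priors$sigma_rate,
       ll_const = sum(lchoose(fr$ntot, fr$y)))
}

# Draw overdispersed initial values; imputed cells start at standard-normal
# draws injected straight into the design copies handed to the chain.
draw_init <- function(fr, mcmc) {
  pr <- fr$spec$priors
  sp <- mcmc$init_spread
  init <- list(
    beta0 = stats::rnorm(1, 0, sp),
    beta = stats::rnorm(fr$K, 0, sp),
    bgov = if (fr$use_gov) stats::rnorm(1, 0, sp) else 0,
    gamma = stats::rnorm(fr$P, 0, sp),
    bprice = if (fr$use_price) stats::rnorm(1, 0, sp) else 0,
    sig = stats::rgamma(4, pr$sigma_shape, rate = pr$sigma_rate),
    lam = pr$lambda_shape / pr$lambda_rate)
  imp <- list(
    X = lapply(fr$mis_X, function(i) stats::rnorm(length(i))),
    gov = stats::rnorm(length(fr$mis_gov)),
    Z = lapply(fr$mis_Z, function(i) stats::rnorm(length(i))),
    price = stats::rnorm(length(fr$mis_price)))
  # realized intercepts from their prior laws given the drawn hyperparameters
  Zf <- fr$Z
  for (p in seq_len(fr$P)) Zf[fr$mis_Z[[p]], p] <- imp$Z[[p]]
  mu_site <- if (fr$P) drop(Zf %*% init$gamma) else numeric(fr$S)
  pricef <- fr$price
  pricef[fr$mis_price] <- imp$price
  mu_year <- if (fr$use_price) init$bprice * pricef else numeric(fr$Y)
  init$usite <- if (fr$use_site) stats::rnorm(fr$S, mu_site, init$sig[1]) else numeric(fr$S)
  init$uyear <- if (fr$use_year) stats::rnorm(fr$Y, mu_year, init$sig[2]) else numeric(fr$Y)
  init$usy <- if (fr$use_sy) stats::rnorm(fr$n, 0, init$sig[3]) else numeric(fr$n)
  init$ucountry <- if (fr$use_country) stats::rnorm(fr$C, 0, init$sig[4]) else numeric(fr$C)
  list(init = init, imp = imp)
}

inject_imputed <- function(cf, fr, imp) {
  for (k in seq_len(fr$K)) cf$X[fr$mis_X[[k]], k] <- imp$X[[k]]
  for (g in seq_along(fr$mis_gov)) cf$gov[fr$mis_gov[[g]]] <- imp$gov[g]
  for (p in seq_len(fr$P)) cf$Z[fr$mis_Z[[p]], p] <- imp$Z[[p]]
  cf$price[fr$mis_price] <- imp$price
  cf
}

#' Fit the hierarchical PIKE model by MCMC
#'
#' Runs the adaptive Metropolis-within-Gibbs sampler over all model
#' parameters: the intercept, every covariate coefficient (Laplace/LASSO
#' priors with a gamma-hyperprior rate lambda), the four levels of random
#' intercepts, their standard deviations (log-scale proposals with Jacobian
#' correction), lambda, and one latent standard-normal node per missing
#' covariate cell. Scale adaptation targets the configured acceptance rate
#' during burn-in only. Retained draws are thinned evenly after burn-in to
#' `mcmc$n_retained` total across chains.
#'
#' @param panel a standardized `carcass_panel` (see [z_transform()];
#'   synthetic panels from [simulate_panel()] are already standardized).
#' @param spec a [model_spec()].
#' @param mcmc an [mcmc_config()].
#' @param impute `"mcmc"` (missing cells are latent nodes updated every
#'   sweep), `"oneshot"` (drawn once from a standard normal at
#'   initialization and held fixed; a sensitivity mode), or `"none"` (error
#'   if any modelled cell is missing).
#' @param verbose print per-chain progress.
#' @return An object of class `pike_glmm` with methods `print`, `summary`,
#'   `coef`, `predict`, `plot`, `simulate` and `residuals`.
#' @export
pike_glmm <- function(panel, spec = model_spec(), mcmc = mcmc_config(),
                      impute = c("mcmc", "oneshot", "none"), verbose = FALSE) {
  impute <- match.arg(impute)
  stopifnot(inherits(panel, "carcass_panel"))
  if (!panel$standardized) {
    stop_validation("panel must be standardized; run z_transform() first")
  }
  fr <- build_frame(panel, spec)
  if (impute == "none" && n_missing_cells(fr) > 0) {
    stop_validation("%d missing covariate cell(s) but impute = 'none'", n_missing_cells(fr))
  }
  cf <- frame_for_cpp(fr, impute == "mcmc")

  per_chain <- max(1L, round(mcmc$n_retained / mcmc$n_chains))
  stride <- max(1L, (mcmc$n_iterations - mcmc$n_burnin) %/% per_chain)
  keep <- mcmc$n_burnin + stride * seq_len(per_chain)
  keep <- keep[keep <= mcmc$n_iterations]

  cn <- draw_colnames(fr)
  chains <- vector("list", mcmc$n_chains)
  accept <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + 1009L * (ch - 1L))
    res <- NULL
    for (try in 1:10) {
      di <- draw_init(fr, mcmc)
      cf_ch <- inject_imputed(cf, fr, di$imp)
      res <- tryCatch(
        mwg_chain(cf_ch, list(n_iter = mcmc$n_iterations, n_burn = mcmc$n_burnin,
                              keep = as.integer(keep), target = mcmc$adapt_target),
                  di$init),
        error = function(e) e)
      if (!inherits(res, "error")) break
    }
    if (inherits(res, "error")) {
      stop("chain ", ch, " failed to initialize at a finite posterior: ",
           conditionMessage(res))
    }
    colnames(res$draws) <- cn
    chains[[ch]] <- res$draws
    accept[[ch]] <- res$accept
    if (verbose) {
      message(sprintf("chain %d/%d: %d retained draws, final lp %.2f",
                      ch, mcmc$n_chains, nrow(res$draws), res$final_lp))
    }
  }

  structure(list(draws = chains, accept = accept, spec = spec, mcmc = mcmc,
                 panel = panel, frame = fr,
                 coef_names = coef_names_of(spec, fr)),
            class = "pike_glmm")
}

#' Pooled draw matrix of a fitted model
#'
#' @param fit a `pike_glmm`.
#' @param pars optional character vector of parameter names to keep.
#' @return A numeric matrix, retained draws (all chains stacked) by
#'   parameter, with a `chain` attribute giving each row's chain.
#' @export
draws_matrix <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "pike_glmm"))
  m <- do.call(rbind, fit$draws)
  chain <- rep(seq_along(fit$draws), vapply(fit$draws, nrow, 1L))
  if (!is.null(pars)) {
    bad <- setdiff(pars, colnames(m))
    if (length(bad)) stop_validation("unknown parameter(s): %s", paste(bad, collapse = ", "))
    m <- m[, pars, drop = FALSE]
  }
  attr(m, "chain") <- chain
  m
}

# Per-draw linear predictor for the training records: n x n_draws. Missing
# cells take their per-draw imputed values.
eta_draws <- function(fit) {
  fr <- fit$frame
  D <- draws_matrix(fit)
  nd <- nrow(D)
  eta <- matrix(rep(D[, "beta0"], each = fr$n), fr$n, nd)
  for (k in seq_len(fr$K)) {
    cv <- fr$spec$site_year_covariates[k]
    xk <- matrix(fr$X[, k], fr$n, nd)
    i <- fr$mis_X[[k]]
    if (length(i)) {
      xk[i, ] <- t(D[, sprintf("imp[%s:%s:%d]", cv, fr$rec$site_id[i], fr$rec$year[i]),
                     drop = FALSE])
    }
    eta <- eta + xk * matrix(rep(D[, cv], each = fr$n), fr$n, nd)
  }
  if (fr$use_gov) {
    gv <- matrix(fr$gov, fr$n, nd)
    for (g in seq_along(fr$mis_gov)) {
      nmg <- sprintf("imp[%s:%s:%d]", fr$spec$country_year_covariate,
                     fr$gov_cells$country_id[g], fr$gov_cells$year[g])
      gv[fr$mis_gov[[g]], ] <- matrix(D[, nmg], length(fr$mis_gov[[g]]), nd, byrow = TRUE)
    }
    eta <- eta + gv * matrix(rep(D[, fr$spec$country_year_covariate], each = fr$n), fr$n, nd)
  }
  if (fr$use_site) eta <- eta + t(D[, sprintf("u_site[%s]", fr$site_ids), drop = FALSE])[fr$site, , drop = FALSE]
  if (fr$use_year) eta <- eta + t(D[, sprintf("u_year[%d]", fr$years), drop = FALSE])[fr$year, , drop = FALSE]
  if (fr$use_country) eta <- eta + t(D[, sprintf("u_country[%s]", fr$country_ids), drop = FALSE])[fr$country, , drop = FALSE]
  if (fr$use_sy) eta <- eta + t(D[, sprintf("u_siteyear[%s:%d]", fr$rec$site_id, fr$rec$year), drop = FALSE])
  eta
}

#' @export
print.pike_glmm <- function(x, ...) {
  cat("Hierarchical binomial PIKE model (Bayesian LASSO)\n")
  cat(sprintf("  %d modelled records | %d sites | %d countries | %d years\n",
              x$frame$n, x$frame$S, x$frame$C, x$frame$Y))
  cat(sprintf("  %d chains x %d iterations (burn-in %d), %d retained draws\n",
              x$mcmc$n_chains, x$mcmc$n_iterations, x$mcmc$n_burnin,
              nrow(draws_matrix(x))))
  cat(sprintf("  %d missing covariate cells imputed in-chain\n",
              n_missing_cells(x$frame)))
  cat("Coefficient posterior means:\n")
  print(round(coef(x), 3))
  invisible(x)
}

#' @export
coef.pike_glmm <- function(object, ...) {
  D <- draws_matrix(object, c("beta0", object$coef_names))
  colMeans(D)
}

#' @export
summary.pike_glmm <- function(object, level = 0.90, ...) {
  D <- draws_matrix(object)
  sig <- grep("^sigma_", colnames(D), value = TRUE)
  rh <- gelman_rubin(object, pars = c("beta0", object$coef_names, sig, "lambda"))
  out <- list(coefficients = coefficient_summary(object, level = level),
              sigma = coefficient_summary(D[, sig, drop = FALSE], level = level),
              lambda = coefficient_summary(D[, "lambda", drop = FALSE], level = level),
              psrf = rh, psrf_max = suppressWarnings(max(rh, na.rm = TRUE)),
              level = level)
  class(out) <- "summary.pike_glmm"
  out
}

#' @export
print.summary.pike_glmm <- function(x, ...) {
  cat(sprintf("Covariate coefficients (posterior mean, %d%% credible interval):\n",
              round(100 * x$level)))
  print(x$coefficients, digits = 3)
  cat("\nRandom-effect standard deviations:\n")
  print(x$sigma[c("name", "mean", "ci_low", "ci_high")], digits = 3)
  cat("\nLASSO rate lambda:\n")
  print(x$lambda[c("name", "mean", "ci_low", "ci_high")], digits = 3)
  cat(sprintf("\nMax split R-hat over monitored parameters: %.3f %s\n",
              x$psrf_max, if (x$psrf_max < 1.1) "(converged)" else "(NOT converged)"))
  invisible(x)
}

#' @export
residuals.pike_glmm <- function(object, type = c("working", "pearson", "response"), ...) {
  type <- match.arg(type)
  fr <- object$frame
  p <- stats::plogis(rowMeans(eta_draws(object)))
  obs <- fr$y / fr$ntot
  r <- switch(type,
              response = obs - p,
              pearson = (obs - p) / sqrt(p * (1 - p) / fr$ntot),
              working = (obs - p) / (p * (1 - p)))
  stats::setNames(r, paste(fr$rec$site_id, fr$rec$year, sep = ":"))
}

#' Posterior-predictive carcass counts
#'
#' For each requested simulation, picks a retained posterior draw and
#' simulates replicate illegal-carcass counts for every training record from
#' the binomial likelihood at that draw's linear predictor.
#'
#' @param object a `pike_glmm`.
#' @param nsim number of replicate datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return A matrix, records by `nsim`.
#' @export
simulate.pike_glmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fr <- object$frame
  eta <- eta_draws(object)
  pick <- sample.int(ncol(eta), nsim, replace = nsim > ncol(eta))
  out <- matrix(0L, fr$n, nsim)
  for (j in seq_len(nsim)) {
    out[, j] <- stats::rbinom(fr$n, fr$ntot, stats::plogis(eta[, pick[j]]))
  }
  rownames(out) <- paste(fr$rec$site_id, fr$rec$year, sep = ":")
  out
}

#' @export
plot.pike_glmm <- function(x, level = 0.90, ...) {
  cs <- coefficient_summary(x, level = level)
  ord <- order(cs$mean)
  cs <- cs[ord, ]
  graphics::plot(cs$mean, seq_len(nrow(cs)), xlim = range(cs$ci_low, cs$ci_high, 0),
                 yaxt = "n", xlab = "coefficient (logit scale)", ylab = "",
                 pch = 19, col = ifelse(cs$supported,
                                        ifelse(cs$mean > 0, "darkorange3", "steelblue4"),
                                        "grey40"), ...)
  graphics::segments(cs$ci_low, seq_len(nrow(cs)), cs$ci_high, seq_len(nrow(cs)),
                     col = ifelse(cs$supported,
                                  ifelse(cs$mean > 0, "darkorange3", "steelblue4"),
                                  "grey40"))
  graphics::abline(v = 0, lty = 2)
  graphics::axis(2, at = seq_len(nrow(cs)), labels = cs$name, las = 1, cex.axis = 0.7)
  invisible(cs)
}

#' Gelman-Rubin split-R-hat convergence diagnostic
#'
#' Each chain is split in half so the statistic is defined even for a single
#' physical chain; values below 1.1 are conventionally taken as converged.
#' Chains with zero variance yield `NaN` with a warning.
#'
#' @param x a `pike_glmm` fit, a list of draw matrices (one per chain, equal
#'   dimensions), or a single matrix/vector (treated as one chain).
#' @param pars optional parameter subset (fit/matrix columns).
#' @return Named numeric vector of split-R-hat values per parameter.
#' @export
gelman_rubin <- function(x, pars = NULL) {
  chains <- if (inherits(x, "pike_glmm")) {
    lapply(x$draws, function(m) if (is.null(pars)) m else m[, pars, drop = FALSE])
  } else if (is.list(x)) {
    lapply(x, as.matrix)
  } else {
    list(as.matrix(x))
  }
  if (!is.null(pars) && !inherits(x, "pike_glmm")) {
    chains <- lapply(chains, function(m) m[, pars, drop = FALSE])
  }
  niter <- unique(vapply(chains, nrow, 1L))
  if (length(niter) != 1) stop_validation("chains have unequal lengths")
  half <- niter %/% 2L
  if (half < 4L) stop_validation("need at least 4 draws per split half")
  splits <- list()
  for (m in chains) {
    splits <- c(splits, list(m[seq_len(half), , drop = FALSE]),
                list(m[seq.int(niter - half + 1L, niter), , drop = FALSE]))
  }
  p <- ncol(chains[[1]])
  out <- numeric(p)
  for (j in seq_len(p)) {
    mns <- vapply(splits, function(m) mean(m[, j]), 1)
    vrs <- vapply(splits, function(m) stats::var(m[, j]), 1)
    W <- mean(vrs)
    B_n <- stats::var(mns)
    if (W == 0) {
      warning("zero within-chain variance for '", colnames(chains[[1]])[j],
              "'; R-hat undefined")
      out[j] <- NaN
    } else {
      out[j] <- sqrt((half - 1) / half + B_n / W)
    }
  }
  stats::setNames(out, colnames(chains[[1]]))
}
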