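# Posterior summaries and figure-style outputs: coefficient table,
# conditional effects with partial residuals, covariate-tercile PIKE
# summaries. Every graphical output has a tabular twin.

#' Posterior coefficient summary
#'
#' Posterior mean and equal-tailed credible interval for each covariate
#' coefficient; a coefficient is flagged `supported` when its interval
#' excludes zero, with the corresponding `sign`.
#'
#' @param object a `pike_glmm` fit (covariate coefficients are summarized)
#'   or a numeric matrix of draws (all columns are summarized).
#' @param level credible level in (0, 1); default 0.90.
#' @param ... unused.
#' @return A data frame with columns `name`, `mean`, `ci_low`, `ci_high`,
#'   `supported`, `sign`.
#' @export
coefficient_summary <- function(object, level = 0.90, ...) {
  UseMethod("coefficient_summary")
}

#' @rdname coefficient_summary
#' @export
coefficient_summary.pike_glmm <- function(object, level = 0.90, ...) {
  coefficient_summary(draws_matrix(object, object$coef_names), level = level)
}

#' @rdname coefficient_summary
#' @export
coefficient_summary.default <- function(object, level = 0.90, ...) {
  if (level <= 0 || level > 1) stop_validation("level must be in (0, 1]")
  m <- as.matrix(object)
  if (is.null(colnames(m))) colnames(m) <- paste0("par", seq_len(ncol(m)))
  a <- (1 - level) / 2
  lo <- apply(m, 2, stats::quantile, a)
  hi <- apply(m, 2, stats::quantile, 1 - a)
  stopifnot(all(lo <= hi))
  supported <- lo > 0 | hi < 0
  data.frame(name = colnames(m), mean = colMeans(m), ci_low = lo, ci_high = hi,
             supported = supported,
             sign = ifelse(!supported, "none", ifelse(lo > 0, "positive", "negative")),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Locate a covariate's per-record values in a fitted model's frame.
record_covariate <- function(fit, covariate) {
  fr <- fit$frame
  spec <- fit$spec
  if (covariate %in% spec$site_year_covariates) {
    k <- match(covariate, spec$site_year_covariates)
    x <- fr$X[, k]
    i <- fr$mis_X[[k]]
    if (length(i)) {
      D <- draws_matrix(fit)
      x[i] <- colMeans(D[, sprintf("imp[%s:%s:%d]", covariate, fr$rec$site_id[i],
                                   fr$rec$year[i]), drop = FALSE])
    }
    x
  } else if (identical(covariate, spec$country_year_covariate)) {
    x <- fr$gov
    for (g in seq_along(fr$mis_gov)) {
      D <- draws_matrix(fit)
      x[fr$mis_gov[[g]]] <- mean(D[, sprintf("imp[%s:%s:%d]", covariate,
                                             fr$gov_cells$country_id[g],
                                             fr$gov_cells$year[g])])
    }
    x
  } else if (covariate %in% spec$site_covariates) {
    p <- match(covariate, spec$site_covariates)
    z <- fr$Z[, p]
    s <- fr$mis_Z[[p]]
    if (length(s)) {
      D <- draws_matrix(fit)
      z[s] <- colMeans(D[, sprintf("imp[%s:%s]", covariate, fr$site_ids[s]),
                         drop = FALSE])
    }
    z[fr$site]
  } else if (identical(covariate, spec$year_covariate)) {
    pr <- fr$price
    if (length(fr$mis_price)) {
      D <- draws_matrix(fit)
      pr[fr$mis_price] <- colMeans(D[, sprintf("imp[%s:%d]", covariate,
                                               fr$years[fr$mis_price]),
                                     drop = FALSE])
    }
    pr[fr$year]
  } else {
    stop_validation("covariate '%s' is not in the fitted model", covariate)
  }
}

#' Conditional effect of one covariate with partial residuals
#'
#' The effect curve is the inverse-logit of the posterior-mean intercept plus
#' the focal coefficient times a grid spanning the covariate's observed
#' range, with all other covariates at their standardized mean (zero) and
#' random effects at their prior means; a 90% band comes from evaluating the
#' curve per retained draw. Each record contributes a partial residual
#' `plogis(beta0_hat + beta_j_hat * x_ij + r_i)` where `r_i` is the record's
#' logit-scale working residual at the posterior-mean fit
#' (`mode = "working"`, default) or the residual of logit(observed PIKE,
#' clipped) against all non-focal fitted terms (`mode = "anchored"`).
#'
#' @param fit a `pike_glmm`.
#' @param covariate name of a covariate in the fitted model.
#' @param n_grid grid resolution.
#' @param level credible level of the band.
#' @param mode partial-residual construction, see above.
#' @param clip proportion clipping used by the anchored mode.
#' @return An object of class `pike_conditional_effect`: list with `curve`
#'   (data frame `x`, `fit`, `lwr`, `upr`), `residuals` (data frame
#'   `site_id`, `year`, `x`, `partial_residual`) and `covariate`.
#' @export
conditional_effect <- function(fit, covariate, n_grid = 100, level = 0.90,
                               mode = c("working", "anchored"), clip = 1e-3) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "pike_glmm"))
  x <- record_covariate(fit, covariate)
  D <- draws_matrix(fit, c("beta0", covariate))
  b0_hat <- mean(D[, "beta0"])
  bj_hat <- mean(D[, covariate])
  g <- seq(min(x), max(x), length.out = n_grid)
  curves <- stats::plogis(outer(rep(1, n_grid), D[, "beta0"]) + outer(g, D[, covariate]))
  a <- (1 - level) / 2
  curve <- data.frame(x = g,
                      fit = stats::plogis(b0_hat + bj_hat * g),
                      lwr = apply(curves, 1, stats::quantile, a),
                      upr = apply(curves, 1, stats::quantile, 1 - a))
  fr <- fit$frame
  eta_hat <- rowMeans(eta_draws(fit))
  p_hat <- stats::plogis(eta_hat)
  obs <- fr$y / fr$ntot
  r <- if (mode == "working") {
    (obs - p_hat) / (p_hat * (1 - p_hat))
  } else {
    stats::qlogis(pmin(pmax(obs, clip), 1 - clip)) - (eta_hat - bj_hat * x)
    # anchored: logit(obs) minus all non-focal terms, then re-centred below
  }
  partial <- if (mode == "working") {
    stats::plogis(b0_hat + bj_hat * x + r)
  } else {
    stats::plogis(b0_hat + r)
  }
  structure(list(curve = curve,
                 residuals = data.frame(site_id = fr$rec$site_id,
                                        year = fr$rec$year, x = x,
                                        partial_residual = partial,
                                        stringsAsFactors = FALSE),
                 covariate = covariate, level = level, mode = mode),
            class = "pike_conditional_effect")
}

#' @export
plot.pike_conditional_effect <- function(x, ...) {
  graphics::plot(x$residuals$x, x$residuals$partial_residual, col = "grey60",
                 pch = 1, xlab = x$covariate, ylab = "PIKE", ylim = c(0, 1), ...)
  graphics::polygon(c(x$curve$x, rev(x$curve$x)), c(x$curve$lwr, rev(x$curve$upr)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(x$curve$x, x$curve$fit, lwd = 2, col = "steelblue4")
  invisible(x)
}

#' Observed PIKE by covariate-extreme site groups
#'
#' Ranks sites by their (site-mean) value of a covariate and groups them into
#' the `n_extreme` lowest, the `n_extreme` highest, and the remainder
#' ("low"/"mid"/"high"), then summarizes the observed PIKE of each group's
#' site-year records with median and quartiles. Ties in the ranking are
#' broken deterministically by site id (with a warning).
#'
#' @param panel a `carcass_panel`.
#' @param covariate a site covariate (e.g. `law_enforcement`) or a site-year
#'   covariate (e.g. `wealth`, averaged per site over its records).
#' @param n_extreme sites per extreme group; needs at least
#'   `2 * n_extreme + 1` sites.
#' @return An object of class `pike_group_summary`: the per-group data frame
#'   (`group`, `n_sites`, `n_records`, `median`, `q25`, `q75`), with the
#'   per-site assignments and per-group PIKE values as attributes.
#' @export
group_pike_summary <- function(panel, covariate, n_extreme = 15L) {
  stopifnot(inherits(panel, "carcass_panel"))
  rec <- panel$records[panel$records$n_total >= 1, , drop = FALSE]
  sids <- sort(unique(rec$site_id))
  if (length(sids) < 2 * n_extreme + 1) {
    stop_validation("need at least %d sites for n_extreme = %d",
                    2 * n_extreme + 1, n_extreme)
  }
  val <- if (covariate %in% names(panel$sites)) {
    panel$sites[[covariate]][match(sids, panel$sites$site_id)]
  } else if (covariate %in% panel$covariates) {
    vapply(sids, function(s) mean(rec[[covariate]][rec$site_id == s], na.rm = TRUE), 1)
  } else {
    stop_validation("covariate '%s' not found in panel", covariate)
  }
  if (anyDuplicated(val)) {
    warning("ties in site-mean '", covariate, "'; breaking by site_id")
  }
  ord <- order(val, sids)
  grp <- rep("mid", length(sids))
  grp[ord[seq_len(n_extreme)]] <- "low"
  grp[ord[seq.int(length(sids) - n_extreme + 1, length(sids))]] <- "high"
  assign <- data.frame(site_id = sids, value = val, group = grp,
                       stringsAsFactors = FALSE)
  pike <- rec$n_illegal / rec$n_total
  gof <- assign$group[match(rec$site_id, assign$site_id)]
  groups <- c("low", "mid", "high")
  vals <- lapply(groups, function(g) pike[gof == g])
  names(vals) <- groups
  out <- data.frame(group = groups,
                    n_sites = vapply(groups, function(g) sum(grp == g), 1L),
                    n_records = lengths(vals),
                    median = vapply(vals, stats::median, 1),
                    q25 = vapply(vals, function(v) unname(stats::quantile(v, 0.25)), 1),
                    q75 = vapply(vals, function(v) unname(stats::quantile(v, 0.75)), 1),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, sites = assign, values = vals, covariate = covariate,
            class = c("pike_group_summary", "data.frame"))
}

#' @export
plot.pike_group_summary <- function(x, ...) {
  graphics::boxplot(attr(x, "values"), ylab = "observed PIKE",
                    xlab = attr(x, "covariate"), ...)
  invisible(x)
}
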