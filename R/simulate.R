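# Synthetic carcass panels with known ground truth. The generator mirrors the
# generative reading of the fitted model exactly: covariates standard normal
# (species Bernoulli(0.5) per site), four levels of normal random intercepts
# with hierarchical means, binomial counts with negative-binomial totals.

#' Configuration of a synthetic carcass panel
#'
#' Defaults emulate the monitoring panel the model class was designed for:
#' 64 sites nested in 30 countries over 19 years starting 2002, with each
#' site-year present with probability 0.64 (about 780 records on average),
#' and highly variable carcass totals (negative binomial, mean 15,
#' dispersion 1, truncated at 1). Default true effects are moderate and
#' sparse — negative wealth, health, governance and law-enforcement effects,
#' a positive ivory-price trend and species (forest) effect, a small
#' positive conflict effect, and exact zeros elsewhere — with site
#' heterogeneity the dominant variance component.
#'
#' @param n_sites,n_countries,n_years,first_year panel dimensions.
#' @param presence_prob probability a site-year record exists (unbalanced
#'   panel); in (0, 1].
#' @param total_carcass_law list with `family` (`"nbinom"` or `"fixed"`),
#'   `mean`, `dispersion` (nbinom size), `min` (lower truncation, >= 1).
#' @param covariates names of the site-by-year covariates to generate.
#' @param true_beta0 intercept of the logit-PIKE regression.
#' @param true_beta named true coefficients for the site-year covariates plus
#'   `governance`.
#' @param true_gamma named true coefficients of the site-intercept mean
#'   regression (`area_km2`, `law_enforcement`, `travel_time`, `species`).
#' @param true_beta_price true coefficient of the ivory-price trend in the
#'   year-intercept mean.
#' @param sigmas named sds of the four random-intercept levels
#'   (`site`, `year`, `siteyear`, `country`); all >= 0.
#' @param missing_rates optional named per-covariate probabilities of
#'   punching a cell to missing (names may also be `governance`,
#'   `ivory_price`, or any site covariate).
#' @param raw_scale if `TRUE`, covariates are written on an affine raw scale
#'   (so that [z_transform()] is exercised); otherwise they are generated
#'   directly on the standardized scale the model consumes.
#' @param raw_params optional named list of `c(mean, sd)` used in raw mode.
#' @param seed integer seed; identical configurations give identical
#'   datasets.
#' @return An object of class `pike_sim_config`.
#' @export
simulation_config <- function(n_sites = 64L, n_countries = 30L, n_years = 19L,
                              first_year = 2002L, presence_prob = 0.64,
                              total_carcass_law = list(family = "nbinom", mean = 15,
                                                       dispersion = 1, min = 1),
                              covariates = c("conflict_lag2", "elephant_density",
                                             "wealth", "health", "precip_anomaly",
                                             "ndvi"),
                              true_beta0 = -0.5,
                              true_beta = c(conflict_lag2 = 0.15,
                                            elephant_density = 0, wealth = -0.3,
                                            health = -0.3, precip_anomaly = 0,
                                            ndvi = 0, governance = -0.4),
                              true_gamma = c(area_km2 = 0, law_enforcement = -0.3,
                                             travel_time = 0, species = 0.5),
                              true_beta_price = 0.3,
                              sigmas = c(site = 0.7, year = 0.2,
                                         siteyear = 0.5, country = 0.5),
                              missing_rates = NULL,
                              raw_scale = FALSE, raw_params = NULL,
                              seed = 1L) {
  if (n_countries < 1 || n_sites < n_countries) {
    stop_validation("need n_sites >= n_countries >= 1")
  }
  if (presence_prob <= 0 || presence_prob > 1) {
    stop_validation("presence_prob must be in (0, 1]")
  }
  if (any(sigmas < 0)) stop_validation("random-effect sds must be >= 0")
  law <- utils::modifyList(list(family = "nbinom", mean = 15, dispersion = 1, min = 1),
                           total_carcass_law)
  if (law$min < 1) stop_validation("total_carcass_law$min must be >= 1")
  need <- setdiff(c(covariates, "governance"), names(true_beta))
  if (length(need)) {
    stop_validation("true_beta is missing coefficients for: %s",
                    paste(need, collapse = ", "))
  }
  if (!is.null(missing_rates) &&
      (any(missing_rates < 0) || any(missing_rates >= 1))) {
    stop_validation("missing_rates must be in [0, 1)")
  }
  structure(list(n_sites = as.integer(n_sites), n_countries = as.integer(n_countries),
                 n_years = as.integer(n_years), first_year = as.integer(first_year),
                 presence_prob = presence_prob, total_carcass_law = law,
                 covariates = covariates, true_beta0 = true_beta0,
                 true_beta = true_beta, true_gamma = true_gamma,
                 true_beta_price = true_beta_price, sigmas = sigmas,
                 missing_rates = missing_rates, raw_scale = isTRUE(raw_scale),
                 raw_params = raw_params, seed = as.integer(seed)),
            class = "pike_sim_config")
}

# The model spec a simulated panel is meant to be fitted with.
spec_for_config <- function(config) {
  model_spec(site_year_covariates = config$covariates,
             country_year_covariate = "governance",
             site_covariates = names(config$true_gamma),
             year_covariate = "ivory_price")
}

rtrunc_nbinom <- function(n, mu, size, min) {
  x <- stats::rnbinom(n, mu = mu, size = size)
  low <- which(x < min)
  tries <- 0L
  while (length(low) && tries < 1000L) {
    x[low] <- stats::rnbinom(length(low), mu = mu, size = size)
    low <- low[x[low] < min]
    tries <- tries + 1L
  }
  x[x < min] <- min
  x
}

#' Simulate binomial carcass counts
#'
#' Draws `Binomial(n_total, plogis(eta))` counts of illegally killed
#' carcasses.
#'
#' @param eta linear predictor value(s).
#' @param n_total total carcasses detected (all >= 1); recycled against
#'   `eta`.
#' @param seed optional seed.
#' @return Integer vector of illegal-carcass counts.
#' @export
simulate_counts <- function(eta, n_total, seed = NULL) {
  if (any(n_total < 1)) stop_validation("n_total must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  m <- max(length(eta), length(n_total))
  stats::rbinom(m, rep_len(n_total, m), stats::plogis(rep_len(eta, m)))
}

#' Simulate a carcass panel with known truth
#'
#' Generates a complete panel from a [simulation_config()]: site-to-country
#' assignment (round-robin shares, randomly allocated), standard-normal
#' covariates at every level (species Bernoulli(0.5) per site), realized
#' random intercepts drawn around their hierarchical means, negative-binomial
#' carcass totals, binomial illegal-carcass counts through the exact linear
#' predictor of the fitted model, and finally missing-data holes punched at
#' the configured per-covariate rates (true values of punched cells are kept
#' in the returned truth state).
#'
#' @param config a `pike_sim_config`.
#' @return An object of class `simulated_dataset`: a list with elements
#'   `panel` (a `carcass_panel`), `truth` (the generating parameter state,
#'   including realized intercepts, the true values of punched cells under
#'   `$imputed`, and the realized `$eta`), `spec` (the matching
#'   [model_spec()]) and `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "pike_sim_config"))
  set.seed(config$seed)
  S <- config$n_sites; C <- config$n_countries; Yn <- config$n_years
  site_ids <- sprintf("S%03d", seq_len(S))
  country_ids <- sprintf("C%03d", seq_len(C))
  yrs <- config$first_year + seq_len(Yn) - 1L

  # Round-robin country shares, randomly allocated to sites.
  site_country <- country_ids[sample(rep_len(seq_len(C), S))]

  gamma_names <- names(config$true_gamma)
  Zsite <- matrix(0, S, length(gamma_names), dimnames = list(site_ids, gamma_names))
  for (p in gamma_names) {
    Zsite[, p] <- if (p == "species") stats::rbinom(S, 1, 0.5) else stats::rnorm(S)
  }

  cy <- expand.grid(country_id = country_ids, year = yrs,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cy$governance <- stats::rnorm(nrow(cy))
  price <- stats::rnorm(Yn)

  present <- matrix(stats::rbinom(S * Yn, 1, config$presence_prob) == 1, S, Yn)
  if (!any(present)) stop_validation("no site-year records present; increase presence_prob")
  idx <- which(present, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  n <- nrow(idx)
  rec <- data.frame(site_id = site_ids[idx[, 1]],
                    country_id = site_country[idx[, 1]],
                    year = yrs[idx[, 2]],
                    n_illegal = 0L, n_total = 0L,
                    stringsAsFactors = FALSE)
  for (cv in config$covariates) rec[[cv]] <- stats::rnorm(n)

  sg <- config$sigmas
  u_country <- stats::rnorm(C, 0, sg[["country"]])
  mu_site <- drop(Zsite %*% config$true_gamma[gamma_names])
  u_site <- stats::rnorm(S, mu_site, sg[["site"]])
  mu_year <- config$true_beta_price * price
  u_year <- stats::rnorm(Yn, mu_year, sg[["year"]])
  u_sy <- stats::rnorm(n, 0, sg[["siteyear"]])

  law <- config$total_carcass_law
  rec$n_total <- switch(law$family,
    nbinom = rtrunc_nbinom(n, law$mean, law$dispersion, law$min),
    fixed = rep.int(as.integer(law$mean), n),
    stop_validation("unknown total_carcass_law family '%s'", law$family))

  sites <- data.frame(site_id = site_ids, country_id = site_country,
                      stringsAsFactors = FALSE)
  for (p in gamma_names) sites[[p]] <- Zsite[, p]
  years_tab <- data.frame(year = yrs, ivory_price = price)

  std <- lapply(setdiff(c(config$covariates, gamma_names, "governance", "ivory_price"),
                        "species"),
                function(cv) c(mean = 0, sd = 1))
  names(std) <- setdiff(c(config$covariates, gamma_names, "governance", "ivory_price"),
                        "species")
  panel <- carcass_panel(rec, sites, cy, years_tab,
                         standardized = TRUE, standardization = std)

  truth <- list(
    beta0 = config$true_beta0,
    beta = config$true_beta[config$covariates],
    beta_gov = unname(config$true_beta["governance"]),
    gamma = config$true_gamma,
    beta_price = config$true_beta_price,
    u_site = stats::setNames(u_site, site_ids),
    u_year = stats::setNames(u_year, as.character(yrs)),
    u_siteyear = stats::setNames(u_sy, paste(rec$site_id, rec$year, sep = ":")),
    u_country = stats::setNames(u_country, country_ids),
    sigma_site = sg[["site"]], sigma_year = sg[["year"]],
    sigma_siteyear = sg[["siteyear"]], sigma_country = sg[["country"]],
    lambda = 1,
    imputed = NULL)

  spec <- spec_for_config(config)
  eta <- linear_predictor(truth, panel, spec)
  panel$records$n_illegal <- stats::rbinom(n, panel$records$n_total, stats::plogis(eta))
  truth$eta <- eta

  punched <- punch_missing(panel, config, truth)
  panel <- punched$panel
  truth <- punched$truth

  if (config$raw_scale) panel <- apply_raw_scale(panel, config)
  validate_panel(panel)
  structure(list(panel = panel, truth = truth, spec = spec, config = config),
            class = "simulated_dataset")
}

punch_missing <- function(panel, config, truth) {
  rates <- config$missing_rates
  if (is.null(rates) || !length(rates)) return(list(panel = panel, truth = truth))
  imp <- list(records = NULL, country_years = NULL, sites = NULL, years = NULL)
  for (cv in names(rates)) {
    r <- rates[[cv]]
    if (r <= 0) next
    if (cv %in% config$covariates) {
      hit <- which(stats::rbinom(nrow(panel$records), 1, r) == 1)
      if (!length(hit)) next
      imp$records <- rbind(imp$records, data.frame(
        site_id = panel$records$site_id[hit], year = panel$records$year[hit],
        covariate = cv, value = panel$records[[cv]][hit], stringsAsFactors = FALSE))
      panel$records[[cv]][hit] <- NA_real_
    } else if (cv == "governance") {
      hit <- which(stats::rbinom(nrow(panel$country_years), 1, r) == 1)
      if (!length(hit)) next
      imp$country_years <- rbind(imp$country_years, data.frame(
        country_id = panel$country_years$country_id[hit],
        year = panel$country_years$year[hit],
        value = panel$country_years$governance[hit], stringsAsFactors = FALSE))
      panel$country_years$governance[hit] <- NA_real_
    } else if (cv == "ivory_price") {
      hit <- which(stats::rbinom(nrow(panel$years), 1, r) == 1)
      if (!length(hit)) next
      imp$years <- rbind(imp$years, data.frame(
        year = panel$years$year[hit], value = panel$years$ivory_price[hit]))
      panel$years$ivory_price[hit] <- NA_real_
    } else if (cv %in% names(panel$sites)) {
      hit <- which(stats::rbinom(nrow(panel$sites), 1, r) == 1)
      if (!length(hit)) next
      imp$sites <- rbind(imp$sites, data.frame(
        site_id = panel$sites$site_id[hit], covariate = cv,
        value = panel$sites[[cv]][hit], stringsAsFactors = FALSE))
      panel$sites[[cv]][hit] <- NA_real_
    } else {
      stop_validation("missing_rates names unknown covariate '%s'", cv)
    }
  }
  truth$imputed <- imp
  list(panel = panel, truth = truth)
}

# Raw-scale mode: push each standardized covariate through an affine map so
# downstream code must Z-transform before fitting.
apply_raw_scale <- function(panel, config) {
  slots <- panel_covariate_slots(panel)
  pars <- config$raw_params %||% list()
  i <- 0
  for (cv in names(slots)) {
    tab <- slots[[cv]]$table
    if (is_binary_col(panel[[tab]][[cv]])) next
    i <- i + 1
    p <- pars[[cv]] %||% c(mean = 10 * i, sd = 1 + i / 2)
    panel[[tab]][[cv]] <- panel[[tab]][[cv]] * p[["sd"]] + p[["mean"]]
  }
  panel$standardized <- FALSE
  panel$standardization <- NULL
  panel
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("Simulated carcass panel (seed", x$config$seed, ")\n")
  print(x$panel)
  cat("  true beta0:", x$truth$beta0, "| sigmas:",
      paste(sprintf("%s=%.2f", c("site", "year", "siteyear", "country"),
                    c(x$truth$sigma_site, x$truth$sigma_year,
                      x$truth$sigma_siteyear, x$truth$sigma_country)),
            collapse = " "), "\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes the panel in the standard CSV schema plus a `truth.json` with the
#' generating parameter values.
#'
#' @param dataset a `simulated_dataset`.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  write_panel(dataset$panel, dir)
  truth <- dataset$truth
  truth$imputed <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
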