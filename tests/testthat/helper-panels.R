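# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# A minimal hand-written two-country, three-site, three-year panel.
tiny_panel <- function(records_extra = NULL) {
  records <- data.frame(
    site_id = c("A", "A", "B", "B", "C"),
    country_id = c("K1", "K1", "K1", "K1", "K2"),
    year = c(2002L, 2003L, 2002L, 2003L, 2002L),
    n_illegal = c(2L, 0L, 5L, 3L, 1L),
    n_total = c(4L, 7L, 10L, 3L, 2L),
    wealth = c(1, 2, 3, 4, 5),
    ndvi = c(0.1, NA, 0.3, 0.2, 0.5),
    stringsAsFactors = FALSE)
  if (!is.null(records_extra)) records <- records_extra(records)
  sites <- data.frame(
    site_id = c("A", "B", "C"),
    country_id = c("K1", "K1", "K2"),
    area_km2 = c(100, 200, 300),
    law_enforcement = c(0.5, 0.2, 0.9),
    travel_time = c(10, 20, 30),
    species = c(0, 0, 1),
    stringsAsFactors = FALSE)
  years <- data.frame(year = 2002:2004, ivory_price = c(1.5, NA, 0.5))
  country_years <- expand.grid(country_id = c("K1", "K2"), year = 2002:2004,
                               KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  country_years$governance <- c(-0.5, 0.5, -0.4, NA, 0.1, 0.3)
  carcass_panel(records, sites, country_years, years)
}

write_tiny_csvs <- function(dir, panel = tiny_panel()) {
  write_panel(panel, dir)
  list(records = file.path(dir, "records.csv"),
       sites = file.path(dir, "sites.csv"),
       country_years = file.path(dir, "country_years.csv"),
       years = file.path(dir, "years.csv"))
}

# Model spec matching the tiny panel's covariates.
tiny_spec <- function(...) {
  model_spec(site_year_covariates = c("wealth", "ndvi"), ...)
}

# Zero parameter state sized for a panel/spec; individual pieces can then be
# overridden.
zero_state <- function(panel, spec = tiny_spec(), ...) {
  fr <- pikeglmm:::build_frame(panel, spec)
  st <- list(
    beta0 = 0,
    beta = stats::setNames(rep(0, fr$K), spec$site_year_covariates),
    beta_gov = 0,
    gamma = stats::setNames(rep(0, fr$P), spec$site_covariates),
    beta_price = 0,
    u_site = stats::setNames(rep(0, fr$S), fr$site_ids),
    u_year = stats::setNames(rep(0, fr$Y), as.character(fr$years)),
    u_siteyear = rep(0, fr$n),
    u_country = stats::setNames(rep(0, fr$C), fr$country_ids),
    sigma_site = 1, sigma_year = 1, sigma_siteyear = 1, sigma_country = 1,
    lambda = 1, imputed = NULL)
  utils::modifyList(st, list(...))
}

# Imputed-value tables resolving every missing cell of a panel to zero (the
# standard-normal prior mean).
zero_imputed <- function(panel, spec = tiny_spec()) {
  fr <- pikeglmm:::build_frame(panel, spec)
  imp <- list()
  recs <- NULL
  for (k in seq_len(fr$K)) {
    i <- fr$mis_X[[k]]
    if (length(i)) {
      recs <- rbind(recs, data.frame(site_id = fr$rec$site_id[i],
                                     year = fr$rec$year[i],
                                     covariate = spec$site_year_covariates[k],
                                     value = 0, stringsAsFactors = FALSE))
    }
  }
  imp$records <- recs
  if (length(fr$mis_gov)) {
    imp$country_years <- data.frame(country_id = fr$gov_cells$country_id,
                                    year = fr$gov_cells$year, value = 0,
                                    stringsAsFactors = FALSE)
  }
  zs <- NULL
  for (p in seq_len(fr$P)) {
    s <- fr$mis_Z[[p]]
    if (length(s)) {
      zs <- rbind(zs, data.frame(site_id = fr$site_ids[s],
                                 covariate = spec$site_covariates[p],
                                 value = 0, stringsAsFactors = FALSE))
    }
  }
  imp$sites <- zs
  if (length(fr$mis_price)) {
    imp$years <- data.frame(year = fr$years[fr$mis_price], value = 0)
  }
  imp
}

# Small, fast simulation configuration for sampler tests.
fast_sim_config <- function(...) {
  simulation_config(n_sites = 12, n_countries = 4, n_years = 6,
                    presence_prob = 1,
                    total_carcass_law = list(family = "nbinom", mean = 30,
                                             dispersion = 1, min = 1),
                    sigmas = c(site = 0.3, year = 0.2, siteyear = 0.3,
                               country = 0.3),
                    ...)
}

fast_mcmc <- function(...) {
  args <- utils::modifyList(list(n_iterations = 1500, n_burnin = 750,
                                 n_chains = 2, n_retained = 600, seed = 7),
                            list(...))
  do.call(mcmc_config, args)
}

# Intercept-only specification (no covariates, no random effects).
intercept_only_spec <- function() {
  model_spec(site_year_covariates = character(),
             country_year_covariate = NULL,
             site_covariates = character(),
             year_covariate = NULL,
             random_effects = character())
}

# One-record panel for the exact 1-D posterior oracle.
one_record_panel <- function(n_illegal = 7L, n_total = 10L) {
  carcass_panel(
    records = data.frame(site_id = "A", country_id = "K1", year = 2002L,
                         n_illegal = n_illegal, n_total = n_total,
                         stringsAsFactors = FALSE),
    sites = data.frame(site_id = "A", country_id = "K1", stringsAsFactors = FALSE),
    country_years = data.frame(country_id = "K1", year = 2002L),
    years = data.frame(year = 2002L),
    standardized = TRUE, standardization = list())
}

# Batch-means Monte-Carlo standard error of the mean of a draw vector.
mcse <- function(x, n_batches = 25) {
  nb <- min(n_batches, floor(length(x) / 4))
  bm <- tapply(x, cut(seq_along(x), nb, labels = FALSE), mean)
  stats::sd(bm) / sqrt(nb)
}
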