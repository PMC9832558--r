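# Carcass panel construction, validation, standardization and covariate
# transforms.

CORE_RECORD_COLS <- c("site_id", "country_id", "year", "n_illegal", "n_total")

#' Construct a site-year carcass panel
#'
#' A carcass panel bundles the four tables the hierarchical PIKE model
#' consumes: site-year carcass records with their site-by-year covariates,
#' a site table (area, law-enforcement capacity, travel time, elephant
#' species), a country-by-year governance table, and a year table carrying
#' the global ivory-price trend. All referential integrity and counting
#' invariants are checked on construction.
#'
#' @param records data frame with columns `site_id`, `country_id`, `year`,
#'   `n_illegal`, `n_total`, plus one numeric column per site-by-year
#'   covariate (e.g. `conflict_lag2`, `elephant_density`, `wealth`, `health`,
#'   `precip_anomaly`, `ndvi`). Missing covariate cells are `NA`.
#' @param sites data frame with columns `site_id`, `country_id`, `area_km2`,
#'   `law_enforcement`, `travel_time`, `species` (0 = savannah elephants,
#'   1 = forest elephants).
#' @param country_years data frame with columns `country_id`, `year`,
#'   `governance`; one row per country-year in the panel span.
#' @param years data frame with columns `year`, `ivory_price`; one row per
#'   panel year (`NA` price allowed).
#' @param standardized logical; whether covariates are already on the
#'   standardized (Z) scale.
#' @param standardization named list of `c(mean, sd)` pairs recorded by
#'   [z_transform()]; `NULL` for raw panels.
#'
#' @return An object of class `carcass_panel`.
#' @seealso [read_panel()], [z_transform()], [observed_pike()]
#' @export
carcass_panel <- function(records, sites, country_years, years,
                          standardized = FALSE, standardization = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  country_years <- as.data.frame(country_years, stringsAsFactors = FALSE)
  years <- as.data.frame(years, stringsAsFactors = FALSE)
  for (col in c("site_id", "country_id")) {
    if (col %in% names(records)) records[[col]] <- as.character(records[[col]])
    if (col %in% names(sites)) sites[[col]] <- as.character(sites[[col]])
  }
  if ("country_id" %in% names(country_years)) {
    country_years$country_id <- as.character(country_years$country_id)
  }
  x <- structure(
    list(records = records, sites = sites, country_years = country_years,
         years = years,
         covariates = setdiff(names(records), CORE_RECORD_COLS),
         standardized = isTRUE(standardized),
         standardization = standardization),
    class = "carcass_panel")
  validate_panel(x)
  x
}

validate_panel <- function(x) {
  rec <- x$records
  need <- setdiff(CORE_RECORD_COLS, names(rec))
  if (length(need)) {
    stop_validation("records table is missing columns: %s",
                    paste(need, collapse = ", "))
  }
  for (col in setdiff(names(rec), c("site_id", "country_id"))) {
    if (!is.numeric(rec[[col]])) {
      stop_validation("records column '%s' is not numeric; unrecognized missing token?", col)
    }
  }
  key <- paste(rec$site_id, rec$year, sep = ":")
  if (anyDuplicated(key)) {
    stop_validation("duplicate (site_id, year) record(s): %s",
                    paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  if (any(is.na(rec$n_illegal)) || any(is.na(rec$n_total))) {
    stop_validation("carcass counts may not be missing")
  }
  if (any(rec$n_illegal < 0) || any(rec$n_total < 0)) {
    stop_validation("negative carcass counts")
  }
  bad <- which(rec$n_illegal > rec$n_total)
  if (length(bad)) {
    stop_validation("n_illegal > n_total for record(s): %s",
                    paste(key[bad], collapse = ", "))
  }

  st <- x$sites
  need <- setdiff(c("site_id", "country_id"), names(st))
  if (length(need)) stop_validation("sites table is missing columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(st$site_id)) stop_validation("duplicate site_id in sites table")
  unknown <- setdiff(rec$site_id, st$site_id)
  if (length(unknown)) {
    stop_validation("records reference unknown site(s): %s", paste(unknown, collapse = ", "))
  }
  site_country <- st$country_id[match(rec$site_id, st$site_id)]
  if (any(site_country != rec$country_id)) {
    stop_validation("record country_id disagrees with sites table for: %s",
                    paste(unique(rec$site_id[site_country != rec$country_id]), collapse = ", "))
  }
  if ("species" %in% names(st)) {
    sp <- st$species[!is.na(st$species)]
    if (length(sp) && !all(sp %in% c(0, 1))) {
      stop_validation("species must be coded 0 (savannah) or 1 (forest)")
    }
  }

  yr <- x$years
  if (!"year" %in% names(yr)) stop_validation("years table is missing 'year'")
  if (anyDuplicated(yr$year)) stop_validation("duplicate year in years table")
  span <- range(yr$year)
  if (any(rec$year < span[1] | rec$year > span[2]) || !all(rec$year %in% yr$year)) {
    stop_validation("record year(s) outside the panel span %d-%d", span[1], span[2])
  }

  cy <- x$country_years
  need <- setdiff(c("country_id", "year"), names(cy))
  if (length(need)) stop_validation("country_years table is missing columns: %s", paste(need, collapse = ", "))
  cykey <- paste(cy$country_id, cy$year, sep = ":")
  if (anyDuplicated(cykey)) stop_validation("duplicate (country_id, year) in country_years")
  want <- paste(rep(unique(st$country_id), each = nrow(yr)), yr$year, sep = ":")
  miss <- setdiff(want, cykey)
  if (length(miss)) {
    stop_validation("country_years is missing %d country-year row(s), e.g. %s",
                    length(miss), miss[1])
  }

  # Covariate names must be unique across the four tables so standardization
  # parameters and coefficients can be keyed by bare covariate name.
  all_cov <- c(x$covariates,
               setdiff(names(st), c("site_id", "country_id")),
               setdiff(names(cy), c("country_id", "year")),
               setdiff(names(yr), "year"))
  if (anyDuplicated(all_cov)) {
    stop_validation("covariate names must be unique across tables: %s",
                    paste(unique(all_cov[duplicated(all_cov)]), collapse = ", "))
  }
  invisible(x)
}

#' @export
print.carcass_panel <- function(x, ...) {
  rec <- x$records
  cat("Carcass panel:", nrow(rec), "site-year records |",
      nrow(x$sites), "sites |",
      length(unique(x$sites$country_id)), "countries |",
      nrow(x$years), "years\n")
  cat("  modelled records (n_total >= 1):", sum(rec$n_total >= 1), "\n")
  cat("  site-year covariates:", paste(x$covariates, collapse = ", "), "\n")
  cat("  standardized:", x$standardized, "\n")
  invisible(x)
}

#' Read a carcass panel from CSV files
#'
#' Reads the four-table CSV schema (records, sites, country-years, years) and
#' validates it into a [carcass_panel()]. Empty cells and the literal `NA`
#' are both accepted as the missing token.
#'
#' @param records_path,sites_path,country_years_path,years_path file paths to
#'   the four UTF-8, comma-separated tables (header row required).
#' @return A validated, unstandardized `carcass_panel`.
#' @export
read_panel <- function(records_path, sites_path, country_years_path, years_path) {
  for (p in c(records_path, sites_path, country_years_path, years_path)) {
    if (!file.exists(p)) stop_validation("file not found: %s", p)
  }
  rd <- function(p) utils::read.csv(p, na.strings = c("", "NA"),
                                    stringsAsFactors = FALSE, encoding = "UTF-8")
  carcass_panel(rd(records_path), rd(sites_path), rd(country_years_path),
                rd(years_path), standardized = FALSE)
}

#' Write a carcass panel to CSV files
#'
#' Inverse of [read_panel()]: writes `records.csv`, `sites.csv`,
#' `country_years.csv` and `years.csv` into `dir` (missing cells as empty).
#'
#' @param panel a `carcass_panel`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the four file paths.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "carcass_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("records.csv", "sites.csv", "country_years.csv", "years.csv"))
  utils::write.csv(panel$records, paths[1], row.names = FALSE, na = "")
  utils::write.csv(panel$sites, paths[2], row.names = FALSE, na = "")
  utils::write.csv(panel$country_years, paths[3], row.names = FALSE, na = "")
  utils::write.csv(panel$years, paths[4], row.names = FALSE, na = "")
  invisible(paths)
}

#' Observed PIKE
#'
#' The Proportion of Illegally Killed Elephants for a record is the number of
#' illegally killed carcasses detected divided by all carcasses detected.
#' Records with zero detected carcasses have no defined PIKE and are excluded
#' from modelling.
#'
#' @param object either a vector of illegal-carcass counts, or a
#'   `carcass_panel` (in which case PIKE is returned for every modelled
#'   record, i.e. those with `n_total >= 1`).
#' @param ... further arguments; for the default method, `n_total`.
#' @return Numeric vector of proportions in \[0, 1\].
#' @export
observed_pike <- function(object, ...) UseMethod("observed_pike")

#' @rdname observed_pike
#' @param n_total total carcass counts (default method).
#' @export
observed_pike.default <- function(object, n_total, ...) {
  n_illegal <- object
  if (length(n_illegal) != length(n_total)) stop_validation("count vectors differ in length")
  if (any(n_total < 1)) stop_validation("PIKE is undefined when n_total = 0")
  if (any(n_illegal < 0) || any(n_illegal > n_total)) {
    stop_validation("need 0 <= n_illegal <= n_total")
  }
  n_illegal / n_total
}

#' @rdname observed_pike
#' @export
observed_pike.carcass_panel <- function(object, ...) {
  rec <- object$records[object$records$n_total >= 1, , drop = FALSE]
  structure(rec$n_illegal / rec$n_total,
            names = paste(rec$site_id, rec$year, sep = ":"))
}

# Enumerate the standardizable covariate columns of a panel: site-year
# covariates in records, site covariates, governance, ivory price. Binary 0/1
# columns (the species flag) are reported but marked non-standardizable so
# the coding the coefficients are interpreted on is preserved.
panel_covariate_slots <- function(panel) {
  slots <- list()
  for (cv in panel$covariates) slots[[cv]] <- list(table = "records", column = cv)
  for (cv in setdiff(names(panel$sites), c("site_id", "country_id"))) {
    slots[[cv]] <- list(table = "sites", column = cv)
  }
  for (cv in setdiff(names(panel$country_years), c("country_id", "year"))) {
    slots[[cv]] <- list(table = "country_years", column = cv)
  }
  for (cv in setdiff(names(panel$years), "year")) {
    slots[[cv]] <- list(table = "years", column = cv)
  }
  slots
}

is_binary_col <- function(v) {
  v <- v[!is.na(v)]
  length(v) > 0 && all(v %in% c(0, 1))
}

#' Z-transform panel covariates
#'
#' Standardizes every covariate column (site-by-year covariates, site
#' covariates, governance, ivory price) to mean 0 and sample standard
#' deviation 1, computed over non-missing values only; `NA` cells stay `NA`
#' and are later treated as standard-normal latent nodes by the sampler.
#' Binary 0/1 columns (the elephant-species flag) keep their coding. The
#' per-covariate `(mean, sd)` pairs are stored so [unstandardize()] can
#' recover the original scale.
#'
#' @param panel an unstandardized `carcass_panel`.
#' @return The standardized panel.
#' @export
z_transform <- function(panel) {
  stopifnot(inherits(panel, "carcass_panel"))
  if (panel$standardized) stop_validation("panel is already standardized")
  slots <- panel_covariate_slots(panel)
  params <- list()
  for (cv in names(slots)) {
    tab <- slots[[cv]]$table
    v <- panel[[tab]][[cv]]
    if (is_binary_col(v)) next
    obs <- v[!is.na(v)]
    if (length(unique(obs)) < 2) {
      stop_validation("covariate '%s' is constant; cannot Z-transform", cv)
    }
    m <- mean(obs)
    s <- stats::sd(obs)
    panel[[tab]][[cv]] <- (v - m) / s
    params[[cv]] <- c(mean = m, sd = s)
  }
  panel$standardized <- TRUE
  panel$standardization <- params
  validate_panel(panel)
  panel
}

#' Undo a Z-transform
#'
#' @param panel a standardized `carcass_panel` produced by [z_transform()].
#' @return The panel on its original covariate scale.
#' @export
unstandardize <- function(panel) {
  stopifnot(inherits(panel, "carcass_panel"))
  if (!panel$standardized) stop_validation("panel is not standardized")
  if (is.null(panel$standardization)) stop_validation("no stored standardization parameters")
  slots <- panel_covariate_slots(panel)
  for (cv in names(panel$standardization)) {
    p <- panel$standardization[[cv]]
    tab <- slots[[cv]]$table
    panel[[tab]][[cv]] <- panel[[tab]][[cv]] * p[["sd"]] + p[["mean"]]
  }
  panel$standardized <- FALSE
  panel$standardization <- NULL
  panel
}

#' Trailing-window conflict intensity
#'
#' Total battle deaths summed over a trailing window of years: the value at
#' year y is the sum over years \[y - window + 1, y\]. Windows are truncated
#' (partial sums) at the start of the series so no site-years are lost;
#' `window = 1` is the identity. The windows used in practice are 1, 2, 3
#' and 5 years.
#'
#' @param deaths numeric vector of battle deaths, indexed by consecutive
#'   years.
#' @param window integer window length (>= 1).
#' @param years optional year index; if supplied it must be consecutive.
#' @return Numeric vector of windowed sums, same length as `deaths`.
#' @export
conflict_lag <- function(deaths, window, years = NULL) {
  if (length(window) != 1 || window < 1 || window != as.integer(window)) {
    stop_validation("window must be a single integer >= 1")
  }
  if (!is.null(years) && length(years) > 1 && any(diff(years) != 1)) {
    stop_validation("year index must be consecutive")
  }
  if (any(is.na(deaths))) stop_validation("deaths series contains missing values")
  if (any(deaths < 0)) stop_validation("deaths must be non-negative")
  n <- length(deaths)
  cs <- cumsum(deaths)
  cs - c(rep(0, min(window, n)), cs)[seq_len(n)]
}

#' Add conflict-lag covariates to a panel
#'
#' Computes [conflict_lag()] per site from a raw battle-deaths column and adds
#' one covariate column per window (`conflict_lag1`, `conflict_lag2`, ...).
#' Each site's records must cover consecutive years for the trailing sums to
#' be well defined.
#'
#' @param panel a `carcass_panel` whose records carry `source_col`.
#' @param windows integer windows (default `c(1, 2, 3, 5)`).
#' @param source_col name of the raw deaths column (default
#'   `"conflict_deaths"`).
#' @return The panel with the new columns appended.
#' @export
add_conflict_lags <- function(panel, windows = c(1, 2, 3, 5),
                              source_col = "conflict_deaths") {
  stopifnot(inherits(panel, "carcass_panel"))
  rec <- panel$records
  if (!source_col %in% names(rec)) stop_validation("no column '%s' in records", source_col)
  ord <- order(rec$site_id, rec$year)
  for (w in windows) rec[[sprintf("conflict_lag%d", w)]] <- NA_real_
  for (sid in unique(rec$site_id)) {
    i <- ord[rec$site_id[ord] == sid]
    yrs <- rec$year[i]
    if (length(yrs) > 1 && any(diff(yrs) != 1)) {
      stop_validation("site %s has non-consecutive years; cannot build conflict lags", sid)
    }
    for (w in windows) {
      rec[[sprintf("conflict_lag%d", w)]][i] <- conflict_lag(rec[[source_col]][i], w)
    }
  }
  panel$records <- rec
  panel$covariates <- setdiff(names(rec), CORE_RECORD_COLS)
  panel
}

# Subset a panel's records (lookup tables are kept whole so group covariates
# stay available for prediction at held-out sites/years).
subset_records <- function(panel, idx) {
  panel$records <- panel$records[idx, , drop = FALSE]
  rownames(panel$records) <- NULL
  panel
}
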