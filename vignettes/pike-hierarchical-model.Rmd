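---
title: "A hierarchical binomial model of illegal elephant killing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical binomial model of illegal elephant killing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Site-based carcass monitoring measures poaching pressure as PIKE — the
Proportion of Illegally Killed Elephants: of all elephant carcasses detected
at a site in a year, the fraction judged illegally killed. `pikeglmm` models
the illegal count of each site-year record as binomial in the total detected
carcasses,

$$
N^{\text{illegal}}_{sy} \sim \text{Binomial}\!\left(\text{PIKE}_{sy},\,
N^{\text{total}}_{sy}\right),
$$

with a logit regression carrying covariates at four scales plus four levels
of normally distributed random intercepts:

$$
\text{logit}(\text{PIKE}_{sy}) = \beta_0 + \sum_k \beta_k X_{sy,k}
 + \beta_{\text{gov}}\,\text{Gov}_{c(s),y}
 + u_s + u_y + u_{sy} + u_{c(s)},
$$

where the site-by-year covariates $X$ default to armed-conflict battle
deaths over a two-year trailing window, elephant density, household wealth,
household health, precipitation anomaly and vegetation density (NDVI), and
$\text{Gov}$ is country-by-year governance quality. The intercept
distributions are hierarchical: site intercepts are centred on a regression
over the time-invariant site covariates (area, law-enforcement capacity,
travel time to the nearest city, and the 0/1 forest-elephant species flag),

$$
u_s \sim N(\gamma^\top x_s,\ \sigma_{\text{site}}), \qquad
u_y \sim N(\beta_{\text{price}}\,\text{price}_y,\ \sigma_{\text{year}}),
$$

and the year intercepts on the global ivory-price trend; the record-level
site-year intercept $u_{sy} \sim N(0, \sigma_{\text{site-year}})$ absorbs
overdispersion and pseudo-replication within a site-year, and
$u_c \sim N(0, \sigma_{\text{country}})$ captures country-level clustering.

Variable selection is Bayesian LASSO: every covariate coefficient (the
$\beta_k$, $\beta_{\text{gov}}$, the $\gamma$s and $\beta_{\text{price}}$)
receives an independent Laplace prior with common rate $\lambda$,
$f(\beta) = \tfrac{\lambda}{2} e^{-\lambda |\beta|}$, and $\lambda$ a
gamma(1, 1) hyperprior. Random-effect standard deviations receive gamma(1, 1)
priors. Covariates are Z-transformed so coefficient magnitudes are
comparable and so that shrinkage acts on a common scale; the binary species
flag keeps its 0/1 coding so its coefficient reads as a forest-vs-savannah
contrast.

### Choices the model statement left open

* **Intercept prior.** The source model class does not pin down a prior for
  $\beta_0$; we use a weakly informative $N(0, 10)$. With standardized
  covariates this is effectively flat over any plausible logit-PIKE.
* **$\lambda$ hyperprior.** A gamma(shape 1, rate 1) default, configurable
  through `model_spec(priors = ...)`. The LASSO-shrinkage property tests use
  concentrated hyperpriors (large shape at fixed mean) to verify that
  stronger rates shrink null coefficients harder.
* **Coefficient bookkeeping.** Coefficients are keyed by covariate name
  throughout, never by position, and the species flag enters the site-mean
  regression alongside area, law enforcement and travel time.
* **Wealth and health** both enter the default covariate list; either can be
  dropped via `model_spec()` when their collinearity in a particular panel
  argues for separate models.

## Data handling

`read_panel()` consumes four CSV tables (records, sites, country-years,
years); empty cells and `NA` are the missing token. Records with zero
detected carcasses have no defined PIKE and carry no binomial information,
so they are excluded from the likelihood (the panel keeps them).
Standardization statistics are computed over non-missing values only:
missing cells are later imputed on the standard-normal scale, and
standardizing after imputation would be circular. Conflict-lag windows
(1, 2, 3, 5 years) are trailing sums truncated at the start of each site's
series — partial sums rather than missing values — so all records stay in
the model whichever window is chosen.

Missing covariate cells are latent nodes with standard-normal priors,
updated by the sampler every sweep against prior times likelihood, exactly
as a declarative Gibbs engine treats unobserved covariates. A `oneshot`
mode (draw once at initialization, hold fixed) is provided for sensitivity
checks, and with no missing cells both modes are bit-identical to not having
imputation machinery at all (this is asserted in the tests).

## The sampler

The engine is a bespoke component-wise adaptive random-walk
Metropolis-within-Gibbs, written for this model rather than delegated to a
general-purpose PPL:

* Scalar coefficients are updated one at a time against the full binomial
  likelihood; the linear predictor and its `log(1+exp())` cache are
  maintained incrementally, so each update costs one pass over the records.
* Random intercepts are updated per group. Records of different sites (or
  years, or countries) are disjoint, so the per-group accept/reject
  decisions within one block are exact.
* The intercept rides a flat ridge against the means of the zero-centred
  intercept levels (adding a constant to $\beta_0$ and subtracting it from
  every country intercept leaves the likelihood unchanged), which plain
  component-wise updates traverse slowly. One translation move per enabled
  level — $\beta_0 \mathrel{+}= \delta$, the whole level $\mathrel{-}=
  \delta$ — is therefore included each sweep; the likelihood cancels and the
  Metropolis ratio involves only the priors.
* $\sigma$s and $\lambda$ are proposed on the log scale with the Jacobian
  folded into the target (for a gamma(a, b) prior the log-scale target is
  $a \log \sigma - b\sigma$ plus the intercept terms).
* Proposal scales adapt toward 0.44 acceptance (the classic optimal rate for
  one-dimensional random walks) by Robbins-Monro steps during burn-in only;
  after burn-in the kernel is fixed, preserving detailed balance.
* Every update consumes exactly one normal and one uniform variate from R's
  RNG, so a seed fully determines a chain regardless of acceptance history.
* Chains are initialized from overdispersed draws: coefficients
  $N(0, \texttt{init\_spread})$, $\sigma$s from their prior, $\lambda$ at
  its prior mean, intercepts from their prior laws given those draws.

Default MCMC settings are 3 chains of 100 000 iterations with a 50 000
burn-in and 5 000 retained draws in total (even-stride thinning), the
full-length settings for a real analysis. The test-suite and acceptance
runs use deliberately reduced sizes — panels of roughly 160–780 records and
chains of 1 500–30 000 iterations — chosen so each check has enough Monte
Carlo precision for its tolerance; these sizes are stated alongside each
check.

Convergence is monitored with split-chain Gelman-Rubin $\hat R$ (each chain
halved, so the statistic exists for a single chain too), with $\hat R < 1.1$
the conventional pass; constant chains return `NaN` with a warning rather
than a spurious pass.

The pure-R `log_likelihood()` / `log_prior()` / `log_posterior()` functions
are an independent implementation of the same density (the posterior is
their sum by construction, one code path); tests reconstruct parameter
states from retained draws and require the sampler's recorded log posterior
to agree with the R path to 1e-8, and compare the sampler's posterior
against deterministic grid quadrature on a one-parameter reduction.

## The synthetic-data generator

`simulate_panel()` is the generative mirror of the fitted model and defines
the conditions under which the package is validated: 64 sites nested in 30
countries over 19 years with each site-year present with probability 0.64
(about 780 records), matching the monitoring panel's shape. Covariates are
standard normal (the species flag Bernoulli(0.5) per site) — i.e. generated
on the post-Z-transform scale the model consumes — with a raw-scale mode
that applies affine maps so the standardization code is exercised too.
Carcass totals are negative binomial (mean 15, dispersion 1, truncated at
one carcass) by default, reflecting the highly variable detection totals of
real sites; the distribution of real totals is not published as a law, so
this is a modelling choice, and the family is configurable (acceptance runs
use mean 50 where the checks need stronger per-record information). Site-to-
country assignment is round-robin shares allocated at random: only the
nesting structure matters to the model. Default true effects are sparse and
moderate (negative wealth, health, governance, law-enforcement effects; a
positive price trend and forest-species contrast; exact zeros elsewhere),
with $\sigma_{\text{site}} = 0.7$ dominating the intercept variance, year
variation smallest, and an intercept of $-0.5$ giving realistic mid-range
PIKE levels.

What the generator deliberately does **not** emulate: spatial
autocorrelation of covariate fields, temporal autocorrelation beyond the
year intercept, detection biases of the PIKE index itself, and
measurement error in covariates. Passing recovery and calibration tests
therefore demonstrates that the machinery is correct under the model's own
assumptions — not that those assumptions hold for any real monitoring panel.

## Model criticism

* **Bayesian p-values.** For each retained draw, replicate counts are
  simulated from the binomial likelihood and a discrepancy is computed for
  observed and replicate data; the p-value is $\Pr(D_{\text{rep}} \ge
  D_{\text{obs}})$. The discrepancy defaults to the chi-squared form
  $\sum (y - np)^2 / (np(1-p))$ with $p$ clipped away from 0 and 1
  (at $10^{-6}$), with Freeman-Tukey
  $\sum (\sqrt{y} - \sqrt{np})^2$ as an option — two standard
  posterior-predictive choices for counts.
* **Predictive validation.** A random 75/25 record split, and a spatially
  blocked split holding out 15 whole sites. Predictions for held-out records
  reuse posterior group effects where the group was seen in training and
  draw unseen groups fresh from their hierarchical law per draw; the
  record-level site-year intercept is always fresh. Performance is the
  squared Pearson correlation between observed PIKE and the per-record
  posterior-predictive median, with a 90% interval obtained by recomputing
  the correlation per draw.
* **Variance decomposition.** Proportional change in variance per level:
  $\text{PCV}_L = (V_L^{\text{RE-only}} - V_L^{\text{full}}) /
  V_L^{\text{RE-only}}$ with $V$ the posterior mean of $\sigma_L^2$,
  comparing the full model against its random-effects-only companion
  (`re_only_spec()`). Because point PCVs hide posterior uncertainty, a
  draw-wise PCV distribution is reported alongside.

## Reporting

`coefficient_summary()` gives posterior means with equal-tailed 90% credible
intervals; a covariate is "supported" when its interval excludes zero.
`conditional_effect()` draws the response-scale effect curve of one
covariate (others at their standardized mean, random effects at their prior
means) with a draw-wise credible band, plus per-record partial residuals.
The partial-residual construction is not standardized in this literature;
the default adds the record's logit-scale working residual at the
posterior-mean fit to the focal term before inverse-linking,
$\text{plogis}(\hat\beta_0 + \hat\beta_j x_{ij} + r_i)$ with
$r_i = (y_i/n_i - \hat p_i) / (\hat p_i (1 - \hat p_i))$; an alternative
"anchored" mode uses the residual of logit(observed PIKE, clipped) against
all non-focal fitted terms. `group_pike_summary()` ranks sites by a
covariate's site mean (stable tie-break by site id) and contrasts observed
PIKE across the 15 lowest, 15 highest and the middle sites.

## Numerical notes and limitations

* The binomial log PMF is evaluated as
  $\log\binom{n}{y} + y\eta - n\log(1+e^\eta)$, finite for arbitrarily large
  $|\eta|$.
* Proposal log-scales are clamped to $[-15, 5]$; adaptation steps shrink as
  $\min(0.25,\ 3/\sqrt{t})$.
* The intercept, country intercepts and site intercepts are only softly
  identified against each other (all could absorb a constant); their
  zero-centred priors anchor them, but individual intercept chains mix more
  slowly than coefficient chains, which is why convergence is monitored on
  the coefficient/σ/λ margin.
* Fits on panels with a handful of records per group estimate σs mostly
  from the prior; gamma(1, 1) is informative there by design.
* PCV can be mildly negative by Monte Carlo noise when covariates explain
  nothing at a level; that is expected behaviour of the estimator, not an
  error.
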