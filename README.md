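# pikeglmm

Hierarchical Bayesian modelling of the **Proportion of Illegally Killed
Elephants (PIKE)** across site-based carcass-monitoring panels, for
quantitative ecologists and conservation scientists asking which
socio-economic, political and environmental factors drive or facilitate
elephant poaching.

Carcass monitoring produces, per site `s` and year `y`, the number of
illegally killed carcasses among all carcasses detected. `pikeglmm` models

```
N_illegal[s,y] ~ Binomial(PIKE[s,y], N_total[s,y])

logit(PIKE[s,y]) = β0 + Σk βk X[s,y,k] + β_gov Gov[c(s),y]
                   + u_site[s] + u_year[y] + u_siteyear[s,y] + u_country[c(s)]

u_site[s] ~ N(γ' x_site[s], σ_site)         # area, law enforcement,
u_year[y] ~ N(β_price price[y], σ_year)     #   travel time, species
u_siteyear ~ N(0, σ_siteyear);  u_country ~ N(0, σ_country)
```

with Bayesian LASSO variable selection: independent Laplace priors with a
common rate λ on every covariate coefficient, λ ~ gamma(1, 1), and
gamma(1, 1) priors on the random-effect standard deviations. Inference is a
bespoke adaptive Metropolis-within-Gibbs sampler (compiled core) with
in-chain imputation of missing covariate cells as standard-normal latent
nodes, split-chain Gelman-Rubin diagnostics, posterior-predictive Bayesian
p-values, random and site-holdout predictive validation, and a proportional
change in variance (PCV) decomposition across the four random-effect
levels. A synthetic-panel generator with known ground truth makes the whole
pipeline testable end to end.

## Worked example

Simulate a monitoring panel with known truth (30 sites, 10 countries,
10 years, unbalanced presence; default true effects: negative wealth,
health, governance and law-enforcement effects, positive ivory-price trend
and forest-species contrast, zeros elsewhere), fit the model, and criticize
it:

```r
library(pikeglmm)

cfg <- simulation_config(n_sites = 30, n_countries = 10, n_years = 10,
                         presence_prob = 0.8, seed = 2024)
dat <- simulate_panel(cfg)

fit <- pike_glmm(dat$panel, dat$spec,
                 mcmc_config(n_iterations = 10000, n_burnin = 5000,
                             n_chains = 2, n_retained = 2000, seed = 1))
summary(fit)

bayesian_p_value(fit, seed = 1)

sp <- split_panel(dat$panel, "random", test_fraction = 0.25, seed = 1)
fit_tr <- pike_glmm(sp$train, dat$spec,
                    mcmc_config(n_iterations = 10000, n_burnin = 5000,
                                n_chains = 2, n_retained = 2000, seed = 1))
obs <- observed_pike(sp$test)
pred <- predict_pike(fit_tr, sp$test, seed = 1)
r_squared(obs, pred[names(obs)])
```

Output (abridged):

```
Covariate coefficients (posterior mean, 90% credible interval):
               name    mean   ci_low ci_high supported     sign
1     conflict_lag2  0.1033 -0.00636  0.2136     FALSE     none
3            wealth -0.3028 -0.41567 -0.1868      TRUE negative
4            health -0.4034 -0.52330 -0.2845      TRUE negative
7        governance -0.3895 -0.49850 -0.2826      TRUE negative
9   law_enforcement -0.3087 -0.62752 -0.0252      TRUE negative
12      ivory_price  0.3643  0.04412  0.6536      TRUE positive
...
LASSO rate lambda:
    name mean ci_low ci_high
1 lambda 3.42   1.93    5.32

Max split R-hat over monitored parameters: 1.038 (converged)
Bayesian p-value: 0.518
Holdout R^2 (random 75/25 split): 0.51
```

The summary flags a covariate as *supported* when its 90% credible interval
excludes zero: here the generator's five active effects are recovered with
the right signs, the shrinkage rate λ sits well above zero (nulls are pulled
toward zero), the Bayesian p-value near 0.5 shows the posterior-predictive
distribution reproduces the data's dispersion, and the model predicts a
quarter of held-out records with R² ≈ 0.5 against observed PIKE.

Other entry points: `read_panel()`/`z_transform()` for real CSV panels,
`conflict_lag()`/`add_conflict_lags()` for armed-conflict windows,
`conditional_effect()` for response-scale effect curves with partial
residuals, `group_pike_summary()` for PIKE contrasts between
covariate-extreme sites, `pcv()` for the variance decomposition, and
`gelman_rubin()` for convergence. A thin command-line wrapper with
`simulate` / `fit` / `assess` / `report` verbs lives at
`inst/cli/pike.R`.

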