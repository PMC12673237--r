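# behavpred

Quantifying **behavioural types** and **behavioural predictability** from
GPS telemetry, and measuring selection on both.

## The problem

Animals differ not only in their *average* behaviour (behavioural type:
how close to open cover an individual tends to stay, how fast it moves)
but also in how *variable* they are around that average. Residual
intra-individual variation (rIIV) — an individual's day-to-day scatter
around its own mean — is interpreted as behavioural (un)predictability:
a low-rIIV individual is routine-bound and predictable, a high-rIIV one
is erratic. For hunted and depredated species both axes matter: a
predator (human or otherwise) can exploit a risky average *and* a
predictable routine. This package provides the full analysis chain for
that question:

1. **Preprocessing** — raw GPS fixes (id, timestamp, x/y, DOP) are
   cleaned (DOP > 7 dropped), truncated to each animal's alive period,
   and aggregated into daily behavioural metrics: mean distance to open
   landcover, edge landcover and hunter-access points (from exact
   Euclidean distance rasters), total daily path length and average
   hourly speed (path / 15 h of diurnal sampling). Days with fewer than
   10 fixes or under 100 m of travel are excluded; distances are
   square-root transformed and every trait is z-scored.
2. **Double-hierarchical Gaussian model (DHGLM)** — for a standardized
   daily trait `y_ij` of individual `i` on day `j`:

   ```
   y_ij ~ Normal(mu_ij, sigma_ij^2)
   mu_ij        = x_ij' beta  + alpha_i        (mean model)
   log sigma_ij = x_ij' gamma + omega_i        (dispersion model)
   (alpha_i, omega_i) ~ BVN(0, {sigma_alpha^2,  rho sigma_alpha sigma_omega;
                                 .,             sigma_omega^2})
   ```

   with hunting stage (pre-hunt / hunt / post-hunt), site and daily fix
   count as covariates in both submodels. `alpha_i` is the behavioural
   type, `omega_i` the individual's rIIV deviation (log-SD scale), and
   `rho` the behavioural type–predictability **syndrome**. Fitting is by
   blocked adaptive MCMC (compiled core; conjugate Gibbs plus adaptive
   Metropolis and ancillary scaling/translation moves), with
   split-chain Rhat convergence checks. Derived posteriors:
   * repeatability `R = sigma_alpha^2 / (sigma_alpha^2 + sigma_eps^2)`,
   * coefficient of variation in predictability
     `CVp = sqrt(exp(sigma_omega^2) - 1)`,
   * the syndrome correlation `rho`.
3. **Selection analysis** — binary season survival is regressed on the
   *posterior draws* of each individual's `alpha_i` (type) or `omega_i`
   (rIIV): one ML logistic fit per retained draw (2000 under the default
   chain configuration), pooled as median, 95% CrI and probability of
   direction (PD). Iterating over the posterior propagates the
   uncertainty of the behavioural estimates (avoiding the "individual
   gambit"). Mortality-source subsets separate harvest-induced
   (survivors + harvested), natural (survivors + predated) and pooled
   selection.
4. **Synthetic data** — generators for patchy landscapes, duty-cycled
   GPS tracks (hourly 05:00–20:00 plus a midnight roost fix, missed
   fixes, right-skewed DOP), DHGLM-distributed daily traits with known
   ground truth, and survival linked to the *true* individual effects,
   so every stage is testable without field data.

Effects are declared significant when the 95% CrI excludes zero or
PD ≥ 89%.

## Worked example

```r
library(behavpred)

params <- dhglm_params(sigma_alpha = 0.5, sigma_omega = 0.3, rho = 0.6)
sim <- simulate_daily_traits(params, n_individuals = 40, days_per_ind = 60,
                             seed = 1)
fit <- fit_dhglm(sim$traits, trait = "y",
                 config = mcmc_config(iterations = 5000, burnin = 2000,
                                      thin = 6, chains = 2, seed = 2))
print(fit)
#> dhglm_fit: trait 'y', 40 individuals, 1000 retained draws (2 chains)
#>   converged: TRUE (max scalar Rhat 1.010)
#>     parameter    median     lower     upper  pd significant
#> 1 sigma_alpha 0.4540660 0.3616295 0.5883176 100        TRUE
#> 2 sigma_omega 0.2996409 0.2377358 0.3821607 100        TRUE
#> 3         rho 0.6471330 0.3584802 0.8123508 100        TRUE

cv_p(fit)
#> cv_p: median 0.306, 95% CrI [0.241, 0.397], PD 100.0%
syndrome(fit)
#> syndrome: median 0.647, 95% CrI [0.358, 0.812], PD 100.0%
```

The generating values (`sigma_alpha` 0.5, `sigma_omega` 0.3, `rho` 0.6,
hence population CVp `sqrt(exp(0.09) - 1) = 0.307`) sit inside every
interval. Selection on predictability, propagating the posterior draws:

```r
surv <- simulate_survival(sim$effects, intercept = 0.4, slope_omega = 1.5,
                          harvest_fraction = 0.6, seed = 3)
est <- iterate_selection(extract_blups(fit), surv, blup_kind = "rIIV",
                         source = "pooled")
est[, c("median", "lower", "upper", "pd", "n_survived", "n_dead")]
#>     median     lower    upper  pd n_survived n_dead
#> 1 1.409173 0.6497456 2.280973 100         28     12
```

A positive pooled log-odds ratio: unpredictable individuals (higher
rIIV) survived better, recovering the simulated slope (+1.5, attenuated
by shrinkage of the estimated effects). An end-to-end run from landscape
to selection table is one call: `run_pipeline(run_config(seed = 1))`,
summarized with `report()`.

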