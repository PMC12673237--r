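---
title: "Behavioural types, predictability and selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioural types, predictability and selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
location–scale hierarchical model at its core, the preprocessing
conventions feeding it, the sampler and its numerical choices, what the
synthetic-data generators do and do not emulate, and the known
limitations of the selection analysis.

## The double-hierarchical Gaussian model

Each standardized daily behavioural trait is modelled with paired mean
and dispersion submodels,

$$y_{ij} \sim \mathcal N(\mu_{ij},\ \sigma_{ij}^2), \qquad
\mu_{ij} = \mathbf x_{ij}'\boldsymbol\beta + \alpha_i, \qquad
\log \sigma_{ij} = \mathbf x_{ij}'\boldsymbol\gamma + \omega_i,$$

with correlated individual intercepts
$(\alpha_i, \omega_i) \sim \mathrm{BVN}(\mathbf 0, \Sigma)$,
$\Sigma = \begin{pmatrix}\sigma_\alpha^2 & \rho\sigma_\alpha\sigma_\omega \\ \cdot & \sigma_\omega^2\end{pmatrix}$.
The shared design $\mathbf x_{ij}$ is treatment-coded — pre-hunt stage
and the first site are the reference levels — and carries the hunt and
post-hunt stage contrasts, a site contrast, and the daily number of GPS
fixes centred at its sample mean. Centring the fix count makes the
intercepts interpretable at an average observation day and decorrelates
them from the slope.

Interpretation: $\alpha_i$ is the individual's behavioural type
(standardized-trait units), $\omega_i$ its residual intra-individual
variation (rIIV) on the log-SD scale — low $\omega_i$ means predictable,
high means unpredictable — and $\rho$ is the behavioural
type–predictability syndrome. Derived quantities, computed per posterior
draw:

* **Repeatability** $R = \sigma_\alpha^2 / (\sigma_\alpha^2 +
  \sigma_\varepsilon^2)$. The residual SD convention is not settled in
  the literature when the dispersion model has covariates; this package
  defines $\sigma_\varepsilon = \exp(\gamma_0)$, the fitted residual SD
  at the reference stage and site and the mean fix count, and documents
  that choice rather than mixing conventions. With centred fixes this is
  simply the dispersion intercept exponentiated.
* **Coefficient of variation in predictability**
  $\mathrm{CV_p} = \sqrt{\exp(\sigma_\omega^2) - 1}$: individual
  residual SDs are log-normal with log-scale SD $\sigma_\omega$, and
  this is exactly the CV of that log-normal. `cv_p()` reports both the
  median of per-draw transforms and the transform of the median
  $\sigma_\omega$ (`at_median`); the two differ by a Jensen gap, and the
  closed form on the median is what matches a table that prints
  $\sigma_\omega$ and CV$_p$ side by side.
* **Syndrome**: the posterior of $\rho$ directly.

Significance follows the credible-interval-or-PD rule: an effect is
flagged when its equal-tailed 95% CrI excludes zero or the probability
of direction is at least 89%. PD is the percentage of draws sharing the
sign of the posterior median (50 when the median is exactly zero, so a
perfectly symmetric posterior is never "significant" by direction).
Quantiles and medians are type-7 (linear interpolation) throughout.

## Priors

Weakly informative and explicit: $\mathcal N(0, 10)$ on every fixed
effect in both submodels, half-Student-t(3, 0, 2.5) on $\sigma_\alpha$
and $\sigma_\omega$, and a uniform prior on $\rho$ (the LKJ(1) density
for a 2×2 correlation matrix). On standardized traits these priors are
several times wider than any plausible effect; they reproduce the
"software default, vague" intent of common Bayesian mixed-model
workflows while being stated in full and configurable via
`dhglm_priors()`.

## The sampler

No gradient-based probabilistic-programming backend is assumed; the
sampler is a blocked adaptive MCMC written as compiled code, with these
moves per iteration:

1. $\boldsymbol\beta$ — exact Gaussian full conditional (weighted least
   squares with the current $\sigma_{ij}$).
2. $\alpha_i$ — exact per-individual Gaussian full conditionals, using
   the conditional prior $\alpha_i \mid \omega_i$.
3. $\omega_i$ — per-individual adaptive random-walk Metropolis. The
   individual's data enter only through $n_i$ and
   $t_i = \sum_j u_{ij}^2 e^{-2\mathbf x_{ij}'\boldsymbol\gamma}$, so
   all individuals are updated in one vectorized pass.
4. $\boldsymbol\gamma$ — joint adaptive Metropolis with an empirical
   proposal covariance (Haario-style), scaled by $2.38/\sqrt p$.
5. Two *scaling moves*: $(\boldsymbol\alpha, \log\sigma_\alpha) \to
   (e^\delta\boldsymbol\alpha, \log\sigma_\alpha + \delta)$ and its
   $\omega$ analogue. The bivariate-normal prior term and the transform
   Jacobian cancel exactly, leaving only the data likelihood and the
   half-t hyperprior in the acceptance ratio. These moves traverse the
   funnel between random effects and their scale that plagues centred
   parameterizations when a variance component is small.
6. *Translation moves* for every design column that is constant within
   individuals (intercept, site): $\beta_k \to \beta_k + \delta$,
   $\alpha_i \to \alpha_i - \delta z_i$ (and the $\gamma/\omega$
   analogue). The likelihood is invariant, so these directly sample the
   fixed-effect/random-effect trade-off that is otherwise the slowest
   direction of the posterior.
7. Hyperparameters $(\log\sigma_\alpha, \log\sigma_\omega,
   \operatorname{artanh}\rho)$ — joint adaptive Metropolis on the
   unconstrained scale, with the appropriate Jacobians.

Adaptation (Robbins–Monro on proposal scales, running proposal
covariances) is confined to the burn-in, so the retained chain is a
valid fixed-kernel sampler. Proposal scales target acceptance 0.44
(scalar moves) and 0.28 (joint moves). Numerical guards: log-SDs are
confined to $[-10, 5]$, $\operatorname{artanh}\rho$ to $[-7, 7]$, and
conditional prior variances are floored at $10^{-12}$ so degenerate
hyperparameter states cannot produce NaNs. Starting values are
empirical (per-individual means and log-SDs after an OLS fit), jittered
per chain so that split-chain Rhat retains diagnostic power; the centred
parameterization is the right one here because each individual
contributes tens of observations, making the likelihood — not the prior
— the dominant term for $(\alpha_i, \omega_i)$.

Convergence is assessed with split-chain Rhat on every parameter; a fit
with any scalar-parameter Rhat ≥ 1.1 is flagged (`converged = FALSE`
plus a warning), never silently accepted. A parameter with numerically
zero within-chain variance is reported as non-computable (`NA`) rather
than pretending 1.00: a constant chain is "converged-degenerate".

The default chain configuration (15,300 iterations, burn-in 300,
thinning 15, two chains) retains exactly 2000 draws, which is also the
number of per-draw survival refits downstream. Validation experiments in
the test suite run reduced chains (2 × 2000 iterations) after checking
that mixing at that length is adequate (max Rhat ≈ 1.04 on the designs
used).

The sampler was cross-checked against an independent implementation of
the identical model and priors in JAGS (`rjags`): posterior medians of
$\sigma_\alpha, \sigma_\omega, \rho$ agree to well under the Monte Carlo
error on a shared dataset. The joint density itself is unit-tested
against an independently coded sum of log-pdfs at $10^{-10}$ tolerance.

## Preprocessing conventions

* **DOP cleaning** keeps fixes with DOP ≤ 7 (strictly-greater dropped).
* **Alive-period truncation** removes fixes on or after a dead
  individual's death date; a dead individual without a death date is an
  error, not a silent pass.
* **Daily metrics** use the diurnal schedule only (05:00–20:00, 16
  scheduled fixes); the midnight roost fix is excluded. This matches the
  15-hour divisor that turns total daily path into average hourly speed:
  including the roost would mix a 9-hour overnight displacement into a
  15-hour denominator. Sub-hourly fixes, when present, are thinned to
  the fix nearest each hour top so path lengths are comparable across
  duty cycles.
* **Distance rasters**: cell-centre to cell-centre Euclidean distances
  via an exact two-pass distance transform (verified against the
  brute-force scan on every grid up to 20×20); distance to hunter
  access is computed point-exact (both a rasterized and an exact
  point-to-point route are available). Edge habitat is forest adjacent
  to open or road cells under the 4-neighbourhood by default
  (8-neighbourhood by flag) — the conservative, common raster
  convention.
* **Day filters** are strict inequalities read literally: days with
  *fewer than* 10 fixes or *less than* 100 m of travel are dropped, so
  a 10-fix, 100-m day survives.
* **Stages**: pre-hunt is March 1 up to the day before the season
  opens; hunt is season start through season end inclusive; post-hunt
  is the day after closing through July 31; records outside March
  1–July 31 are dropped.
* **Standardization** happens after filtering (means and SDs are 0/1 on
  the analysed set, sample SD with $n-1$), square-root transforms are
  applied to the three distance traits only, and the transform metadata
  travels with the table for back-transformation.

## What the generators emulate — and what they do not

`make_landscape()` builds patchy open/forest mosaics by thresholding
smoothed Gaussian noise (patch size set by smoothing passes), straight
road corridors, and access points on roads; 30 m cells by default, the
resolution of common landcover products. `simulate_tracks()` produces
the telemetry duty cycle (hourly 05:00–20:00 plus one midnight roost
fix), per-fix loss with probability `miss_prob`, and Gamma-distributed
DOP with mean 4 and roughly a tenth of its mass above the cleaning
threshold of 7, so the cleaning filter is genuinely exercised. Movement
is a biased correlated random walk anchored to a home centre with
Gamma(2) step lengths averaging `step_scale` metres. Home-range and
step scales are free parameters, not estimates: defaults (150 m hourly
steps on a ~2 km landscape) give plausible spatial autocorrelation and
multi-day home-range fidelity, nothing more. Roosting ecology, habitat
selection, diel activity rhythms and landcover-dependent movement are
*not* modelled — so passing tests demonstrate correctness of the
estimation machinery on data whose generative process is known, not
realism of turkey movement.

`simulate_daily_traits()` draws directly from the DHGLM above with
configurable stage schedule (default season April 10 – May 7, inside the
typical early-April-to-early-May windows of the emulated systems),
alternating two sites, and Binomial(16, 0.92) daily fix counts. Its
defaults mirror a published trait column (stage effects a few tenths of
an SD, $\sigma_\alpha = 0.44$, $\sigma_\omega = 0.34$, $\rho = 0.6$).
`simulate_survival()` links binary survival to the *true* effects
through a logistic model, so attenuation introduced by using estimated
BLUPs downstream is measurable; dead individuals are labelled harvest
vs predation with a configurable fraction.

Validation experiments in the test suite use: 60 individuals × 80 days
(hyperparameter recovery and interval coverage, 20 replicates), 108
individuals × 87 days (end-to-end selection recovery, matching a
published design's sample sizes), 100 × 90 (absence of spurious
predictability variance when $\sigma_\omega = 0$), and 40 × 40 (JAGS
cross-check). These sizes were chosen as the study-realistic designs for
each question.

## Selection analysis: design choices and a known limitation

Per-draw logistic fits are ML (IRLS, tolerance $10^{-8}$) on the draw's
BLUP values directly, with no re-standardization, one covariate at a
time; pooling is over the 2000 per-draw point estimates (median,
equal-tailed 95% interval, PD). Separation — possible in small
mortality subsets — is detected (boundary fitted probabilities,
non-convergence, or |slope| > 15) and flagged; flagged draws are
excluded, and an estimate with more than 10% flagged draws is marked
unreliable. A subset with no deaths yields an all-flagged, `NA`
estimate rather than an error, since that is a legitimate degenerate
design. Per-draw standard errors are retained for diagnostics but kept
out of the headline summary.

**Limitation — the pooled-draw PD is not a calibrated null test.** The
spread of the 2000 per-draw slopes reflects only the posterior
uncertainty of the behavioural estimates; the binomial sampling noise
of the survival outcomes (the dominant error source, since each refit
sees the same outcomes) does not enter it. When individual effects are
estimated precisely — many repeated measures per individual — the
per-draw slopes cluster tightly around whatever the realized
data-level slope happens to be, and PD approaches 100 even when the
true selection gradient is zero. High PD in this framework therefore
certifies that the *sign is robust to behavioural-measurement
uncertainty*, not that it is robust to sampling variation in survival;
the credible interval of the pooled slopes must be read the same way.
The end-to-end tests document both faces: a simulated +1.5 slope on
predictability is recovered with PD > 97.5 essentially always, while a
null slope also produces PD ≥ 89 far more often than a calibrated test
would. Users wanting a frequency-calibrated test should pair the pooled
estimate with, for example, the per-draw Wald intervals or a posterior
predictive check on survival.

With posterior uncertainty sent to zero (all draws identical) the
pooled estimate collapses, by construction, to the single ML slope with
a zero-width interval — the classical estimate is nested as a special
case.

## Reproducibility

Every generator and the sampler take explicit seeds; pipeline stages
derive their seeds deterministically from one master seed
(`derive_seed()`), so whole runs are byte-identical under a fixed
configuration. Chains use R's RNG, so results are reproducible across
platforms with the same R version.
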