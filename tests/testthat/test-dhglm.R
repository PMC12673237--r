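one_obs_data <- function(y = 0, n_fixes = 12) {
  data.frame(id = "a", stage = "pre-hunt", site = "A",
             n_fixes = n_fixes, y = y)
}

test_that("joint log density reproduces closed-form single-point values", {
  p0 <- dhglm_params(beta = c(intercept = 0, hunt = 0, posthunt = 0,
                              site = 0, fixes = 0),
                     gamma = c(intercept = 0, hunt = 0, posthunt = 0,
                               site = 0, fixes = 0),
                     sigma_alpha = 0, sigma_omega = 0, rho = 0)
  a <- c(a = 0); o <- c(a = 0)
  # standard-normal point
  expect_equal(dhglm_log_density(p0, a, o, one_obs_data()),
               -0.5 * log(2 * pi))
  expect_equal(round(dhglm_log_density(p0, a, o, one_obs_data()), 4),
               -0.9189)
  # doubling the residual SD through the dispersion intercept
  p2 <- dhglm_params(beta = p0$beta,
                     gamma = c(intercept = log(2), hunt = 0, posthunt = 0,
                               site = 0, fixes = 0),
                     sigma_alpha = 0, sigma_omega = 0, rho = 0)
  expect_equal(dhglm_log_density(p2, a, o, one_obs_data()),
               -0.5 * log(2 * pi) - log(2))
  # non-finite inputs rejected
  expect_error(dhglm_log_density(p0, a, o, one_obs_data(y = NaN)),
               "non-finite")
})

test_that("split Rhat flags mixing failures and degenerate chains", {
  set.seed(10)
  # two i.i.d. chains from the same distribution
  draws <- cbind(theta = rnorm(2000))
  chain <- rep(1:2, each = 1000)
  expect_lt(abs(rhat(draws, chain = chain)[["theta"]] - 1), 0.05)

  # chains centred 10 apart
  bad <- cbind(theta = c(rnorm(1000), rnorm(1000, 10)))
  expect_gt(rhat(bad, chain = chain)[["theta"]], 3)

  # identical constant chains: non-computable
  const <- cbind(theta = rep(1.5, 2000))
  expect_true(is.na(rhat(const, chain = chain)[["theta"]]))
})

test_that("posterior summaries apply the PD and significance rules", {
  # 1780 of 2000 draws positive: PD exactly 89, significant despite a
  # CrI spanning zero
  set.seed(11)
  x <- c(runif(1780, 0.01, 2), runif(220, -2, -0.01))
  s <- summarize_draws(x)
  expect_equal(s$pd, 89)
  expect_lt(s$lower, 0)
  expect_true(s$significant)

  # all draws positive: PD 100 and CrI excludes zero
  s2 <- summarize_draws(abs(x))
  expect_equal(s2$pd, 100)
  expect_gt(s2$lower, 0)
  expect_true(s2$significant)

  # symmetric draws: PD 50, not significant
  s3 <- summarize_draws(c(x, -x))
  expect_equal(s3$pd, 50)
  expect_false(s3$significant)

  # PD invariant to draw order; CrI monotone in the credible level
  expect_equal(prob_direction(sample(x)), prob_direction(x))
  lv <- sapply(c(0.5, 0.8, 0.95), function(l) {
    s <- summarize_draws(x, level = l); c(s$lower, s$upper)
  })
  expect_true(all(diff(lv[1, ]) < 0) && all(diff(lv[2, ]) > 0))
})

test_that("MCMC configuration arithmetic matches the chain identity", {
  cfg <- mcmc_config()
  expect_equal(cfg$retained, 2 * (15300 - 300) / 15)
  expect_equal(mcmc_config(iterations = 2000, burnin = 500, thin = 5,
                           chains = 2)$retained, 600)
  expect_error(mcmc_config(iterations = 100, burnin = 200), "iterations")
})

test_that("fit recovers structure on a small simulated trait", {
  sim <- small_sim(n_ind = 25, days = 40, seed = 21,
                   sigma_alpha = 0.5, sigma_omega = 0.3, rho = 0.6)
  fit <- suppressWarnings(fit_dhglm(sim$traits, "y",
                                    fast_config(seed = 31)))
  expect_s3_class(fit, "dhglm_fit")
  expect_equal(nrow(fit$draws), fit$config$retained)
  expect_true(all(is.finite(fit$draws)))
  expect_true(all(abs(fit$draws[, "rho"]) <= 1))
  s <- summarize_draws(fit, pars = c("sigma_alpha", "sigma_omega", "rho"))
  expect_gt(s$median[1], 0.25)  # clear among-individual variance
  expect_gt(s$median[3], 0)     # syndrome sign recovered

  # BLUP extraction: aligned draws, known ids only
  bl <- extract_blups(fit)
  expect_equal(dim(bl$alpha), c(fit$config$retained, 25))
  expect_identical(colnames(bl$omega), fit$ids)
  expect_error(extract_blups(fit, ids = "nobody"), "nobody")

  # an individual with an extreme positive mean ranks highest
  d2 <- sim$traits
  d2$y[d2$id == "ind007"] <- d2$y[d2$id == "ind007"] + 3
  fit2 <- suppressWarnings(fit_dhglm(d2, "y", fast_config(seed = 32)))
  am <- colMeans(extract_blups(fit2)$alpha)
  expect_equal(names(which.max(am)), "ind007")

  # derived posteriors respect their ranges
  R <- repeatability(fit); cvp <- cv_p(fit); syn <- syndrome(fit)
  expect_true(all(R$draws >= 0 & R$draws <= 1))
  expect_true(all(cvp$draws >= 0))
  expect_true(abs(syn$median) <= 1)
  # Jensen gap: both CVp conventions reported and close
  expect_lt(abs(cvp$at_median - cvp$median), 0.02)

  expect_error(fit_dhglm(sim$traits[1:3, ], "y", fast_config()),
               "at least 2 individuals")
})

test_that("no spurious predictability variance under a homogeneous dispersion", {
  # sigma_omega = 0: every individual shares one residual SD, so the
  # fitted CVp must collapse towards zero and the individual means shrink
  p <- dhglm_params(sigma_alpha = 0.4, sigma_omega = 0, rho = 0)
  sim <- simulate_daily_traits(p, 100, 90, seed = 41)
  fit <- suppressWarnings(fit_dhglm(sim$traits, "y",
                                    fast_config(seed = 42, iterations = 2000)))
  expect_lt(cv_p(fit)$median, 0.1)

  # sigma_alpha = 0 as well: prior-dominated alphas shrink toward zero
  p0 <- dhglm_params(sigma_alpha = 0, sigma_omega = 0, rho = 0)
  sim0 <- simulate_daily_traits(p0, 40, 60, seed = 43)
  fit0 <- suppressWarnings(fit_dhglm(sim0$traits, "y",
                                     fast_config(seed = 44)))
  expect_lt(mean(abs(colMeans(extract_blups(fit0)$alpha))), 0.05)
  expect_lt(cv_p(fit0)$median, 0.1)
})

test_that("posterior agrees with an independent JAGS implementation", {
  library(rjags)
  p <- dhglm_params(sigma_alpha = 0.5, sigma_omega = 0.3, rho = 0.6)
  sim <- simulate_daily_traits(p, 40, 40, seed = 5)
  d <- sim$traits
  fit <- suppressWarnings(fit_dhglm(d, "y",
                                    mcmc_config(iterations = 4000,
                                                burnin = 1000, thin = 3,
                                                chains = 2, seed = 9)))
  mine <- summarize_draws(fit, pars = c("sigma_alpha", "sigma_omega", "rho"))

  ids <- sort(unique(d$id)); idx <- match(d$id, ids)
  X <- cbind(1, d$stage == "hunt", d$stage == "post-hunt", d$site == "B",
             d$n_fixes - mean(d$n_fixes))
  model <- "
  model {
    for (j in 1:N) {
      mu[j] <- inprod(X[j,], beta) + alpha[id[j]]
      lsd[j] <- inprod(X[j,], gamma) + omega[id[j]]
      y[j] ~ dnorm(mu[j], exp(-2*lsd[j]))
    }
    for (i in 1:Q) {
      omega[i] ~ dnorm(0, 1/(so*so))
      alpha[i] ~ dnorm(rho*(sa/so)*omega[i], 1/(sa*sa*(1-rho*rho)))
    }
    for (k in 1:P) { beta[k] ~ dnorm(0, 0.01); gamma[k] ~ dnorm(0, 0.01) }
    sa ~ dt(0, 1/(2.5*2.5), 3) T(0,)
    so ~ dt(0, 1/(2.5*2.5), 3) T(0,)
    rho ~ dunif(-1, 1)
  }"
  jm <- rjags::jags.model(textConnection(model),
                          data = list(y = d$y, X = X, id = idx, N = nrow(d),
                                      Q = length(ids), P = ncol(X)),
                          n.chains = 2, n.adapt = 1000, quiet = TRUE)
  update(jm, 2000, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("sa", "so", "rho"), n.iter = 6000,
                              thin = 3, progress.bar = "none")
  jq <- summary(samp)$quantiles
  expect_equal(mine$median[mine$parameter == "sigma_alpha"],
               jq["sa", "50%"], tolerance = 0.05)
  expect_equal(mine$median[mine$parameter == "sigma_omega"],
               jq["so", "50%"], tolerance = 0.05)
  expect_equal(mine$median[mine$parameter == "rho"],
               jq["rho", "50%"], tolerance = 0.08)
})
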