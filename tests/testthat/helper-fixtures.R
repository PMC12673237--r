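# shared fixtures, built in code

tiny_landscape <- function(seed = 11, width = 20, height = 20, ...) {
  make_landscape(width, height, cell_size = 30, open_fraction = 0.3,
                 n_roads = 2, n_access = 3, seed = seed, ...)
}

# brute-force Euclidean distance to the nearest TRUE cell (centre to
# centre, metres); the O(cells x features) oracle for distance_raster
brute_distance <- function(mask, cell_size) {
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask)))
    out[r, c] <- min(sqrt((idx[, 1] - r)^2 + (idx[, 2] - c)^2)) * cell_size
  out
}

# independently coded joint log density: pointwise normal logpdfs plus a
# conditional-decomposition bivariate normal (different route than the
# package's quadratic-form implementation)
oracle_log_density <- function(beta, gamma, alpha, omega, sa, so, rho,
                               X, y, idx) {
  mu <- as.numeric(X %*% beta) + alpha[idx]
  sdv <- exp(as.numeric(X %*% gamma) + omega[idx])
  ll <- sum(vapply(seq_along(y),
                   function(j) dnorm(y[j], mu[j], sdv[j], log = TRUE), 0))
  for (i in seq_along(alpha)) {
    ll <- ll + dnorm(alpha[i], 0, sa, log = TRUE) +
      dnorm(omega[i], rho * (so / sa) * alpha[i],
            so * sqrt(1 - rho^2), log = TRUE)
  }
  ll
}

# quick daily-trait simulation for fit-based tests
small_sim <- function(n_ind = 20, days = 30, seed = 3, ...) {
  p <- dhglm_params(...)
  simulate_daily_traits(p, n_ind, days, seed = seed)
}

fast_config <- function(seed = 1, iterations = 1500, burnin = 500,
                        thin = 5, chains = 2) {
  mcmc_config(iterations = iterations, burnin = burnin, thin = thin,
              chains = chains, seed = seed)
}
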