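#' Derive a stage-specific seed from a master seed
#'
#' Every stochastic stage of a pipeline run receives its own seed, derived
#' deterministically from the master seed and a stage label, so that stages
#' can be re-run independently and whole runs are reproducible.
#'
#' @param master integer master seed.
#' @param stage character label of the stage (e.g. `"tracks"`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  # modular arithmetic in double precision; operands stay below 2^52
  s <- (abs(master) %% 2147483647) * 69621 + h * 7919 + 1
  as.integer(s %% 2147483646 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Probability of direction of a posterior sample
#'
#' The percentage of draws sharing the sign of the posterior median,
#' reported on the 50--100 scale. A sample whose median is exactly zero is
#' reported as 50.
#'
#' @param x numeric vector of posterior draws.
#' @return A single number in `[50, 100]`.
#' @export
prob_direction <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  if (median(x) == 0) return(50)
  100 * max(mean(x > 0), mean(x < 0))
}

#' Closed-form coefficient of variation in predictability
#'
#' Converts the among-individual standard deviation of the dispersion-model
#' random intercepts (log-SD scale) into the population-level coefficient of
#' variation of the individual residual SDs: `CVp = sqrt(exp(sigma_omega^2) - 1)`.
#' This is the coefficient of variation of a log-normal variable with log-scale
#' SD `sigma_omega`.
#'
#' @param sigma_omega non-negative SD of individual dispersion intercepts.
#' @return CVp on the same scale as the individual residual SDs (unitless).
#' @export
#' @examples
#' cvp_closed_form(0.3)
cvp_closed_form <- function(sigma_omega) {
  stopifnot(is.numeric(sigma_omega), all(sigma_omega >= 0 | is.na(sigma_omega)))
  sqrt(exp(sigma_omega^2) - 1)
}

# equal-tailed credible interval, type-7 quantiles
cri <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  unname(quantile(x, c(a, 1 - a), type = 7, names = FALSE))
}

# significance per the CrI-or-PD rule: CrI excludes 0 OR PD >= pd_cut
is_significant <- function(lo, hi, pd, pd_cut = 89) {
  (lo > 0 | hi < 0) | (pd >= pd_cut)
}
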