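#' Simulate binary survival linked to true individual effects
#'
#' Each individual survives the season with probability
#' `plogis(intercept + slope_alpha * alpha_i + slope_omega * omega_i)`,
#' so selection acts on the *true* behavioural type and predictability, not
#' on their estimates; attenuation introduced downstream by estimation is
#' therefore measurable. Dead individuals are assigned a mortality source:
#' `harvest` with probability `harvest_fraction`, otherwise `predation`.
#'
#' @param effects a `true_effects` object from [simulate_daily_traits()].
#' @param intercept baseline survival log-odds.
#' @param slope_alpha log-odds change per unit of the mean-model individual
#'   effect (behavioural type).
#' @param slope_omega log-odds change per unit of the dispersion-model
#'   individual effect (rIIV / predictability).
#' @param harvest_fraction probability a death is a harvest, in `[0, 1]`.
#' @param seed integer seed.
#' @return A survival table: data frame with `id`, `outcome`
#'   (1 = survived, 0 = dead) and `source` (`none`/`harvest`/`predation`).
#' @export
simulate_survival <- function(effects, intercept = 0, slope_alpha = 0,
                              slope_omega = 0, harvest_fraction = 0.6,
                              seed = 1) {
  stopifnot(inherits(effects, "true_effects"))
  if (harvest_fraction < 0 || harvest_fraction > 1)
    stop("harvest_fraction must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  ids <- names(effects$alpha)
  p <- plogis(intercept + slope_alpha * effects$alpha +
                slope_omega * effects$omega)
  outcome <- rbinom(length(p), 1, p)
  source <- ifelse(outcome == 1, "none",
                   ifelse(runif(length(p)) < harvest_fraction,
                          "harvest", "predation"))
  data.frame(id = ids, outcome = outcome, source = source,
             row.names = NULL)
}

#' Deterministic survival table with fixed group sizes
#'
#' Builds a survival table with exact survivor / harvested / predated
#' counts, useful for reproducing a study's design structure in tests and
#' examples. Defaults give the 64 / 27 / 17 composition (108 individuals,
#' 44 dead) of a published hunted-bird dataset.
#'
#' @param n_survived,n_harvested,n_predated group sizes.
#' @return A survival table as in [simulate_survival()].
#' @export
survival_design <- function(n_survived = 64, n_harvested = 27,
                            n_predated = 17) {
  n <- n_survived + n_harvested + n_predated
  data.frame(
    id = sprintf("ind%03d", seq_len(n)),
    outcome = rep(c(1L, 0L), c(n_survived, n_harvested + n_predated)),
    source = rep(c("none", "harvest", "predation"),
                 c(n_survived, n_harvested, n_predated))
  )
}
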