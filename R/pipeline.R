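#' Default pipeline configuration
#'
#' A complete, reproducible configuration for an end-to-end synthetic run:
#' landscape generation, track simulation, preprocessing, per-trait
#' model fits and selection analysis. Every stochastic stage derives its
#' seed deterministically from the single master `seed`. Values can be
#' overridden by a nested list or loaded from YAML with
#' [read_run_config()].
#'
#' @param seed master seed.
#' @param ... named overrides of top-level sections (merged shallowly).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    landscape = list(width = 60, height = 60, cell_size = 30,
                     open_fraction = 0.3, n_roads = 2, n_access = 4),
    tracks = list(n_individuals = 25, start_date = "2022-03-01",
                  n_days = 120, miss_prob = 0.08, step_scale = 150),
    season = list(hunt_start = "2022-04-10", hunt_end = "2022-05-07"),
    filters = list(dop_max = 7, min_fixes = 10, min_path = 100),
    survival = list(trait = "dist_open", intercept = 0.4,
                    slope_type = 0.5, slope_riiv = 1, harvest_fraction = 0.6),
    mcmc = list(iterations = 3000, burnin = 500, thin = 5, chains = 2),
    traits = c("dist_open", "dist_edge", "dist_access", "speed")
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param file YAML path.
#' @param config a `run_config`.
#' @return `read_run_config()` a `run_config`; `write_run_config()` the
#'   path, invisibly.
#' @export
read_run_config <- function(file) {
  raw <- yaml::read_yaml(file)
  if (is.null(raw$seed)) stop("config must set a seed")
  do.call(run_config, c(list(seed = raw$seed),
                        raw[setdiff(names(raw), "seed")]))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' Run the full synthetic analysis pipeline
#'
#' Generates a landscape and GPS tracks, cleans and truncates the fixes,
#' computes daily behavioural metrics, assigns hunting stages, filters
#' low-information days, standardizes the four traits, fits the
#' double-hierarchical model per trait, and estimates selection on
#' behavioural types and predictability for harvest, predation and pooled
#' mortality. Survival is simulated from each individual's realized
#' behaviour (standardized mean and log residual SD of the configured
#' trait), so selection signal flows through the whole pipeline. All
#' outputs are written as CSV (plus a JSON manifest) under `outdir` when
#' given; identical configurations produce identical outputs.
#'
#' @param config a `run_config` (or YAML path).
#' @param outdir optional output directory.
#' @return A `run_artifacts` list: `daily`, `model_input`, `fits`,
#'   `summaries`, `selection`, `rhat`, `survival`, `dropped`, `config`.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  dropped <- list()

  land <- do.call(make_landscape,
                  c(config$landscape, seed = derive_seed(seed, "landscape")))
  fixes <- do.call(simulate_tracks,
                   c(list(landscape = land), config$tracks,
                     seed = derive_seed(seed, "tracks")))

  n0 <- nrow(fixes)
  fixes <- clean_fixes(fixes, dop_max = config$filters$dop_max)
  dropped$dop_cleaning <- n0 - nrow(fixes)

  grids <- list(open = distance_raster(land, "open"),
                edge = distance_raster(land, "edge"),
                access = distance_raster(land, "access"))

  daily_all <- daily_metrics(fixes, grids)
  surv <- behaviour_survival(daily_all, config$survival,
                             derive_seed(seed, "survival"))

  dd <- death_dates_for(surv, config$season, derive_seed(seed, "deaths"))
  n0 <- nrow(fixes)
  fixes <- truncate_to_alive(fixes, surv, dd)
  dropped$death_truncation <- n0 - nrow(fixes)

  daily <- daily_metrics(fixes, grids)
  ids <- sort(unique(daily$id))
  sites <- setNames(rep(c("A", "B"), length.out = length(ids)), ids)
  n0 <- nrow(daily)
  daily <- assign_stage(daily, config$season, sites)
  dropped$outside_window <- n0 - nrow(daily)
  n0 <- nrow(daily)
  daily <- filter_days(daily, config$filters$min_fixes,
                       config$filters$min_path)
  dropped$day_filters <- n0 - nrow(daily)

  mi <- transform_standardize(daily)
  mcfg <- do.call(mcmc_config,
                  c(config$mcmc, seed = derive_seed(seed, "mcmc")))

  # individuals whose whole record was truncated or filtered away carry no
  # behavioural estimates and cannot enter the survival refits
  surv_use <- surv[surv$id %in% unique(mi$id), , drop = FALSE]

  fits <- list(); summaries <- list(); selection <- list(); rhats <- list()
  for (tr in config$traits) {
    fit <- fit_dhglm(mi, trait = tr, config = mcfg)
    fits[[tr]] <- fit
    summaries[[tr]] <- trait_summary(fit)
    rhats[[tr]] <- data.frame(trait = tr, parameter = names(fit$rhat),
                              rhat = unname(fit$rhat), row.names = NULL)
    blups <- extract_blups(fit)
    for (kind in c("type", "rIIV"))
      for (src in c("harvest", "predation", "pooled"))
        selection[[paste(tr, kind, src)]] <-
          iterate_selection(blups, surv_use, kind, src, trait = tr)
  }
  summaries <- do.call(rbind, summaries)
  selection <- do.call(rbind, selection)
  rhats <- do.call(rbind, rhats)
  rownames(summaries) <- rownames(selection) <- rownames(rhats) <- NULL
  dropped <- data.frame(rule = names(dropped),
                        n_dropped = unlist(dropped), row.names = NULL)

  art <- structure(list(daily = daily, model_input = mi, fits = fits,
                        summaries = summaries, selection = selection,
                        rhat = rhats, survival = surv, dropped = dropped,
                        config = config),
                   class = "run_artifacts")
  if (!is.null(outdir)) write_artifacts(art, outdir)
  art
}

# survival simulated from realized behaviour: standardized per-individual
# mean (behavioural type proxy) and log residual SD (predictability proxy)
behaviour_survival <- function(daily, scfg, seed) {
  v <- daily[[scfg$trait]]
  if (scfg$trait != "speed") v <- sqrt(v)
  m_i <- tapply(v, daily$id, mean)
  s_i <- tapply(v, daily$id, function(x) max(sd(x), 1e-6))
  z_m <- as.numeric(scale(m_i))
  z_s <- as.numeric(scale(log(s_i)))
  eff <- structure(list(alpha = setNames(z_m, names(m_i)),
                        omega = setNames(z_s, names(m_i)),
                        sigma_alpha = 1, sigma_omega = 1, rho = cor(z_m, z_s)),
                   class = "true_effects")
  simulate_survival(eff, intercept = scfg$intercept,
                    slope_alpha = scfg$slope_type,
                    slope_omega = scfg$slope_riiv,
                    harvest_fraction = scfg$harvest_fraction, seed = seed)
}

# death dates: harvests during the hunting season, predations anywhere in
# the March-July window
death_dates_for <- function(surv, season, seed) {
  set.seed(seed)
  dead <- surv[surv$outcome == 0, , drop = FALSE]
  hs <- as.Date(season$hunt_start); he <- as.Date(season$hunt_end)
  yr <- format(hs, "%Y")
  lo <- as.Date(paste0(yr, "-03-01")); hi <- as.Date(paste0(yr, "-07-31"))
  dt <- ifelse(dead$source == "harvest",
               hs + sample.int(as.integer(he - hs) + 1L, nrow(dead),
                               replace = TRUE) - 1L,
               lo + sample.int(as.integer(hi - lo) + 1L, nrow(dead),
                               replace = TRUE) - 1L)
  data.frame(id = dead$id, death_date = as.Date(dt, origin = "1970-01-01"))
}

# tidy per-trait summary in published-table layout: mean-model fixed
# effects, dispersion fixed effects, variance components, repeatability,
# CVp, syndrome correlation
trait_summary <- function(fit) {
  fx <- summarize_draws(fit, pars = grep("^(beta|gamma)_",
                                         colnames(fit$draws), value = TRUE))
  fx$section <- ifelse(grepl("^beta_", fx$parameter),
                       "mean fixed effects", "dispersion fixed effects")
  vc <- summarize_draws(fit, pars = c("sigma_alpha", "sigma_omega"))
  vc$section <- "random effects"
  der <- do.call(rbind, lapply(
    list(repeatability(fit), cv_p(fit), syndrome(fit)),
    function(d) data.frame(parameter = d$name, median = d$median,
                           lower = d$lower, upper = d$upper, pd = d$pd,
                           significant = is_significant(d$lower, d$upper,
                                                        d$pd))))
  der$section <- "derived"
  out <- rbind(fx, vc, der)
  out <- data.frame(trait = fit$trait, section = out$section,
                    out[, c("parameter", "median", "lower", "upper", "pd",
                            "significant")])
  rownames(out) <- NULL
  out
}

write_artifacts <- function(art, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(outdir, f)
  write.csv(art$daily, pth("daily_traits.csv"), row.names = FALSE)
  write_model_input(art$model_input, pth("model_input.csv"),
                    pth("transforms.json"))
  write.csv(art$summaries, pth("trait_summaries.csv"), row.names = FALSE)
  write.csv(art$selection, pth("selection_estimates.csv"), row.names = FALSE)
  write.csv(art$rhat, pth("rhat.csv"), row.names = FALSE)
  write.csv(art$survival, pth("survival.csv"), row.names = FALSE)
  write.csv(art$dropped, pth("dropped_records.csv"), row.names = FALSE)
  manifest <- list(config = unclass(art$config),
                   package_version = as.character(utils::packageVersion("behavpred")),
                   r_version = R.version.string,
                   n_individuals = length(unique(art$daily$id)),
                   n_days = nrow(art$daily))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' Human-readable pipeline report
#'
#' Prints convergence diagnostics, the derived per-trait statistics and
#' the selection table, flagging significance by the credible-interval /
#' probability-of-direction rule and spelling out the sign convention
#' (positive log-odds ratio: larger values associated with higher
#' survival).
#'
#' @param artifacts a `run_artifacts` from [run_pipeline()].
#' @return The artifacts, invisibly.
#' @export
report <- function(artifacts) {
  stopifnot(inherits(artifacts, "run_artifacts"))
  a <- artifacts
  cat("== pipeline report ==\n")
  cat(sprintf("individuals: %d, analysed days: %d\n",
              length(unique(a$daily$id)), nrow(a$daily)))
  cat("records dropped:\n")
  for (i in seq_len(nrow(a$dropped)))
    cat(sprintf("  %-18s %d\n", a$dropped$rule[i], a$dropped$n_dropped[i]))
  conv <- vapply(a$fits, function(f) f$converged, TRUE)
  cat(sprintf("converged fits: %d/%d (Rhat < 1.1)\n", sum(conv), length(conv)))
  cat("\nderived statistics per trait:\n")
  der <- a$summaries[a$summaries$section == "derived", ]
  for (i in seq_len(nrow(der)))
    cat(sprintf("  %-12s %-14s %6.3f [%6.3f, %6.3f]%s\n",
                der$trait[i], der$parameter[i], der$median[i], der$lower[i],
                der$upper[i], ifelse(der$significant[i], " *", "")))
  cat("\nselection (log-odds ratios; positive = higher survival for larger values):\n")
  s <- a$selection
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %-5s %-10s %6.2f [%6.2f, %6.2f] PD %5.1f%%%s%s\n",
                s$trait[i], s$blup_kind[i], s$source[i], s$median[i],
                s$lower[i], s$upper[i], s$pd[i],
                ifelse(s$significant[i], " *", ""),
                ifelse(s$unreliable[i], " (unreliable)", "")))
  invisible(artifacts)
}
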