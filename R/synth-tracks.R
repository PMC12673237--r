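#' Simulate GPS tracks over a landscape
#'
#' Generates hourly diurnal fixes (05:00--20:00) plus one roost fix at
#' midnight per individual-day, mirroring a common wild-bird telemetry
#' duty cycle. Movement follows a biased correlated random walk anchored to
#' a per-individual home centre: step lengths are Gamma-distributed with
#' mean `step_scale`, headings persist and are pulled back towards home,
#' and individuals return to a roost near home overnight. Each scheduled
#' fix is dropped independently with probability `miss_prob`, and every fix
#' carries a dilution-of-precision (DOP) value drawn from a right-skewed
#' Gamma distribution (mean 4), so a realistic minority of fixes exceeds
#' the usual quality threshold of 7.
#'
#' @param landscape a `landscape_grid` bounding the walk.
#' @param n_individuals number of individuals.
#' @param start_date `Date` (or string) of the first tracking day.
#' @param n_days number of tracking days per individual.
#' @param miss_prob per-fix probability of a missed fix (`< 1`).
#' @param dop_shape Gamma shape of the DOP distribution (mean fixed at 4).
#' @param step_scale mean hourly step length, metres.
#' @param seed integer seed.
#' @return A fix table: data frame with columns `id`, `timestamp`
#'   (POSIXct, UTC), `x`, `y` (planar metres), `dop`.
#' @export
simulate_tracks <- function(landscape, n_individuals, start_date, n_days,
                            miss_prob = 0.08, dop_shape = 3,
                            step_scale = 150, seed = 1) {
  stopifnot(inherits(landscape, "landscape_grid"))
  if (n_days < 1) stop("n_days must be at least 1")
  if (miss_prob >= 1) stop("miss_prob must be < 1")
  if (n_individuals < 1) stop("n_individuals must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  start_date <- as.Date(start_date)

  xmax <- ncol(landscape$classes) * landscape$cell_size
  ymax <- nrow(landscape$classes) * landscape$cell_size
  ids <- sprintf("ind%03d", seq_len(n_individuals))
  hours <- c(0L, 5:20)  # midnight roost + diurnal schedule

  out <- vector("list", n_individuals)
  for (i in seq_len(n_individuals)) {
    home <- c(runif(1, 0.2 * xmax, 0.8 * xmax),
              runif(1, 0.2 * ymax, 0.8 * ymax))
    pos <- home
    heading <- runif(1, 0, 2 * pi)
    n_fix_day <- length(hours)
    xs <- ys <- matrix(NA_real_, n_days, n_fix_day)
    for (d in seq_len(n_days)) {
      roost <- reflect_into(home + rnorm(2, 0, 30), xmax, ymax)
      xs[d, 1] <- roost[1]; ys[d, 1] <- roost[2]
      pos <- roost
      for (h in seq_along(5:20)) {
        len <- rgamma(1, shape = 2, rate = 2 / step_scale)
        to_home <- home - pos
        d_home <- sqrt(sum(to_home^2))
        pull <- if (d_home > 0) min(1, d_home / (8 * step_scale)) else 0
        w <- 0.8 * c(cos(heading), sin(heading)) +
          pull * (if (d_home > 0) to_home / d_home else c(0, 0)) +
          0.7 * rnorm(2)
        heading <- atan2(w[2], w[1])
        pos <- reflect_into(pos + len * c(cos(heading), sin(heading)),
                            xmax, ymax)
        xs[d, h + 1] <- pos[1]; ys[d, h + 1] <- pos[2]
      }
    }
    stamps <- rep(start_date + (seq_len(n_days) - 1L), each = n_fix_day)
    stamps <- as.POSIXct(stamps, tz = "UTC") + rep(hours, n_days) * 3600
    keep <- runif(n_days * n_fix_day) >= miss_prob
    out[[i]] <- data.frame(
      id = ids[i],
      timestamp = stamps[keep],
      x = as.vector(t(xs))[keep],
      y = as.vector(t(ys))[keep],
      dop = rgamma(sum(keep), shape = dop_shape, rate = dop_shape / 4)
    )
  }
  fixes <- do.call(rbind, out)
  rownames(fixes) <- NULL
  fixes
}

# reflect a point into [0, xmax] x [0, ymax]
reflect_into <- function(p, xmax, ymax) {
  for (k in 1:2) {
    m <- if (k == 1) xmax else ymax
    while (p[k] < 0 || p[k] > m) {
      if (p[k] < 0) p[k] <- -p[k]
      if (p[k] > m) p[k] <- 2 * m - p[k]
    }
  }
  p
}
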