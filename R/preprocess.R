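#' Remove fixes with inadequate positional quality
#'
#' Retains fixes whose dilution of precision (DOP) is at or below
#' `dop_max`; the conventional cleaning threshold drops fixes with DOP
#' strictly greater than 7. Row order is preserved.
#'
#' @param fixes fix table with a `dop` column.
#' @param dop_max maximum acceptable DOP.
#' @return The filtered fix table.
#' @export
clean_fixes <- function(fixes, dop_max = 7) {
  if (is.null(fixes$dop) || anyNA(fixes$dop))
    stop("all fixes must carry a dop value")
  out <- fixes[fixes$dop <= dop_max, , drop = FALSE]
  if (nrow(out) == 0) warning("no fixes remain after DOP cleaning")
  rownames(out) <- NULL
  out
}

#' Truncate fixes of dead individuals to their alive period
#'
#' Removes all fixes on or after the death date of each individual that
#' did not survive; survivors' fixes are untouched.
#'
#' @param fixes fix table.
#' @param survival survival table (`id`, `outcome`, `source`).
#' @param death_dates data frame with `id` and `death_date` (coercible to
#'   `Date`) covering every dead individual.
#' @return The truncated fix table.
#' @export
truncate_to_alive <- function(fixes, survival, death_dates) {
  dead <- survival$id[survival$outcome == 0]
  missing <- setdiff(dead, death_dates$id)
  if (length(missing) > 0)
    stop("no death date for dead individual(s): ",
         paste(missing, collapse = ", "))
  dd <- as.Date(death_dates$death_date)
  names(dd) <- death_dates$id
  fixdate <- as.Date(fixes$timestamp, tz = "UTC")
  drop <- fixes$id %in% dead & fixdate >= dd[fixes$id]
  out <- fixes[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Daily movement metrics from cleaned fixes
#'
#' Aggregates fixes into one record per individual-day: the number of
#' diurnal fixes, the mean distance to each landscape feature sampled at
#' the fix locations, the total daily path length (sum of consecutive-fix
#' Euclidean steps), and the average hourly speed (total path divided by
#' the 15-hour diurnal collection window).
#'
#' Only the diurnal schedule (05:00--20:00) enters the metrics; the
#' midnight roost fix is excluded, consistent with the 15-hour divisor.
#' When sub-hourly fixes are present they are first thinned to the fix
#' nearest each hour top, so path lengths are comparable across duty
#' cycles. Distance to hunter access can optionally be computed
#' point-exact from the access coordinates instead of sampled from its
#' raster.
#'
#' @param fixes cleaned fix table.
#' @param grids named list of `distance_grid`s: `open`, `edge`, `access`.
#' @param access_points optional data frame (`x`, `y`); when given,
#'   distance to access is the exact minimum point-to-point distance.
#' @return Daily trait table: `id`, `date`, `n_fixes`, `dist_open`,
#'   `dist_edge`, `dist_access`, `total_path`, `speed`.
#' @export
daily_metrics <- function(fixes, grids, access_points = NULL) {
  stopifnot(all(c("open", "edge") %in% names(grids)))
  if (is.null(access_points) && is.null(grids$access))
    stop("provide grids$access or access_points")
  tt <- as.POSIXlt(fixes$timestamp, tz = "UTC")
  offset_min <- tt$min + tt$sec / 60
  hr <- tt$hour + (offset_min >= 30)
  date <- as.Date(fixes$timestamp, tz = "UTC")
  # thin to the fix nearest each hour top within id-date-hour
  off <- pmin(offset_min, 60 - offset_min)
  ord <- order(fixes$id, date, hr, off)
  key <- paste(fixes$id, date, hr)[ord]
  keep <- ord[!duplicated(key)]
  keep <- keep[hr[keep] >= 5 & hr[keep] <= 20]  # diurnal window only

  f <- fixes[keep, , drop = FALSE]
  f$date <- date[keep]
  f <- f[order(f$id, f$timestamp), , drop = FALSE]

  d_open <- sample_distance(grids$open, f$x, f$y)
  d_edge <- sample_distance(grids$edge, f$x, f$y)
  d_acc <- if (!is.null(access_points)) {
    apply(outer(f$x, access_points$x, `-`)^2 +
            outer(f$y, access_points$y, `-`)^2, 1,
          function(r) sqrt(min(r)))
  } else {
    sample_distance(grids$access, f$x, f$y)
  }

  grp <- split(seq_len(nrow(f)), list(f$id, f$date), drop = TRUE)
  recs <- lapply(grp, function(ix) {
    path <- if (length(ix) > 1)
      sum(sqrt(diff(f$x[ix])^2 + diff(f$y[ix])^2)) else 0
    data.frame(id = f$id[ix[1]], date = f$date[ix[1]],
               n_fixes = length(ix),
               dist_open = mean(d_open[ix]), dist_edge = mean(d_edge[ix]),
               dist_access = mean(d_acc[ix]),
               total_path = path, speed = path / 15)
  })
  out <- do.call(rbind, recs)
  out <- out[order(out$id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop low-information days
#'
#' Keeps records with at least `min_fixes` fixes and a total path of at
#' least `min_path` metres. The conventional thresholds exclude days with
#' *fewer than* 10 fixes and days when the individual travelled *less
#' than* 100 m, so equality survives both filters.
#'
#' @param daily daily trait table.
#' @param min_fixes,min_path retention thresholds.
#' @return The filtered table.
#' @export
filter_days <- function(daily, min_fixes = 10, min_path = 100) {
  out <- daily[daily$n_fixes >= min_fixes & daily$total_path >= min_path, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign hunting stages to daily records
#'
#' Labels each record `pre-hunt` (March 1 up to the day before the season
#' opens), `hunt` (season start through season end, inclusive) or
#' `post-hunt` (the day after the season closes through July 31), using the
#' season dates of the record's site and year. Records outside
#' March 1 -- July 31 are dropped.
#'
#' @param daily daily trait table.
#' @param seasons data frame with `site`, `year`, `hunt_start`, `hunt_end`,
#'   or a single list with `hunt_start`/`hunt_end` applied to all site-years.
#' @param sites named character vector mapping `id` to site; not needed if
#'   `daily` already has a `site` column.
#' @return The table with `site` and `stage` columns, out-of-window
#'   records removed.
#' @export
assign_stage <- function(daily, seasons, sites = NULL) {
  if (is.null(daily$site)) {
    if (is.null(sites)) stop("provide a site column or an id-to-site map")
    daily$site <- unname(sites[daily$id])
  }
  yr <- format(as.Date(daily$date), "%Y")
  if (is.data.frame(seasons)) {
    key <- paste(daily$site, yr)
    skey <- paste(seasons$site, seasons$year)
    miss <- unique(key[!key %in% skey])
    if (length(miss) > 0)
      stop("no season definition for site-year: ",
           paste(miss, collapse = ", "))
    m <- match(key, skey)
    hs <- as.Date(seasons$hunt_start)[m]
    he <- as.Date(seasons$hunt_end)[m]
  } else {
    hs <- rep(as.Date(seasons$hunt_start), nrow(daily))
    he <- rep(as.Date(seasons$hunt_end), nrow(daily))
  }
  daily$stage <- stage_of_date_vec(as.Date(daily$date), hs, he)
  out <- daily[!is.na(daily$stage), , drop = FALSE]
  rownames(out) <- NULL
  out
}

stage_of_date_vec <- function(dates, hunt_start, hunt_end) {
  yr <- format(dates, "%Y")
  mar1 <- as.Date(paste0(yr, "-03-01"))
  jul31 <- as.Date(paste0(yr, "-07-31"))
  out <- rep(NA_character_, length(dates))
  out[dates >= mar1 & dates < hunt_start] <- "pre-hunt"
  out[dates >= hunt_start & dates <= hunt_end] <- "hunt"
  out[dates > hunt_end & dates <= jul31] <- "post-hunt"
  out
}

#' Transform and standardize daily traits for model input
#'
#' Applies a square-root transform to the three distance traits (to reduce
#' right skew; average hourly speed is left raw) and z-scores every trait
#' to mean 0, SD 1 (sample SD, n - 1 denominator). The centring and
#' scaling constants and the transform flags are stored as metadata so
#' fitted effects can be back-transformed.
#'
#' @param daily filtered daily trait table with `stage` and `site`.
#' @param traits trait columns to standardize.
#' @param sqrt_traits subset of `traits` to square-root transform first.
#' @return A `model_input` data frame (`id`, `date`, `stage`, `site`,
#'   `n_fixes`, standardized trait columns) with a `transforms` attribute.
#' @export
transform_standardize <- function(daily,
                                  traits = c("dist_open", "dist_edge",
                                             "dist_access", "speed"),
                                  sqrt_traits = c("dist_open", "dist_edge",
                                                  "dist_access")) {
  if (nrow(daily) == 0) stop("no records to standardize")
  stopifnot(all(traits %in% names(daily)), all(sqrt_traits %in% traits))
  out <- daily[, intersect(c("id", "date", "stage", "site", "n_fixes"),
                           names(daily)), drop = FALSE]
  meta <- data.frame(trait = traits, sqrt = traits %in% sqrt_traits,
                     center = NA_real_, scale = NA_real_)
  for (k in seq_along(traits)) {
    v <- daily[[traits[k]]]
    if (meta$sqrt[k]) v <- sqrt(v)
    s <- sd(v)
    if (!is.finite(s) || s == 0)
      stop(sprintf("trait '%s' has zero variance; cannot standardize",
                   traits[k]))
    meta$center[k] <- mean(v); meta$scale[k] <- s
    out[[traits[k]]] <- (v - meta$center[k]) / s
  }
  attr(out, "transforms") <- meta
  class(out) <- c("model_input", class(out))
  out
}

#' Write / read a model-input table with its transform metadata
#'
#' The table is written as CSV and the transform metadata (sqrt flags,
#' centring means, scaling SDs) as a JSON sidecar.
#'
#' @param mi a `model_input` table.
#' @param csv_file,json_file output paths.
#' @return `write_model_input()` returns the paths invisibly;
#'   `read_model_input()` returns the restored `model_input`.
#' @export
write_model_input <- function(mi, csv_file, json_file) {
  stopifnot(inherits(mi, "model_input"))
  write.csv(as.data.frame(mi), csv_file, row.names = FALSE)
  jsonlite::write_json(attr(mi, "transforms"), json_file, digits = NA)
  invisible(c(csv = csv_file, json = json_file))
}

#' @rdname write_model_input
#' @export
read_model_input <- function(csv_file, json_file) {
  out <- read.csv(csv_file)
  out$date <- as.Date(out$date)
  attr(out, "transforms") <- as.data.frame(jsonlite::read_json(
    json_file, simplifyVector = TRUE))
  class(out) <- c("model_input", class(out))
  out
}
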