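make_fix <- function(id, date, hour, x, y, dop = 1) {
  data.frame(id = id,
             timestamp = as.POSIXct(paste0(date, " ", sprintf("%02d", hour),
                                           ":00:00"), tz = "UTC"),
             x = x, y = y, dop = dop)
}

test_that("DOP cleaning keeps the boundary and drops above it", {
  fx <- do.call(rbind, lapply(1:4, function(i)
    make_fix("a", "2022-03-01", 4 + i, i * 10, 0,
             dop = c(1, 7, 7.1, 12)[i])))
  out <- clean_fixes(fx)
  expect_equal(out$dop, c(1, 7))

  # identity when all DOP fine
  fx$dop <- 1
  expect_equal(clean_fixes(fx), fx)

  # count check on a mixed table
  set.seed(1)
  dop <- c(runif(87, 0.5, 7), runif(13, 7.01, 15))[sample(100)]
  fx100 <- make_fix("a", "2022-03-01", 5, 1:100, 0, dop = dop)
  expect_equal(nrow(clean_fixes(fx100)), 87)
  expect_warning(clean_fixes(transform(fx100, dop = 99)), "no fixes")
  expect_error(clean_fixes(transform(fx100, dop = NULL)), "dop")
})

test_that("truncation to the alive period matches a brute-force date filter", {
  set.seed(2)
  days <- as.Date("2022-03-01") + 0:19
  fx <- do.call(rbind, lapply(c("a", "b", "c"), function(id)
    do.call(rbind, lapply(days, function(d)
      make_fix(id, d, sample(5:20, 1), runif(1, 0, 100), runif(1, 0, 100))))))
  surv <- data.frame(id = c("a", "b", "c"), outcome = c(1, 0, 0),
                     source = c("none", "harvest", "predation"))
  dd <- data.frame(id = c("b", "c"),
                   death_date = as.Date(c("2022-03-10", "2022-03-01")))
  out <- truncate_to_alive(fx, surv, dd)
  keep <- !(fx$id == "b" & as.Date(fx$timestamp) >= as.Date("2022-03-10")) &
    fx$id != "c"  # c's death date equals its first fix date: zero fixes
  expect_equal(out, `rownames<-`(fx[keep, ], NULL))
  expect_false("c" %in% out$id)
  # survivor untouched
  expect_equal(sum(out$id == "a"), 20)
  # dead individual without a death date is a rejection
  expect_error(truncate_to_alive(fx, surv, dd[1, ]), "c")
})

test_that("daily metrics: straight-line arithmetic and single-fix days", {
  l <- make_landscape(50, 50, open_fraction = 0.3, n_roads = 2, n_access = 3,
                      seed = 4)
  grids <- list(open = distance_raster(l, "open"),
                edge = distance_raster(l, "edge"),
                access = distance_raster(l, "access"))
  # 15 hourly fixes on a straight line spaced 100 m
  fx <- do.call(rbind, lapply(1:15, function(i)
    make_fix("a", "2022-03-05", 4 + i, 15 + (i - 1) * 100, 615)))
  dm <- daily_metrics(fx, grids)
  expect_equal(dm$n_fixes, 15)
  expect_equal(dm$total_path, 1400)
  expect_equal(dm$speed, 1400 / 15)
  expect_equal(dm$speed, 93.3333, tolerance = 1e-4)

  # single-fix day: distances from the grid cell, zero path
  single <- make_fix("a", "2022-03-06", 9, 15 + 7 * 30, 15 + 3 * 30)
  dm1 <- daily_metrics(single, grids)
  expect_equal(dm1$n_fixes, 1)
  expect_equal(dm1$total_path, 0)
  expect_equal(dm1$dist_open, grids$open$dist[4, 8])
  expect_equal(dm1$dist_edge, grids$edge$dist[4, 8])

  # the midnight roost fix is excluded from the metrics
  with_roost <- rbind(make_fix("a", "2022-03-05", 0, 1400, 1400), fx)
  expect_equal(daily_metrics(with_roost, grids), dm)

  # fix outside the grid is rejected with coordinates
  expect_error(daily_metrics(make_fix("a", "2022-03-07", 9, 1e5, 0), grids),
               "outside")
})

test_that("daily metrics equal an independent recomputation on random days", {
  l <- tiny_landscape(seed = 5, width = 40, height = 40)
  grids <- list(open = distance_raster(l, "open"),
                edge = distance_raster(l, "edge"),
                access = distance_raster(l, "access"))
  fx <- simulate_tracks(l, 4, "2022-03-01", 6, miss_prob = 0.15, seed = 6)
  dm <- daily_metrics(fx, grids)

  # oracle: plain-loop recomputation from raw arrays
  hrs <- as.POSIXlt(fx$timestamp, tz = "UTC")$hour
  diurnal <- fx[hrs >= 5 & hrs <= 20, ]
  diurnal$date <- as.Date(diurnal$timestamp, tz = "UTC")
  for (i in seq_len(nrow(dm))) {
    g <- diurnal[diurnal$id == dm$id[i] & diurnal$date == dm$date[i], ]
    g <- g[order(g$timestamp), ]
    expect_equal(dm$n_fixes[i], nrow(g))
    path <- if (nrow(g) > 1)
      sum(sqrt(diff(g$x)^2 + diff(g$y)^2)) else 0
    expect_equal(dm$total_path[i], path)
    expect_equal(dm$speed[i], path / 15)
    rr <- ceiling(g$y / 30); cc <- ceiling(g$x / 30)
    expect_equal(dm$dist_open[i], mean(grids$open$dist[cbind(rr, cc)]))
  }

  # order stability: permuting input rows leaves every record unchanged
  set.seed(7)
  dm2 <- daily_metrics(fx[sample(nrow(fx)), ], grids)
  expect_equal(dm2, dm)
})

test_that("day filters use strict 'fewer than'/'less than' semantics", {
  daily <- data.frame(id = "a", date = as.Date("2022-03-01") + 0:2,
                      n_fixes = c(9, 10, 12),
                      total_path = c(500, 99, 100))
  out <- filter_days(daily)
  expect_equal(nrow(out), 1)
  expect_equal(out$n_fixes, 12)
  expect_equal(out$total_path, 100)

  # identity when everything passes
  ok <- data.frame(id = "a", date = as.Date("2022-03-01") + 0:9,
                   n_fixes = 15, total_path = 1000)
  expect_equal(filter_days(ok), ok)

  # random fixture equals the direct predicate count
  set.seed(8)
  rnd <- data.frame(id = "a", date = as.Date("2022-03-01") + 0:199,
                    n_fixes = sample(5:16, 200, TRUE),
                    total_path = runif(200, 0, 400))
  expect_equal(nrow(filter_days(rnd)),
               sum(rnd$n_fixes >= 10 & rnd$total_path >= 100))
})

test_that("stage assignment follows the season windows", {
  season <- list(hunt_start = "2022-04-10", hunt_end = "2022-05-07")
  daily <- data.frame(id = "a",
                      date = as.Date(c("2022-03-01", "2022-04-09",
                                       "2022-04-10", "2022-05-07",
                                       "2022-05-08", "2022-07-31",
                                       "2022-02-28", "2022-08-01")),
                      n_fixes = 15, total_path = 1000)
  out <- assign_stage(daily, season, sites = c(a = "A"))
  expect_equal(out$stage, c("pre-hunt", "pre-hunt", "hunt", "hunt",
                            "post-hunt", "post-hunt"))
  # records outside March 1 - July 31 dropped
  expect_equal(nrow(out), 6)

  # per-site-year seasons; missing definitions are a named rejection
  seas <- data.frame(site = "A", year = 2022,
                     hunt_start = "2022-04-10", hunt_end = "2022-05-07")
  out2 <- assign_stage(daily, seas, sites = c(a = "A"))
  expect_equal(out2$stage, out$stage)
  daily$site <- "B"
  expect_error(assign_stage(daily, seas), "B 2022")
})

test_that("standardization: sqrt on distances, z-scores, stored metadata", {
  daily <- data.frame(id = "a", date = as.Date("2022-03-01") + 0:2,
                      stage = "pre-hunt", site = "A", n_fixes = 15,
                      dist_open = c(0, 1, 4), dist_edge = c(4, 1, 0),
                      dist_access = c(0, 1, 4), speed = c(10, 20, 30))
  mi <- transform_standardize(daily)
  expect_equal(mi$dist_open, c(-1, 0, 1))
  expect_equal(mi$dist_edge, c(1, 0, -1))
  expect_equal(mi$speed, c(-1, 0, 1))
  meta <- attr(mi, "transforms")
  expect_true(all(meta$sqrt[meta$trait != "speed"]))
  expect_false(meta$sqrt[meta$trait == "speed"])

  # contract: means 0, SDs 1 to numerical precision (filtered set only)
  set.seed(9)
  big <- data.frame(id = "a", date = as.Date("2022-03-01") + 0:499,
                    stage = "pre-hunt", site = "A",
                    n_fixes = sample(10:16, 500, TRUE),
                    dist_open = exp(rnorm(500, 5, 1)),
                    dist_edge = exp(rnorm(500, 4, 1)),
                    dist_access = exp(rnorm(500, 6, 1)),
                    speed = rnorm(500, 100, 20))
  mb <- transform_standardize(big)
  for (tr in c("dist_open", "dist_edge", "dist_access", "speed")) {
    expect_lt(abs(mean(mb[[tr]])), 1e-10)
    expect_lt(abs(sd(mb[[tr]]) - 1), 1e-10)
  }

  # sqrt reduces skew of log-normal distances
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  expect_lt(abs(skew(sqrt(big$dist_open))), abs(skew(big$dist_open)))

  # zero-variance trait is a named rejection
  cons <- daily; cons$speed <- 5
  expect_error(transform_standardize(cons), "speed")

  # round-trip through CSV + JSON sidecar
  cf <- tempfile(fileext = ".csv"); jf <- tempfile(fileext = ".json")
  write_model_input(mb, cf, jf)
  mb2 <- read_model_input(cf, jf)
  expect_equal(as.data.frame(mb2), as.data.frame(mb), tolerance = 1e-12)
  expect_equal(attr(mb2, "transforms"), attr(mb, "transforms"),
               tolerance = 1e-12)
  unlink(c(cf, jf))
})
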