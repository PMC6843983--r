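test_that("season mapping follows meteorological month boundaries", {
  expect_equal(as.character(season_of(as.Date("2008-07-15"))), "summer")
  expect_equal(as.character(season_of(as.Date("2008-12-01"))), "winter")
  expect_equal(as.character(season_of(as.Date("2008-03-01"))), "spring")
  expect_equal(as.character(season_of(as.Date(c("2008-02-29", "2008-09-01",
                                                "2008-11-30", "2008-05-31")))),
               c("winter", "autumn", "autumn", "spring"))
})

test_that("year-over-year differences pair calendar days, skip Feb 29 and NAs", {
  dates <- seq(as.Date("2007-01-01"), as.Date("2008-12-31"), by = "day")
  s <- make_series(dates, tmax = rep(15, length(dates)))
  d <- yoy_differences(s, "tmax")
  expect_true(all(d$diff == 0))
  expect_equal(nrow(d), 365)          # Feb 29 2008 has no pair and is dropped
  expect_false("02-29" %in% format(d$date, "%m-%d"))

  # constant shift
  yr <- as.integer(format(dates, "%Y"))
  s2 <- make_series(dates, tmax = ifelse(yr == 2008, 10.5, 10))
  d2 <- yoy_differences(s2, "tmax")
  expect_true(all(d2$diff == 0.5))

  # randomized series with 10% missingness equals the brute-force double loop
  set.seed(7)
  vals <- stats::rnorm(length(dates), 15, 5)
  vals[sample(length(vals), round(0.1 * length(vals)))] <- NA
  s3 <- make_series(dates, tmax = vals)
  got <- yoy_differences(s3, "tmax")
  want <- oracle_yoy(s3, "tmax")
  expect_equal(got$date, want$date)
  expect_equal(got$diff, want$diff)

  # antisymmetry: swapping the two years' values negates every difference
  md <- format(s3$date, "%m-%d")
  s5 <- s3
  for (mday in unique(md)) {
    i07 <- which(md == mday & yr == 2007)
    i08 <- which(md == mday & yr == 2008)
    if (length(i07) == 1 && length(i08) == 1) {
      s5$tmax[i07] <- s3$tmax[i08]
      s5$tmax[i08] <- s3$tmax[i07]
    }
  }
  d5 <- yoy_differences(s5, "tmax")
  expect_equal(d5$date, got$date)
  expect_equal(d5$diff, -got$diff)

  expect_error(yoy_differences(make_series(dates[1:100], 1:100), "tmax"),
               "2 calendar years")
})

test_that("variation summaries equal a direct group-by, with flagged empty strata", {
  one <- data.frame(date = as.Date("2008-07-10"), diff = 1.0)
  sm <- summarize_variation(one)
  expect_equal(sm$mean_variation[sm$season == "summer"], 1.0)
  expect_equal(sm$n_pairs[sm$season == "summer"], 1L)
  expect_equal(sm$n_pairs[sm$season %in% c("spring", "autumn", "winter")], rep(0L, 3))
  expect_true(all(is.na(sm$mean_variation[sm$n_pairs == 0])))

  set.seed(12)
  dd <- data.frame(date = sample(seq(as.Date("2008-01-01"), as.Date("2008-12-31"),
                                     by = "day"), 1000, replace = TRUE),
                   diff = stats::rnorm(1000))
  sm <- summarize_variation(dd)
  grp <- tapply(dd$diff, season_of(dd$date), mean)
  for (sea in names(grp))
    expect_equal(sm$mean_variation[sm$season == sea], unname(grp[sea]))
  # annual mean equals the pair-count-weighted mean of the seasonal means
  seas <- sm[sm$season != "annual", ]
  expect_equal(sm$mean_variation[sm$season == "annual"],
               sum(seas$mean_variation * seas$n_pairs) / sum(seas$n_pairs))
  expect_equal(sm$n_pairs[sm$season == "annual"], 1000L)
})

test_that("trend fit reduces to least squares and recovers injected trends", {
  cfg <- generator_config(n_stations = 6, lattice_nx = 4, lattice_ny = 4,
                          date_start = "2007-01-01", date_end = "2009-12-31",
                          seed = 3)
  st <- generate_station_series(cfg)

  # closed-form check: no harmonics, no station effects -> OLS slope
  sub <- st[st$station_id == "s001", ]
  tf <- fit_trend(sub, "tmax", harmonics = 0, station_effects = FALSE)
  t_years <- as.numeric(sub$date - min(sub$date)) / 365.25
  t_years <- t_years - mean(t_years)
  expect_equal(tf$trend[["mean"]], stats::cov(t_years, sub$tmax) / stats::var(t_years),
               tolerance = 1e-10)
  expect_lte(tf$trend[["q2.5"]], tf$trend[["mean"]])
  expect_gte(tf$trend[["q97.5"]], tf$trend[["mean"]])

  expect_error(fit_trend(sub[sub$date == sub$date[1], ], "tmax"), "distinct days")

  # null-trend coverage over seeded replicates
  hits <- 0L
  for (s in 1:20) {
    cfg0 <- generator_config(n_stations = 8, lattice_nx = 4, lattice_ny = 4,
                             date_start = "2007-01-01", date_end = "2009-12-31",
                             trend = c(tmax = 0, tmin = 0), seed = 100 + s)
    sts <- generate_station_series(cfg0)
    f <- fit_trend(sts, "tmax")
    if (f$trend[["q2.5"]] <= 0 && f$trend[["q97.5"]] >= 0) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("trend interval coverage holds for an injected minimum-temperature trend", {
  # scaled-down replicates: the 95% interval should cover the generating
  # value in at least 42 of 50 nominal... run 25 here with threshold 20
  hits <- 0L
  zs <- numeric(25)
  for (s in 1:25) {
    cfg <- generator_config(n_stations = 10, lattice_nx = 4, lattice_ny = 4,
                            date_start = "2007-01-01", date_end = "2009-12-31",
                            trend = c(tmax = 0.159, tmin = 0.332), seed = 200 + s)
    st <- generate_station_series(cfg)
    f <- fit_trend(st, "tmin")
    truth <- 0.332 / 5
    if (f$trend[["q2.5"]] <= truth && f$trend[["q97.5"]] >= truth) hits <- hits + 1L
    zs[s] <- (f$trend[["mean"]] - truth) / f$trend[["sd"]]
  }
  expect_gte(hits, 20L)
  expect_lt(abs(mean(zs)), 1)   # no systematic bias
})

test_that("kriging interpolates exactly with zero nugget and matches dense GP algebra", {
  set.seed(5)
  stn <- data.frame(x = stats::runif(9, 0, 50000), y = stats::runif(9, 0, 50000),
                    value = stats::rnorm(9, 2, 1))
  ms <- matern_spec(30000, 1.5)

  # prediction at a station location equals the station value as nugget -> 0
  at_station <- data.frame(x = stn$x[4], y = stn$y[4])
  kr <- krige_to_cells(stn, at_station, ms, nugget_sd = 0)
  expect_equal(kr$pred, stn$value[4], tolerance = 1e-8)
  expect_equal(kr$pred_sd, 0, tolerance = 1e-6)

  # constant station field predicts the constant everywhere
  stc <- stn; stc$value <- 3.3
  grid <- expand.grid(x = seq(0, 50000, length.out = 5),
                      y = seq(0, 50000, length.out = 5))
  krc <- krige_to_cells(stc, grid, ms, nugget_sd = 0.2)
  expect_equal(krc$pred, rep(3.3, 25), tolerance = 1e-10)

  # dense brute-force GP conditional mean oracle, <= 10 stations
  kr2 <- krige_to_cells(stn, grid, ms, nugget_sd = 0.3)
  K <- ms$sd^2 * matern1_correlation(as.matrix(stats::dist(stn[, c("x", "y")])),
                                     ms$range) + diag(0.3^2, 9)
  Ki <- solve(K)
  one <- rep(1, 9)
  mhat <- drop(one %*% Ki %*% stn$value) / drop(one %*% Ki %*% one)
  dx <- outer(grid$x, stn$x, "-"); dy <- outer(grid$y, stn$y, "-")
  Kc <- ms$sd^2 * matern1_correlation(sqrt(dx^2 + dy^2), ms$range)
  expect_equal(kr2$pred, drop(mhat + Kc %*% Ki %*% (stn$value - mhat)),
               tolerance = 1e-8)
  expect_equal(kr2$pred_sd, sqrt(ms$sd^2 - diag(Kc %*% Ki %*% t(Kc))),
               tolerance = 1e-8)
  # conditional sd never exceeds the prior sd
  expect_true(all(kr2$pred_sd <= ms$sd + 1e-12))

  # ill-conditioning: duplicated station with zero nugget
  dup <- rbind(stn, stn[1, ])
  expect_error(krige_to_cells(dup, grid, ms, nugget_sd = 0), "ill-conditioned")
  expect_error(krige_to_cells(stn[1:2, ], grid, ms, 0.1), "3 stations")
})

test_that("station-level variation summaries feed kriging", {
  cfg <- generator_config(n_stations = 8, lattice_nx = 4, lattice_ny = 4,
                          date_start = "2007-01-01", date_end = "2008-12-31",
                          seed = 44)
  st <- generate_station_series(cfg)
  sv <- station_variation(st, "tmax", season = "annual")
  expect_equal(nrow(sv), 8)
  expect_true(all(sv$n_pairs > 300))
  one <- st[st$station_id == sv$station_id[1], ]
  expect_equal(sv$value[1], mean(yoy_differences(one, "tmax")$diff))
})
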