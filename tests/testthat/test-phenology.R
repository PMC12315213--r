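test_that("daily thermal time follows the simple-average formula", {
  expect_equal(daily_thermal_time(10, 20, 8), 7)
  expect_equal(daily_thermal_time(0, 10, 8), 0)   # mean below base floors at 0
  expect_equal(daily_thermal_time(28, 40, 8, 30), 22) # cap then subtract
  expect_equal(daily_thermal_time(c(10, 0), c(20, 10), 8), c(7, 0))
})

test_that("parameter invariants are enforced", {
  expect_error(crop_phenology_params(stage_thresholds = c(100, 100, 200, 300)),
               "increasing")
  expect_error(crop_phenology_params(stage_kc = c(0.3, -1, 1.2, 0.5)),
               "positive")
  expect_error(crop_phenology_params(base_temp = 35, upper_cutoff_temp = 30),
               "base_temp")
})

test_that("zero forcing accumulates nothing and never matures", {
  params <- crop_phenology_params()
  s <- make_series(3, start_year = 2000, tmin = 6, tmax = 10) # mean = base
  ph <- run_season(s, params, 2002)
  expect_false(is.na(ph$sowing_date))
  expect_equal(max(ph$accumulated), 0)
  expect_false(ph$maturity_reached)
  expect_true(is.na(ph$maturity_date))
})

test_that("constant forcing matures exactly ceil(H/d) days after sowing", {
  params <- crop_phenology_params()
  H <- max(params$stage_thresholds)
  for (d_tt in c(7, 10, 13)) {
    # tmean = base + d_tt gives d_tt degC day per day
    s <- make_series(3, start_year = 2000,
                     tmin = params$base_temp + d_tt - 5,
                     tmax = params$base_temp + d_tt + 5)
    ph <- run_season(s, params, 2002)
    expect_true(ph$maturity_reached)
    days_to_maturity <- as.numeric(ph$maturity_date - ph$sowing_date) + 1
    expect_equal(days_to_maturity, ceiling(H / d_tt))
  }
})

test_that("doubling the forcing halves the crossing time up to rounding", {
  params <- crop_phenology_params()
  H <- max(params$stage_thresholds)
  mk <- function(d_tt) make_series(3, start_year = 2000,
                                   tmin = params$base_temp + d_tt - 4,
                                   tmax = params$base_temp + d_tt + 4)
  slow <- run_season(mk(6), params, 2002)
  fast <- run_season(mk(12), params, 2002)
  t_slow <- as.numeric(slow$maturity_date - slow$sowing_date) + 1
  t_fast <- as.numeric(fast$maturity_date - fast$sowing_date) + 1
  expect_equal(t_slow, ceiling(H / 6))
  expect_equal(t_fast, ceiling(H / 12))
  expect_lte(abs(t_fast - t_slow / 2), 1)
})

test_that("accumulation is non-decreasing and stages never step backwards", {
  params <- crop_phenology_params()
  set.seed(3)
  s <- make_series(2, start_year = 2000,
                   tmin = stats::runif(731, 2, 14),
                   tmax = stats::runif(731, 14, 30))
  ph <- run_season(s, params, 2001)
  expect_true(all(diff(ph$accumulated) >= 0))
  sown <- ph$stage > 0
  expect_true(all(diff(ph$stage[sown]) >= 0))
  entries <- ph$stage_entry_dates
  defined <- !is.na(entries)
  expect_true(all(diff(as.numeric(entries[defined])) >= 0))
})

test_that("uniform warming never delays maturity or any stage entry", {
  params <- crop_phenology_params()
  set.seed(5)
  s <- make_series(2, start_year = 2000,
                   tmin = stats::runif(731, 0, 12),
                   tmax = stats::runif(731, 12, 26))
  warm <- shift_temperature(s, 2)
  a <- run_season(s, params, 2001)
  b <- run_season(warm, params, 2001)
  both <- !is.na(a$stage_entry_dates) & !is.na(b$stage_entry_dates)
  expect_true(all(b$stage_entry_dates[both] <= a$stage_entry_dates[both]))
  if (a$maturity_reached) {
    expect_true(b$maturity_reached)
    expect_lte(as.numeric(b$maturity_date), as.numeric(a$maturity_date))
  }
})

test_that("a trigger sowing rule that never fires is an unsown outcome, not an error", {
  params <- crop_phenology_params(
    sowing_rule = list(type = "trigger", earliest = "09-01",
                       window = 10, trigger = 50))
  s <- make_series(2, start_year = 2000, tmin = 5, tmax = 15)
  ph <- run_season(s, params, 2001)
  expect_true(is.na(ph$sowing_date))
  expect_false(ph$maturity_reached)
})

test_that("maturity failure fraction counts failing seasons over a slice", {
  params <- crop_phenology_params()
  # 21 calendar years -> seasons 1981..2000; make exactly 5 of 20 too cold
  n_days <- as.integer(as.Date("2000-12-31") - as.Date("1980-01-01")) + 1
  dates <- seq(as.Date("1980-01-01"), as.Date("2000-12-31"), by = "day")
  season_year <- as.integer(format(dates, "%Y")) +
    (format(dates, "%m-%d") >= "07-01")
  cold <- season_year %in% c(1983, 1987, 1991, 1995, 1999)
  tmean_offset <- ifelse(cold, 0, 10) # warm seasons: 10 degC day forcing
  s <- make_series(21, start_year = 1980,
                   tmin = params$base_temp + tmean_offset - 5,
                   tmax = params$base_temp + tmean_offset + 5)
  expect_equal(maturity_failure_fraction(s, params, c(1981, 2000)), 0.25)
  # all-mature slice
  warm <- make_series(21, start_year = 1980, tmin = 13, tmax = 23)
  expect_equal(maturity_failure_fraction(warm, params, c(1981, 2000)), 0)
  expect_error(maturity_failure_fraction(s, params, c(1990, 1990)), "2 full")
})

test_that("stage timing shifts are zero for identical inputs and negative under warming", {
  params <- crop_phenology_params()
  set.seed(9)
  mk_season <- function(offset, yr) {
    s <- make_series(2, start_year = yr,
                     tmin = stats::runif(731, 2, 12) + offset,
                     tmax = stats::runif(731, 12, 28) + offset)
    run_season(s, params, yr + 1)
  }
  base <- lapply(c(2000, 2002, 2004), function(y) mk_season(0, y))
  same <- stage_timing_shift(base, base)
  expect_equal(same$shift_days, rep(0, length(params$stage_thresholds)))
  set.seed(9)
  warm <- lapply(c(2000, 2002, 2004), function(y) mk_season(2, y))
  shifted <- stage_timing_shift(base, warm)
  expect_true(all(shifted$shift_days <= 0, na.rm = TRUE))
})

test_that("constant forcing halves the crossing day when thermal time doubles", {
  params <- crop_phenology_params()
  mk <- function(d_tt) make_series(3, start_year = 2000,
                                   tmin = params$base_temp + d_tt - 3,
                                   tmax = params$base_temp + d_tt + 3)
  slow <- list(run_season(mk(5), params, 2002))
  fast <- list(run_season(mk(10), params, 2002))
  sh <- stage_timing_shift(slow, fast)
  # each boundary h crossed on day ceil(h/d): shift = ceil(h/10) - ceil(h/5)
  expected <- ceiling(params$stage_thresholds / 10) -
    ceiling(params$stage_thresholds / 5)
  expect_equal(sh$shift_days, expected)
})

test_that("crop parameters round-trip through the YAML file format", {
  p <- read_crop_params(system.file("extdata", "maize_silage.yaml",
                                    package = "agroclimr"))
  expect_s3_class(p, "crop_phenology_params")
  expect_equal(p$base_temp, 8)
  expect_equal(p$stage_thresholds, c(150, 450, 900, 1350))
  expect_equal(p$stage_kc, crop_phenology_params()$stage_kc)
  expect_equal(p$sowing_rule$month_day, "10-01")
})
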