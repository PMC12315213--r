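test_that("builtin specs carry the eleven crop-hazard rows field-for-field", {
  specs <- builtin_hazard_specs()
  expect_equal(nrow(specs), 11)
  expect_equal(nrow(dplyr::distinct(specs[, c("crop_name", "hazard_kind")])), 11)
  row <- function(crop, kind) specs[specs$crop_name == crop &
                                      specs$hazard_kind == kind, ]
  w <- row("wheat", "heat_stress")
  expect_equal(w$critical_value, 25)
  expect_equal(c(w$window_start, w$window_end), c("10-15", "12-15"))
  expect_equal(w$comparator, ">")
  cf <- row("chestnuts", "frost")
  expect_equal(c(cf$comparator, cf$critical_value), c("<", "-4"))
  expect_equal(c(cf$window_start, cf$window_end), c("09-15", "01-31"))
  ch <- row("chestnuts", "heat_stress")
  expect_equal(ch$critical_value, 40)
  expect_equal(c(ch$window_start, ch$window_end), c("09-01", "11-30"))
  oh <- row("onions", "heat_stress")
  expect_equal(oh$critical_value, 31)
  expect_equal(c(oh$window_start, oh$window_end), c("01-01", "02-29"))
  of <- row("onions", "frost")
  expect_equal(of$critical_value, 0)
  expect_equal(c(of$window_start, of$window_end), c("11-01", "11-30"))
  orow <- row("onions", "extreme_rainfall")
  expect_equal(orow$rain_span_days, 7L)
  expect_equal(orow$rain_min_exceed_days, 3L)
  expect_equal(orow$rain_daily_amount, 5)
  expect_equal(c(orow$window_start, orow$window_end), c("01-01", "03-31"))
  ph <- row("peas", "heat_stress")
  expect_equal(ph$critical_value, 30)
  expect_equal(c(ph$window_start, ph$window_end), c("11-01", "02-29"))
  pf <- row("peas", "frost")
  expect_equal(pf$critical_value, -2)
  expect_equal(c(pf$window_start, pf$window_end), c("09-01", "11-30"))
  po_h <- row("potatoes", "heat_stress")
  expect_equal(po_h$critical_value, 20)
  po_f <- row("potatoes", "frost")
  expect_equal(po_f$critical_value, 0)
  expect_equal(c(po_f$window_start, po_f$window_end), c("11-01", "02-29"))
  mz <- row("maize", "heat_stress")
  expect_equal(mz$critical_value, 30)
  expect_equal(c(mz$window_start, mz$window_end), c("12-15", "02-15"))
})

test_that("windows resolve across year boundaries and leap days", {
  w <- resolve_window("12-15", "02-15", 2001)
  expect_equal(w$start, as.Date("2000-12-15"))
  expect_equal(w$end, as.Date("2001-02-15"))
  # 29 Feb resolves to 28 Feb in non-leap years, 29 Feb in leap years
  expect_equal(resolve_window("01-01", "02-29", 2001)$end,
               as.Date("2001-02-28"))
  expect_equal(resolve_window("01-01", "02-29", 2004)$end,
               as.Date("2004-02-29"))
  # within-year window stays in the season year
  w2 <- resolve_window("09-01", "11-30", 1999)
  expect_equal(format(w2$start, "%Y"), "1999")
})

test_that("threshold counting uses strict comparisons on constructed inputs", {
  specs <- builtin_hazard_specs()
  wheat <- specs[specs$crop_name == "wheat", ]
  s <- make_series(1, tmax = 20, tmin = 10)
  expect_equal(count_hazard_days(s, wheat, 2000)$event_days, 0)
  # exactly at the critical value does not count (strict >)
  s25 <- make_series(1, tmax = 25, tmin = 10)
  expect_equal(count_hazard_days(s25, wheat, 2000)$event_days, 0)
  hot_days <- as.Date("2000-11-01") + 0:5
  s6 <- set_on_dates(s, "tmax", hot_days, 26)
  expect_equal(count_hazard_days(s6, wheat, 2000)$event_days, 6)
})

test_that("counts match the day-scan oracle on randomized series", {
  specs <- builtin_hazard_specs()
  set.seed(42)
  for (rep in 1:60) {
    sp <- specs[sample(nrow(specs), 1), ]
    n <- sample(1:2, 1)
    s <- make_series(n, start_year = 2000,
                     tmin = stats::runif(366 * n, -8, 12),
                     tmax = stats::runif(366 * n, 12, 42),
                     precip = stats::rbinom(366 * n, 1, 0.4) *
                       stats::rgamma(366 * n, 0.8, scale = 8))
    for (season in covered_seasons(s, sp)) {
      got <- count_hazard_days(s, sp, season)
      expect_equal(got$event_days, oracle_count_days(s, sp, season))
      if (sp$hazard_kind == "extreme_rainfall") {
        expect_equal(got$triggered, oracle_rain_triggered(s, sp, season))
      }
    }
  }
})

test_that("the rain rule triggers on >3 qualifying days in a wholly contained span", {
  specs <- builtin_hazard_specs()
  rain <- specs[specs$hazard_kind == "extreme_rainfall", ]
  s <- make_series(1, precip = 0)
  # 3 qualifying days in a 7-day span: not triggered (strictly more needed)
  s3 <- set_on_dates(s, "precip", as.Date("2000-02-01") + c(0, 2, 4), 10)
  r3 <- count_hazard_days(s3, rain, 2000)
  expect_false(r3$triggered)
  expect_equal(r3$event_days, 3)
  # 4 qualifying days inside one week: triggered
  s4 <- set_on_dates(s, "precip", as.Date("2000-02-01") + c(0, 2, 4, 6), 10)
  expect_true(count_hazard_days(s4, rain, 2000)$triggered)
  # 4 qualifying days straddling the window end: span not wholly inside
  s_edge <- set_on_dates(s, "precip",
                         as.Date("2000-03-29") + c(0, 1, 2, 3), 10)
  expect_false(count_hazard_days(s_edge, rain, 2000)$triggered)
  # exactly 5 mm qualifies (>= inside the rule)
  s5 <- set_on_dates(s, "precip", as.Date("2000-02-01") + 0:3, 5)
  expect_true(count_hazard_days(s5, rain, 2000)$triggered)
})

test_that("warming monotonicity: heat counts never fall, frost counts never rise", {
  specs <- builtin_hazard_specs()
  set.seed(7)
  s <- make_series(2, tmin = stats::runif(731, -6, 10),
                   tmax = stats::runif(731, 10, 35))
  warm <- shift_temperature(s, 2)
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    if (sp$hazard_kind == "extreme_rainfall") next
    for (season in covered_seasons(s, sp)) {
      d <- count_hazard_days(warm, sp, season)$event_days -
        count_hazard_days(s, sp, season)$event_days
      if (sp$hazard_kind == "heat_stress") expect_gte(d, 0) else expect_lte(d, 0)
    }
  }
})

test_that("splitting a threshold window preserves the total count", {
  specs <- builtin_hazard_specs()
  pot <- specs[specs$crop_name == "potatoes" &
                 specs$hazard_kind == "heat_stress", ]
  set.seed(11)
  s <- make_series(2, tmax = stats::runif(731, 15, 30), tmin = 5)
  full <- count_hazard_days(s, pot, 2001)$event_days
  left <- pot; left$window_end <- "12-31"
  right <- pot; right$window_start <- "01-01"
  expect_equal(count_hazard_days(s, left, 2000)$event_days +
                 count_hazard_days(s, right, 2001)$event_days, full)
})

test_that("uncovered windows raise a coverage error with the missing range", {
  specs <- builtin_hazard_specs()
  wheat <- specs[specs$crop_name == "wheat", ]
  s <- make_series(1, start_year = 2000)
  expect_error(count_hazard_days(s, wheat, 2001), "2001-10-15")
})

test_that("risk change is the difference of per-cell mean annual event days", {
  base <- tibble::tibble(cell_id = rep(c("a", "b"), each = 3),
                         event_days = c(1, 1, 1, 2, 3, 4))
  fut <- tibble::tibble(cell_id = rep(c("a", "b"), each = 3),
                        event_days = c(7, 7, 7, 2, 3, 4))
  ch <- hazard_risk_change(base, fut)
  expect_equal(ch$change[ch$cell_id == "a"], 6)
  expect_equal(ch$change[ch$cell_id == "b"], 0)
  expect_equal(hazard_risk_change(base, base)$change, c(0, 0))
  bad <- tibble::tibble(cell_id = "c", event_days = 1)
  expect_error(hazard_risk_change(base, bad), "a.*b.*c")
})
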