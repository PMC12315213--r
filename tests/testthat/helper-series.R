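# Build a climate series from constant or supplied daily values.
make_series <- function(n_years = 1, start_year = 2000,
                        tmin = 10, tmax = 20, precip = 0,
                        radiation = 15, rel_humidity = 70, wind = 3,
                        cell_id = "test", latitude = -40,
                        scenario_id = "baseline", member_id = 1L) {
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + n_years - 1)),
               by = "day")
  n <- length(dates)
  rep_n <- function(x) if (length(x) == n) x else rep_len(x, n)
  climate_series(
    tibble::tibble(date = dates, tmin = rep_n(tmin), tmax = rep_n(tmax),
                   precip = rep_n(precip), radiation = rep_n(radiation),
                   rel_humidity = rep_n(rel_humidity), wind = rep_n(wind)),
    cell_id = cell_id, latitude = latitude,
    scenario_id = scenario_id, member_id = member_id
  )
}

# Set a value on specific dates of a series field.
set_on_dates <- function(series, field, dates, value) {
  series$data[[field]][series$data$date %in% as.Date(dates)] <- value
  series
}

# Independent day-scan oracle for threshold hazard counting.
oracle_count_days <- function(series, spec, season_label) {
  w <- resolve_window(spec$window_start, spec$window_end, season_label)
  n <- 0L
  for (i in seq_len(nrow(series$data))) {
    day <- series$data$date[i]
    if (day < w$start || day > w$end) next
    v <- series$data[[spec$variable]][i]
    hit <- if (spec$hazard_kind == "extreme_rainfall") {
      series$data$precip[i] >= spec$rain_daily_amount
    } else if (spec$comparator == ">") v > spec$critical_value
    else v < spec$critical_value
    if (hit) n <- n + 1L
  }
  n
}

# Exhaustive enumeration oracle for the sliding rain rule.
oracle_rain_triggered <- function(series, spec, season_label) {
  w <- resolve_window(spec$window_start, spec$window_end, season_label)
  days <- seq(w$start, w$end, by = "day")
  m <- spec$rain_span_days
  if (length(days) < m) return(FALSE)
  for (start in seq_len(length(days) - m + 1)) {
    span <- days[start:(start + m - 1)]
    q <- sum(series$data$precip[series$data$date %in% span] >=
               spec$rain_daily_amount)
    if (q > spec$rain_min_exceed_days) return(TRUE)
  }
  FALSE
}

small_gen_config <- function(seed = 1, n_years = 2, ...) {
  weather_gen_config(seed = seed, n_years = n_years,
                     cells = make_grid_cells(1, 1), ...)
}
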