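#' Construct a crop hazard specification
#'
#' A hazard spec pairs one crop with one climate hazard: a sensitive calendar
#' window (month-day to month-day), a daily variable, a comparator and a
#' critical value. Threshold hazards (heat stress, frost) count days on
#' which the variable strictly exceeds (`>`) or falls strictly below (`<`)
#' the critical value, exactly as the inequalities are printed in the
#' source hazard table. Extreme-rainfall hazards instead carry a rule of the
#' form "more than `rain_min_exceed_days` days in any `rain_span_days`-day
#' span with daily precipitation >= `rain_daily_amount` mm".
#'
#' Windows whose end month-day precedes their start (e.g. 15 Dec - 15 Feb)
#' span the year boundary and belong to the season of their end date. A
#' window end of 29 Feb resolves to 28 Feb in non-leap years.
#'
#' @param crop_name Crop label.
#' @param hazard_kind One of `"heat_stress"`, `"frost"`, `"extreme_rainfall"`.
#' @param variable One of `"tmax"`, `"tmin"`, `"precip"`.
#' @param comparator `">"` or `"<"` (strict, as printed).
#' @param critical_value Threshold in the variable's units (degC or mm/day).
#' @param window_start,window_end Month-day strings, `"MM-DD"`.
#' @param rain_span_days,rain_min_exceed_days,rain_daily_amount Rain-rule
#'   parameters; required exactly when `hazard_kind = "extreme_rainfall"`.
#'   The rule triggers when some span contains strictly more than
#'   `rain_min_exceed_days` qualifying days.
#' @return A one-row tibble (class `hazard_spec` rows are plain data so
#'   spec tables can be read from or written to CSV directly).
#' @export
hazard_spec <- function(crop_name, hazard_kind, variable, comparator,
                        critical_value, window_start, window_end,
                        rain_span_days = NA_integer_,
                        rain_min_exceed_days = NA_integer_,
                        rain_daily_amount = NA_real_) {
  hazard_kind <- match.arg(hazard_kind,
                           c("heat_stress", "frost", "extreme_rainfall"))
  variable <- match.arg(variable, c("tmax", "tmin", "precip"))
  comparator <- match.arg(comparator, c(">", "<"))
  if (identical(window_start, window_end)) {
    stop("hazard window must not be empty (window_start == window_end)",
         call. = FALSE)
  }
  if (!is.finite(critical_value)) {
    stop("critical_value must be finite", call. = FALSE)
  }
  is_rain <- hazard_kind == "extreme_rainfall"
  if (is_rain && (is.na(rain_span_days) || is.na(rain_min_exceed_days) ||
                  is.na(rain_daily_amount))) {
    stop("extreme_rainfall specs require the rain-rule fields", call. = FALSE)
  }
  if (!is_rain && !(is.na(rain_span_days) && is.na(rain_min_exceed_days) &&
                    is.na(rain_daily_amount))) {
    stop("rain-rule fields are only valid for extreme_rainfall specs",
         call. = FALSE)
  }
  tibble::tibble(
    crop_name = crop_name, hazard_kind = hazard_kind, variable = variable,
    comparator = comparator, critical_value = critical_value,
    window_start = window_start, window_end = window_end,
    rain_span_days = as.integer(rain_span_days),
    rain_min_exceed_days = as.integer(rain_min_exceed_days),
    rain_daily_amount = as.numeric(rain_daily_amount)
  )
}

#' Built-in hazard specifications for six arable crops
#'
#' The eleven crop-hazard rows used throughout the package: heat stress,
#' frost and extreme rainfall thresholds with their crop-sensitive calendar
#' windows for chestnuts, onions, peas, potatoes, wheat and maize.
#'
#' @return A tibble with one row per crop-hazard combination (11 rows), in
#'   the column layout of [hazard_spec()].
#' @export
builtin_hazard_specs <- function() {
  dplyr::bind_rows(
    hazard_spec("chestnuts", "heat_stress", "tmax", ">", 40, "09-01", "11-30"),
    hazard_spec("chestnuts", "frost", "tmin", "<", -4, "09-15", "01-31"),
    hazard_spec("onions", "heat_stress", "tmax", ">", 31, "01-01", "02-29"),
    hazard_spec("onions", "frost", "tmin", "<", 0, "11-01", "11-30"),
    hazard_spec("onions", "extreme_rainfall", "precip", ">", 5, "01-01", "03-31",
                rain_span_days = 7L, rain_min_exceed_days = 3L,
                rain_daily_amount = 5),
    hazard_spec("peas", "heat_stress", "tmax", ">", 30, "11-01", "02-29"),
    hazard_spec("peas", "frost", "tmin", "<", -2, "09-01", "11-30"),
    hazard_spec("potatoes", "heat_stress", "tmax", ">", 20, "11-01", "02-29"),
    hazard_spec("potatoes", "frost", "tmin", "<", 0, "11-01", "02-29"),
    hazard_spec("wheat", "heat_stress", "tmax", ">", 25, "10-15", "12-15"),
    hazard_spec("maize", "heat_stress", "tmax", ">", 30, "12-15", "02-15")
  )
}

# Resolve "MM-DD" against a year, mapping 29 Feb to 28 Feb in non-leap years.
month_day_in_year <- function(md, year) {
  d <- as.Date(sprintf("%d-%s", year, md), format = "%Y-%m-%d")
  if (is.na(d) && md == "02-29") d <- as.Date(sprintf("%d-02-28", year))
  if (is.na(d)) stop(sprintf("invalid month-day '%s'", md), call. = FALSE)
  d
}

#' Resolve a hazard window for one season
#'
#' Maps a month-day window onto concrete dates for a harvest season. Windows
#' whose end month-day precedes their start span the year boundary: their
#' end falls in `season_label` and their start in the preceding year.
#'
#' @param window_start,window_end `"MM-DD"` strings.
#' @param season_label Harvest-year integer; the window end falls in this year.
#' @return List with Date elements `start` and `end`.
#' @export
resolve_window <- function(window_start, window_end, season_label) {
  cross_year <- window_end < window_start # zero-padded MM-DD sorts calendrically
  start_year <- if (cross_year) season_label - 1L else season_label
  list(start = month_day_in_year(window_start, start_year),
       end = month_day_in_year(window_end, season_label))
}

#' Count hazard days in one season's sensitive window
#'
#' For threshold hazards, counts days in the resolved window where the
#' variable satisfies the strict comparison against the critical value. For
#' extreme-rainfall hazards, `event_days` counts window days with
#' precipitation at or above the rule's daily amount, and `triggered` is
#' `TRUE` when some `rain_span_days`-day span lying wholly inside the window
#' contains strictly more than `rain_min_exceed_days` qualifying days.
#'
#' @param series A [climate_series()].
#' @param spec One [hazard_spec()] row.
#' @param season_label Harvest-year integer.
#' @return One-row tibble: `cell_id`, `season_label`, `crop_name`,
#'   `hazard_kind`, `event_days`, `triggered` (`NA` for threshold hazards).
#' @export
count_hazard_days <- function(series, spec, season_label) {
  stopifnot(inherits(series, "climate_series"), nrow(spec) == 1)
  w <- resolve_window(spec$window_start, spec$window_end, season_label)
  d <- series$data
  if (w$start < d$date[1] || w$end > d$date[nrow(d)]) {
    stop(sprintf(
      "series does not cover the %s window for season %d (needs %s to %s)",
      spec$hazard_kind, season_label, format(w$start), format(w$end)),
      call. = FALSE)
  }
  inw <- d$date >= w$start & d$date <= w$end
  if (spec$hazard_kind == "extreme_rainfall") {
    q <- d$precip[inw] >= spec$rain_daily_amount
    event_days <- sum(q)
    m <- spec$rain_span_days
    triggered <- if (length(q) >= m) {
      runsum <- cumsum(q)
      spans <- runsum[m:length(q)] - c(0, runsum)[seq_len(length(q) - m + 1)]
      any(spans > spec$rain_min_exceed_days)
    } else FALSE
  } else {
    v <- d[[spec$variable]][inw]
    event_days <- if (spec$comparator == ">") {
      sum(v > spec$critical_value)
    } else {
      sum(v < spec$critical_value)
    }
    triggered <- NA
  }
  tibble::tibble(
    cell_id = series$cell_id, season_label = as.integer(season_label),
    crop_name = spec$crop_name, hazard_kind = spec$hazard_kind,
    event_days = as.integer(event_days), triggered = triggered
  )
}

#' Seasons of a series fully covered by a hazard window
#'
#' Partial first and last seasons (windows extending beyond the series) are
#' dropped, not padded.
#'
#' @param series A [climate_series()].
#' @param spec One [hazard_spec()] row.
#' @return Integer vector of season labels.
#' @export
covered_seasons <- function(series, spec) {
  yrs <- series_years(series)
  cand <- seq(min(yrs), max(yrs) + 1L)
  first <- series$data$date[1]; last <- series$data$date[nrow(series$data)]
  keep <- vapply(cand, function(y) {
    w <- resolve_window(spec$window_start, spec$window_end, y)
    w$start >= first && w$end <= last
  }, TRUE)
  cand[keep]
}

#' Count hazard days for every covered season
#'
#' @inheritParams count_hazard_days
#' @return Tibble of per-season results, one row per covered season.
#' @export
hazard_annual_series <- function(series, spec) {
  seasons <- covered_seasons(series, spec)
  if (length(seasons) == 0) {
    stop("series covers no complete season for this hazard window", call. = FALSE)
  }
  dplyr::bind_rows(lapply(seasons, function(y) count_hazard_days(series, spec, y)))
}

#' Change in hazard risk between two periods
#'
#' The per-cell change statistic: future mean annual event days minus
#' baseline mean annual event days, pooling seasons (and members, if
#' several) within each cell.
#'
#' @param baseline_results,future_results Tibbles of per-season results as
#'   returned by [count_hazard_days()]/[hazard_annual_series()], covering
#'   the same set of cells.
#' @return Tibble: `cell_id`, `baseline_mean`, `future_mean`, `change`
#'   (days/year).
#' @export
hazard_risk_change <- function(baseline_results, future_results) {
  b_cells <- unique(baseline_results$cell_id)
  f_cells <- unique(future_results$cell_id)
  extra <- c(setdiff(b_cells, f_cells), setdiff(f_cells, b_cells))
  if (length(extra) > 0) {
    stop("baseline and future cover different cells: ",
         paste(sort(unique(extra)), collapse = ", "), call. = FALSE)
  }
  b <- dplyr::summarise(dplyr::group_by(baseline_results, .data$cell_id),
                        baseline_mean = mean(.data$event_days), .groups = "drop")
  f <- dplyr::summarise(dplyr::group_by(future_results, .data$cell_id),
                        future_mean = mean(.data$event_days), .groups = "drop")
  out <- dplyr::inner_join(b, f, by = "cell_id")
  out$change <- out$future_mean - out$baseline_mean
  out
}
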