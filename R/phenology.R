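#' Crop phenology parameters
#'
#' Parameters of the thermal-time (growing-degree-day) engine: a base
#' temperature, an optional upper cutoff, a sowing rule, ordered accumulated
#' thermal-time thresholds marking the FAO growth-stage boundaries
#' (initial -> development -> mid -> late -> maturity), and one water-demand
#' coefficient (Kc) per active stage.
#'
#' Daily thermal time uses the simple-average method,
#' `max(0, min(Tmean, cutoff) - base)` with `Tmean = (tmin + tmax)/2`.
#' Crossing the last threshold means maturity. The default maize values
#' (base 8 degC, cutoff 30 degC, Kc 0.3/0.75/1.2/0.5 in the FAO-56
#' convention) are conventional settings for a temperate maize silage crop,
#' exposed here precisely so they can be replaced by a local calibration.
#'
#' Seasons follow the southern-hemisphere convention: a season labelled by
#' its harvest year runs from `season_start` (default 1 July of the previous
#' calendar year) to `season_cutoff` (default 30 June of the harvest year).
#'
#' @param crop_name Crop label.
#' @param base_temp Base temperature (degC).
#' @param upper_cutoff_temp Optional upper cutoff (degC); `NULL` disables it.
#' @param sowing_rule Either `list(type = "fixed", month_day = "MM-DD")` or
#'   `list(type = "trigger", earliest = "MM-DD", window = <days>,
#'   trigger = <degC>)`: sow on the first day at or after `earliest` whose
#'   trailing `window`-day mean temperature reaches `trigger`.
#' @param stage_thresholds Strictly increasing accumulated thermal time
#'   (degC day) at each stage boundary; the last value is the maturity
#'   requirement.
#' @param stage_kc Positive water-demand coefficient per active stage; same
#'   length as `stage_thresholds`.
#' @param season_start,season_cutoff Month-day strings bounding a season.
#' @return A `crop_phenology_params` list.
#' @export
crop_phenology_params <- function(crop_name = "maize",
                                  base_temp = 8,
                                  upper_cutoff_temp = 30,
                                  sowing_rule = list(type = "fixed",
                                                     month_day = "10-01"),
                                  stage_thresholds = c(150, 450, 900, 1350),
                                  stage_kc = c(0.3, 0.75, 1.2, 0.5),
                                  season_start = "07-01",
                                  season_cutoff = "06-30") {
  if (any(diff(stage_thresholds) <= 0)) {
    stop("stage_thresholds must be strictly increasing", call. = FALSE)
  }
  if (any(stage_kc <= 0)) stop("stage_kc must be positive", call. = FALSE)
  if (length(stage_kc) != length(stage_thresholds)) {
    stop("stage_kc must have one value per stage threshold", call. = FALSE)
  }
  if (!is.null(upper_cutoff_temp) && base_temp >= upper_cutoff_temp) {
    stop("base_temp must be below upper_cutoff_temp", call. = FALSE)
  }
  sowing_rule$type <- match.arg(sowing_rule$type, c("fixed", "trigger"))
  structure(
    list(crop_name = crop_name, base_temp = base_temp,
         upper_cutoff_temp = upper_cutoff_temp, sowing_rule = sowing_rule,
         stage_thresholds = stage_thresholds, stage_kc = stage_kc,
         season_start = season_start, season_cutoff = season_cutoff),
    class = "crop_phenology_params"
  )
}

#' Read crop parameters from a YAML file
#' @param path YAML file with fields matching [crop_phenology_params()].
#' @return A `crop_phenology_params` object.
#' @export
read_crop_params <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(crop_phenology_params, y)
}

#' Daily thermal time (growing degree days)
#'
#' `max(0, min(Tmean, cutoff) - base)` with `Tmean = (tmin + tmax)/2`;
#' never negative. Vectorised over days.
#'
#' @param tmin,tmax Daily minimum and maximum temperature (degC).
#' @param base_temp Base temperature (degC).
#' @param upper_cutoff_temp Optional upper cutoff (degC), `NULL` to disable.
#' @return Thermal time in degC day.
#' @export
daily_thermal_time <- function(tmin, tmax, base_temp,
                               upper_cutoff_temp = NULL) {
  tmean <- (tmin + tmax) / 2
  if (!is.null(upper_cutoff_temp)) tmean <- pmin(tmean, upper_cutoff_temp)
  pmax(0, tmean - base_temp)
}

thermal_time_for_params <- function(d, params) {
  daily_thermal_time(d$tmin, d$tmax, params$base_temp, params$upper_cutoff_temp)
}

season_bounds <- function(params, season_label) {
  start_year <- if (params$season_cutoff < params$season_start) {
    season_label - 1L
  } else {
    season_label
  }
  list(start = month_day_in_year(params$season_start, start_year),
       end = month_day_in_year(params$season_cutoff, season_label))
}

resolve_sowing_date <- function(d, params, bounds) {
  rule <- params$sowing_rule
  md_date <- function(md) {
    cand <- month_day_in_year(md, as.integer(format(bounds$start, "%Y")))
    if (cand < bounds$start) {
      cand <- month_day_in_year(md, as.integer(format(bounds$end, "%Y")))
    }
    cand
  }
  if (rule$type == "fixed") {
    s <- md_date(rule$month_day)
    if (s < bounds$start || s > bounds$end) return(as.Date(NA))
    return(s)
  }
  earliest <- md_date(rule$earliest)
  w <- rule$window
  tmean <- (d$tmin + d$tmax) / 2
  roll <- as.numeric(stats::filter(tmean, rep(1 / w, w), sides = 1))
  ok <- which(d$date >= earliest & !is.na(roll) & roll >= rule$trigger)
  if (length(ok) == 0) as.Date(NA) else d$date[ok[1]]
}

#' Run the phenology engine for one season
#'
#' Resolves the sowing date, accumulates thermal time daily from sowing to
#' the season cutoff, derives the FAO stage sequence (the stage index is one
#' plus the number of boundary thresholds already reached) and determines
#' whether the crop reached maturity (crossed the final threshold) before
#' the cutoff. A sowing rule that never triggers is a model outcome, not an
#' error: the season is returned unsown with `maturity_reached = FALSE`.
#'
#' @param series A [climate_series()].
#' @param params A [crop_phenology_params()].
#' @param season_label Harvest-year integer.
#' @return A `season_phenology` list: `season_label`, `sowing_date`,
#'   `dates`, `thermal_time`, `accumulated` (non-decreasing degC day),
#'   `stage` (integer per day), `stage_entry_dates` (one per boundary,
#'   `NA` if not reached), `maturity_reached`, `maturity_date`.
#' @export
run_season <- function(series, params, season_label) {
  stopifnot(inherits(series, "climate_series"),
            inherits(params, "crop_phenology_params"))
  b <- season_bounds(params, season_label)
  d <- series$data
  if (b$start < d$date[1] || b$end > d$date[nrow(d)]) {
    stop(sprintf("series does not cover season %d (needs %s to %s)",
                 season_label, format(b$start), format(b$end)), call. = FALSE)
  }
  d <- d[d$date >= b$start & d$date <= b$end, ]
  sow <- resolve_sowing_date(d, params, b)
  empty <- list(season_label = as.integer(season_label), sowing_date = sow,
                dates = d$date, thermal_time = rep(0, nrow(d)),
                accumulated = rep(0, nrow(d)),
                stage = rep(0L, nrow(d)),
                stage_entry_dates = rep(as.Date(NA),
                                        length(params$stage_thresholds)),
                maturity_reached = FALSE, maturity_date = as.Date(NA))
  class(empty) <- "season_phenology"
  if (is.na(sow)) return(empty)

  grown <- d$date >= sow
  tt <- numeric(nrow(d))
  tt[grown] <- thermal_time_for_params(d[grown, ], params)
  acc <- cumsum(tt)
  stage <- integer(nrow(d))
  stage[grown] <- 1L + findInterval(acc[grown], params$stage_thresholds)
  entry <- as.Date(vapply(params$stage_thresholds, function(h) {
    i <- which(acc >= h)[1]
    if (is.na(i)) NA_real_ else as.numeric(d$date[i])
  }, 1), origin = "1970-01-01")
  nb <- length(params$stage_thresholds)
  out <- empty
  out$sowing_date <- sow
  out$thermal_time <- tt
  out$accumulated <- acc
  out$stage <- stage
  out$stage_entry_dates <- entry
  out$maturity_reached <- !is.na(entry[nb])
  out$maturity_date <- entry[nb]
  out
}

#' Fraction of seasons failing to reach maturity in a time slice
#'
#' The maturity-failure metric over a multi-year window: the share of
#' seasons in which accumulated thermal time never reached the final stage
#' threshold before the season cutoff (unsown seasons count as failures).
#'
#' @param series A [climate_series()].
#' @param params A [crop_phenology_params()].
#' @param slice Integer vector `c(first, last)` of harvest-year labels
#'   (20-year windows by convention).
#' @return Fraction in `[0, 1]`.
#' @export
maturity_failure_fraction <- function(series, params, slice) {
  seasons <- seq(slice[1], slice[2])
  if (length(seasons) < 2) {
    stop("slice must cover at least 2 full seasons", call. = FALSE)
  }
  failed <- vapply(seasons, function(y) {
    !run_season(series, params, y)$maturity_reached
  }, TRUE)
  mean(failed)
}

season_day_of_entry <- function(ph) {
  as.numeric(ph$stage_entry_dates) - as.numeric(ph$dates[1]) + 1
}

#' Shift in phenological stage timing between two sets of seasons
#'
#' Compares the day-of-season on which each stage boundary is crossed
#' between a baseline and a future set of [run_season()] results. Negative
#' shifts are advances (earlier development under warming). When the two
#' sets are the same length they are treated as paired seasons and the
#' standard deviation is that of the paired differences; otherwise the shift
#' is a difference of means with the combined inter-annual standard
#' deviation. A stage never reached in one set is reported as `NA` without
#' affecting the other stages.
#'
#' @param baseline,future Lists of `season_phenology` objects sharing the
#'   same [crop_phenology_params()].
#' @return Tibble: `stage_boundary`, `shift_days`, `sd_days`, `n_baseline`,
#'   `n_future`.
#' @export
stage_timing_shift <- function(baseline, future) {
  if (length(baseline) == 0 || length(future) == 0) {
    stop("both season sets must be non-empty", call. = FALSE)
  }
  nb <- length(baseline[[1]]$stage_entry_dates)
  bd <- vapply(baseline, season_day_of_entry, numeric(nb))
  fd <- vapply(future, season_day_of_entry, numeric(nb))
  bd <- matrix(bd, nrow = nb); fd <- matrix(fd, nrow = nb)
  paired <- ncol(bd) == ncol(fd)
  rows <- lapply(seq_len(nb), function(j) {
    b <- bd[j, ]; f <- fd[j, ]
    if (all(is.na(b)) || all(is.na(f))) {
      return(tibble::tibble(stage_boundary = j, shift_days = NA_real_,
                            sd_days = NA_real_,
                            n_baseline = sum(!is.na(b)),
                            n_future = sum(!is.na(f))))
    }
    if (paired) {
      diffs <- f - b
      tibble::tibble(stage_boundary = j,
                     shift_days = mean(diffs, na.rm = TRUE),
                     sd_days = stats::sd(diffs[!is.na(diffs)]),
                     n_baseline = sum(!is.na(b)), n_future = sum(!is.na(f)))
    } else {
      tibble::tibble(stage_boundary = j,
                     shift_days = mean(f, na.rm = TRUE) - mean(b, na.rm = TRUE),
                     sd_days = sqrt(stats::var(b, na.rm = TRUE) +
                                      stats::var(f, na.rm = TRUE)),
                     n_baseline = sum(!is.na(b)), n_future = sum(!is.na(f)))
    }
  })
  dplyr::bind_rows(rows)
}
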