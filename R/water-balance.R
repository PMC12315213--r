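#' Daily reference evapotranspiration
#'
#' Default method is Priestley-Taylor: radiation- and temperature-driven,
#' `ET0 = alpha * Delta/(Delta + gamma) * Rns / lambda` with `alpha = 1.26`,
#' psychrometric constant `gamma = 0.0665` kPa/degC, latent heat
#' `lambda = 2.45` MJ/kg and net shortwave `Rns = (1 - 0.23) * radiation`
#' (soil heat flux and net longwave neglected at the daily step). A
#' simplified FAO-56 Penman-Monteith variant using relative humidity and
#' wind is available with `method = "penman_monteith"` (same net-radiation
#' approximation).
#'
#' @param tmin,tmax Daily temperatures (degC).
#' @param radiation Solar radiation (MJ/m2/day).
#' @param rel_humidity Relative humidity (%), used by Penman-Monteith.
#' @param wind Wind speed (m/s), used by Penman-Monteith.
#' @param method `"priestley_taylor"` (default) or `"penman_monteith"`.
#' @return Reference ET in mm/day (vectorised, never negative).
#' @export
reference_et <- function(tmin, tmax, radiation, rel_humidity = NULL,
                         wind = NULL,
                         method = c("priestley_taylor", "penman_monteith")) {
  method <- match.arg(method)
  tmean <- (tmin + tmax) / 2
  sat_vp <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  delta <- 4098 * sat_vp(tmean) / (tmean + 237.3)^2
  gamma <- 0.0665
  rns <- (1 - 0.23) * radiation
  if (method == "priestley_taylor") {
    et <- 1.26 * delta / (delta + gamma) * rns / 2.45
  } else {
    if (is.null(rel_humidity) || is.null(wind)) {
      stop("penman_monteith needs rel_humidity and wind", call. = FALSE)
    }
    es <- (sat_vp(tmax) + sat_vp(tmin)) / 2
    ea <- rel_humidity / 100 * es
    et <- (0.408 * delta * rns +
             gamma * 900 / (tmean + 273) * wind * (es - ea)) /
      (delta + gamma * (1 + 0.34 * wind))
  }
  pmax(0, et)
}

#' Soil parameters for the water-balance bucket
#' @param cell_id Cell identifier.
#' @param available_water_capacity Plant-available store size (mm, > 0).
#' @return A `soil_params` list.
#' @export
soil_params <- function(cell_id, available_water_capacity) {
  if (!is.numeric(available_water_capacity) || available_water_capacity <= 0) {
    stop("available_water_capacity must be > 0", call. = FALSE)
  }
  structure(list(cell_id = as.character(cell_id),
                 available_water_capacity = available_water_capacity),
            class = "soil_params")
}

#' Advance the soil-water bucket by one day
#'
#' The single-bucket FAO-style daily step. Crop demand is
#' `kc * reference ET`; actual ET is supply-limited, scaling linearly with
#' soil water below the stress threshold `stress_f * capacity` and
#' additionally capped at the water physically available that day
#' (`soil_water + precip`), so the mass balance
#' `delta storage = precip - actual_et - drainage` closes exactly. Excess
#' above capacity leaves as drainage. The day's unmet demand
#' (`crop_demand - actual_et`) is added to the accumulated potential
#' evapotranspiration deficit (PED).
#'
#' @param state List with `soil_water` (mm) and `accumulated_ped` (mm), as
#'   returned by a previous call.
#' @param record One day's weather: a list or one-row data frame with
#'   `tmin`, `tmax`, `precip`, `radiation` (and `rel_humidity`, `wind` for
#'   the Penman-Monteith option).
#' @param soil A [soil_params()].
#' @param kc Crop water-demand coefficient for the day (> 0 while a crop is
#'   active, 0 otherwise).
#' @param stress_f Fraction of capacity below which ET becomes
#'   supply-limited (default 0.5).
#' @param et_method Passed to [reference_et()].
#' @return The new state: `soil_water`, `pet`, `crop_demand`, `actual_et`,
#'   `drainage`, `daily_deficit`, `accumulated_ped`.
#' @export
step_day <- function(state, record, soil, kc, stress_f = 0.5,
                     et_method = "priestley_taylor") {
  cap <- soil$available_water_capacity
  pet <- reference_et(record$tmin, record$tmax, record$radiation,
                      record$rel_humidity, record$wind, method = et_method)
  demand <- kc * pet
  frac <- min(1, state$soil_water / (stress_f * cap))
  aet <- min(demand * frac, state$soil_water + record$precip)
  drainage <- max(0, state$soil_water + record$precip - aet - cap)
  sw <- state$soil_water + record$precip - aet - drainage
  deficit <- demand - aet
  list(soil_water = sw, pet = pet, crop_demand = demand, actual_et = aet,
       drainage = drainage, daily_deficit = deficit,
       accumulated_ped = state$accumulated_ped + deficit)
}

# Inlined bucket recurrence over a day range; pinned against step_day() by a
# test. kc is a per-day vector (0 = no crop demand).
wb_run <- function(d, kc, capacity, initial_soil_water, stress_f,
                   et_method, irrigated = FALSE) {
  n <- nrow(d)
  pet <- reference_et(d$tmin, d$tmax, d$radiation, d$rel_humidity, d$wind,
                      method = et_method)
  demand <- kc * pet
  precip <- d$precip
  sw_v <- aet_v <- dr_v <- def_v <- irr_v <- numeric(n)
  sw <- initial_soil_water
  thr <- stress_f * capacity
  for (i in seq_len(n)) {
    dem <- demand[i]
    frac <- if (sw >= thr) 1 else sw / thr
    aet <- dem * frac
    avail <- sw + precip[i]
    if (aet > avail) aet <- avail
    drain <- sw + precip[i] - aet - capacity
    if (drain < 0) drain <- 0
    sw <- sw + precip[i] - aet - drain
    def <- dem - aet
    if (irrigated) {
      irr_v[i] <- def
      def <- 0
    }
    sw_v[i] <- sw; aet_v[i] <- aet; dr_v[i] <- drain; def_v[i] <- def
  }
  tibble::tibble(
    date = d$date, pet = pet, kc = kc, crop_demand = demand,
    precip = precip, actual_et = aet_v, drainage = dr_v,
    soil_water = sw_v, daily_deficit = def_v, irrigation = irr_v,
    accumulated_ped = cumsum(def_v)
  )
}

#' Run a constant-coefficient water balance over a date range
#'
#' The classic fixed-Kc potential evapotranspiration deficit: the bucket
#' runs with a single crop coefficient over an explicit date range, without
#' phenological staging. Used for pasture-style PED and as a reference for
#' the staged model.
#'
#' @param series A [climate_series()].
#' @param soil A [soil_params()].
#' @param kc Constant crop coefficient.
#' @param start,end Date range (defaults to the whole series).
#' @param initial_fraction Initial store as a fraction of capacity
#'   (default 1: full profile, a winter-recharge assumption).
#' @param stress_f,et_method See [step_day()].
#' @param irrigated Unlimited-irrigation mode: the daily deficit is met by
#'   irrigation (logged in the `irrigation` column) and PED stays 0.
#' @return A daily trace tibble (see [step_day()] for columns); the final
#'   `accumulated_ped` is the period PED.
#' @export
run_water_balance <- function(series, soil, kc = 1,
                              start = NULL, end = NULL,
                              initial_fraction = 1, stress_f = 0.5,
                              et_method = "priestley_taylor",
                              irrigated = FALSE) {
  d <- series$data
  if (!is.null(start)) d <- d[d$date >= as.Date(start), ]
  if (!is.null(end)) d <- d[d$date <= as.Date(end), ]
  if (nrow(d) == 0) stop("empty date range", call. = FALSE)
  wb_run(d, rep(kc, nrow(d)), soil$available_water_capacity,
         initial_fraction * soil$available_water_capacity,
         stress_f, et_method, irrigated)
}

#' Seasonal potential evapotranspiration deficit for a staged crop
#'
#' Couples the water-balance bucket to the phenology engine: the crop's
#' stage sequence for the season selects the day's Kc, demand is zero
#' before sowing, and the accumulated deficit (PED) is returned at maturity
#' (`accumulation = "growth"`, the default) or carried through to the
#' season cutoff with the final stage's Kc (`accumulation = "calendar"`).
#' The bucket itself runs from the season start in both modes so that soil
#' storage reflects pre-sowing rainfall.
#'
#' @param series A [climate_series()].
#' @param params A [crop_phenology_params()].
#' @param soil A [soil_params()].
#' @param season_label Harvest-year integer.
#' @param accumulation `"growth"` or `"calendar"` (see above).
#' @param initial_fraction,stress_f,et_method,irrigated See
#'   [run_water_balance()].
#' @return List: `season_label`, `ped` (mm, >= 0), `trace` (daily tibble
#'   with `stage` column), `phenology` (the [run_season()] result).
#' @export
run_season_ped <- function(series, params, soil, season_label,
                           accumulation = c("growth", "calendar"),
                           initial_fraction = 1, stress_f = 0.5,
                           et_method = "priestley_taylor",
                           irrigated = FALSE) {
  accumulation <- match.arg(accumulation)
  ph <- run_season(series, params, season_label)
  d <- series$data
  d <- d[d$date >= ph$dates[1] & d$date <= ph$dates[length(ph$dates)], ]
  nstage <- length(params$stage_kc)
  kc <- numeric(nrow(d))
  active <- ph$stage >= 1L & ph$stage <= nstage
  kc[active] <- params$stage_kc[ph$stage[active]]
  post <- ph$stage > nstage # at or past maturity
  if (accumulation == "calendar") kc[post] <- params$stage_kc[nstage]
  trace <- wb_run(d, kc, soil$available_water_capacity,
                  initial_fraction * soil$available_water_capacity,
                  stress_f, et_method, irrigated)
  trace$stage <- ph$stage
  end_i <- if (accumulation == "growth" && ph$maturity_reached) {
    which(trace$date == ph$maturity_date)
  } else {
    nrow(trace)
  }
  list(season_label = as.integer(season_label),
       ped = trace$accumulated_ped[end_i],
       trace = trace, phenology = ph)
}

#' Monthly crop water demand profile over a time slice
#'
#' Summarises daily crop demand from a collection of seasonal traces into a
#' per-calendar-month climatology: the mean (across seasons and ensemble
#' members) of the monthly summed demand, together with the full set of
#' season-by-member values (the scatter behind the mean). Months with no
#' demand in any trace report 0.
#'
#' @param traces A list of seasonal results from [run_season_ped()] (or any
#'   list of objects with a `trace` tibble holding `date` and `crop_demand`).
#' @return Tibble: `month` (1-12), `mean_demand` (mm), `n_values`, and
#'   `values` (list column of all season-by-member monthly sums).
#' @export
monthly_demand_profile <- function(traces) {
  if (length(traces) == 0) stop("at least one trace is required", call. = FALSE)
  per <- lapply(traces, function(tr) {
    t <- tr$trace
    m <- as.integer(format(t$date, "%m"))
    v <- vapply(1:12, function(mm) sum(t$crop_demand[m == mm]), 1)
    v
  })
  mat <- do.call(cbind, per)
  tibble::tibble(
    month = 1:12,
    mean_demand = rowMeans(mat),
    n_values = ncol(mat),
    values = lapply(1:12, function(i) mat[i, ])
  )
}

#' Demand-weighted centre of the growing season
#'
#' The demand-weighted mean month of a [monthly_demand_profile()], measured
#' in months since the season start (July = 1 ... June = 12 under the
#' default southern-hemisphere season). A smaller value means the bulk of
#' crop water demand falls earlier in the season.
#'
#' @param profile A [monthly_demand_profile()] result.
#' @param season_start_month First month of the season (default 7, July).
#' @return Weighted mean season-month (numeric).
#' @export
demand_weighted_center <- function(profile, season_start_month = 7) {
  idx <- ((profile$month - season_start_month) %% 12) + 1
  if (sum(profile$mean_demand) == 0) return(NA_real_)
  sum(idx * profile$mean_demand) / sum(profile$mean_demand)
}
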