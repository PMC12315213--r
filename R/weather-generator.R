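#' Weather generator configuration
#'
#' Configures the stochastic daily weather generator that emulates 5 km
#' gridded downscaled climate projections. The generator follows the classic
#' WGEN-family structure: a seasonal sinusoid plus AR(1) anomaly for
#' temperature (shared by `tmin`/`tmax` through a positive diurnal range, so
#' `tmax >= tmin` holds by construction), a first-order two-state Markov
#' chain for precipitation occurrence with gamma-distributed wet-day
#' amounts, and climatological sinusoids with bounded noise for radiation,
#' relative humidity and wind.
#'
#' @param seed Integer base seed. Each (cell, member) pair derives its own
#'   reproducible stream from it.
#' @param n_years Number of whole calendar years to generate.
#' @param start_year First calendar year (default 1981).
#' @param cells Data frame with one row per grid cell: `cell_id`,
#'   `latitude` (decimal degrees, negative = southern hemisphere),
#'   `temp_mean` (degC annual mean) and `temp_amplitude` (degC seasonal
#'   half-range). See [make_grid_cells()].
#' @param ar1 AR(1) coefficient of the daily temperature anomaly, in `[0, 1)`.
#' @param noise_sd Innovation standard deviation of the anomaly (degC).
#' @param diurnal_range Mean daily `tmax - tmin` (degC, > 0).
#' @param diurnal_range_sd Day-to-day s.d. of the diurnal range; realised
#'   ranges are floored at 0.5 degC.
#' @param p_wet_wet,p_dry_wet Markov transition probabilities
#'   P(wet | wet yesterday) and P(wet | dry yesterday), in `[0, 1]`.
#' @param rain_shape,rain_scale Gamma shape and scale (mm) of wet-day amounts.
#' @param radiation_mean,radiation_amplitude Annual mean and seasonal
#'   half-range of solar radiation (MJ/m2/day).
#' @param radiation_sd,rh_mean,rh_sd,wind_mean,wind_sd Noise scales and means
#'   for radiation, relative humidity (%) and wind (m/s); all fields are
#'   clipped to their physical ranges.
#'
#' @return A `weather_gen_config` list.
#' @export
weather_gen_config <- function(seed,
                               n_years,
                               start_year = 1981,
                               cells = make_grid_cells(1, 1),
                               ar1 = 0.7,
                               noise_sd = 2,
                               diurnal_range = 8,
                               diurnal_range_sd = 1.5,
                               p_wet_wet = 0.6,
                               p_dry_wet = 0.25,
                               rain_shape = 0.8,
                               rain_scale = 8,
                               radiation_mean = 15,
                               radiation_amplitude = 9,
                               radiation_sd = 3,
                               rh_mean = 75,
                               rh_sd = 10,
                               wind_mean = 4,
                               wind_sd = 1.5) {
  cfg <- list(
    seed = seed, n_years = n_years, start_year = start_year,
    cells = tibble::as_tibble(cells),
    ar1 = ar1, noise_sd = noise_sd,
    diurnal_range = diurnal_range, diurnal_range_sd = diurnal_range_sd,
    p_wet_wet = p_wet_wet, p_dry_wet = p_dry_wet,
    rain_shape = rain_shape, rain_scale = rain_scale,
    radiation_mean = radiation_mean, radiation_amplitude = radiation_amplitude,
    radiation_sd = radiation_sd, rh_mean = rh_mean, rh_sd = rh_sd,
    wind_mean = wind_mean, wind_sd = wind_sd
  )
  class(cfg) <- "weather_gen_config"
  validate_weather_gen_config(cfg)
}

validate_weather_gen_config <- function(cfg) {
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) {
      stop(sprintf("invalid weather generator configuration: `%s` %s",
                   field, what), call. = FALSE)
    }
  }
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 && is.finite(cfg$seed),
      "seed", "must be a single finite number")
  chk(is.numeric(cfg$n_years) && cfg$n_years >= 1, "n_years", "must be >= 1")
  chk(all(c("cell_id", "latitude", "temp_mean", "temp_amplitude") %in%
            names(cfg$cells)), "cells",
      "must have columns cell_id, latitude, temp_mean, temp_amplitude")
  chk(nrow(cfg$cells) >= 1, "cells", "must have at least one row")
  chk(cfg$ar1 >= 0 && cfg$ar1 < 1, "ar1", "must be in [0, 1)")
  chk(cfg$noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(cfg$diurnal_range > 0, "diurnal_range", "must be > 0")
  chk(cfg$p_wet_wet >= 0 && cfg$p_wet_wet <= 1, "p_wet_wet", "must be in [0, 1]")
  chk(cfg$p_dry_wet >= 0 && cfg$p_dry_wet <= 1, "p_dry_wet", "must be in [0, 1]")
  chk(cfg$rain_shape > 0, "rain_shape", "must be > 0")
  chk(cfg$rain_scale > 0, "rain_scale", "must be > 0")
  invisible(cfg)
}

#' Build a rectangular grid of cells with a latitudinal climate gradient
#'
#' Convenience constructor for the generator's `cells` table: an `nx` by `ny`
#' grid spanning a latitude range, with annual-mean temperature decreasing
#' away from the equator (the cold-limited south end of a New Zealand-like
#' domain).
#'
#' @param nx,ny Grid dimensions.
#' @param lat_range Latitude range, default `c(-35, -46)` (north to south).
#' @param temp_at_35 Annual-mean temperature at 35 degrees latitude (degC).
#' @param lapse Cooling per degree of latitude away from 35 (degC/deg).
#' @param temp_amplitude Seasonal half-range (degC).
#' @return A tibble with columns `cell_id`, `x`, `y`, `latitude`,
#'   `temp_mean`, `temp_amplitude`.
#' @export
make_grid_cells <- function(nx, ny, lat_range = c(-35, -46),
                            temp_at_35 = 15, lapse = 0.6,
                            temp_amplitude = 5) {
  lats <- if (ny == 1) mean(lat_range) else
    seq(lat_range[1], lat_range[2], length.out = ny)
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  lat <- lats[g$y]
  tibble::tibble(
    cell_id = sprintf("c%03d_%03d", g$x, g$y),
    x = g$x, y = g$y,
    latitude = lat,
    temp_mean = temp_at_35 - lapse * (abs(lat) - 35),
    temp_amplitude = temp_amplitude
  )
}

#' Scenario perturbation
#'
#' Describes how one emissions scenario perturbs generated weather: a warming
#' offset added to `tmin` and `tmax` (by default ramped linearly from 0 at
#' the series start to its full value at the end, mimicking a transient
#' scenario; set `ramp = FALSE` for a constant offset) and a multiplicative
#' precipitation scale. Distinct ensemble members differ only by their
#' random-number stream.
#'
#' @param scenario_id Label, conventionally one of `"RCP2.6"`, `"RCP4.5"`,
#'   `"RCP6.0"`, `"RCP8.5"`, or `"baseline"`.
#' @param warming_offset Degrees Celsius added to both temperature fields.
#' @param precip_scale Multiplicative factor on precipitation amounts (> 0).
#' @param member_count Pseudo-ensemble size (>= 1).
#' @param ramp Ramp the offset linearly over the series (default `TRUE`).
#' @return A `scenario_perturbation` list.
#' @export
scenario_perturbation <- function(scenario_id = "baseline",
                                  warming_offset = 0,
                                  precip_scale = 1,
                                  member_count = 1L,
                                  ramp = TRUE) {
  if (!is.numeric(precip_scale) || precip_scale <= 0) {
    stop("invalid perturbation: `precip_scale` must be > 0", call. = FALSE)
  }
  if (member_count < 1) {
    stop("invalid perturbation: `member_count` must be >= 1", call. = FALSE)
  }
  structure(
    list(scenario_id = scenario_id, warming_offset = warming_offset,
         precip_scale = precip_scale, member_count = as.integer(member_count),
         ramp = isTRUE(ramp)),
    class = "scenario_perturbation"
  )
}

#' Default perturbations for the four RCP scenarios
#'
#' End-of-century warming offsets and precipitation scales representative of
#' mid-latitude projections for the four representative concentration
#' pathways, suitable for the synthetic experiments in this package. These
#' are generator settings, not downscaled model output.
#'
#' @param member_count Ensemble size per scenario (default 6).
#' @return Named list of [scenario_perturbation()] objects keyed by scenario.
#' @export
rcp_perturbations <- function(member_count = 6L) {
  mk <- function(id, dt, ps) {
    scenario_perturbation(id, warming_offset = dt, precip_scale = ps,
                          member_count = member_count, ramp = TRUE)
  }
  list(
    "RCP2.6" = mk("RCP2.6", 0.7, 1.00),
    "RCP4.5" = mk("RCP4.5", 1.4, 1.02),
    "RCP6.0" = mk("RCP6.0", 1.8, 1.03),
    "RCP8.5" = mk("RCP8.5", 3.0, 1.05)
  )
}

# Derive a reproducible 31-bit stream seed for one (cell, member) pair.
# Perturbation fields deliberately do not enter, so a perturbed series is the
# baseline series plus deterministic post-processing (perturbation linearity).
stream_seed <- function(seed, cell_index, member_id) {
  s <- (as.double(seed) %% 2147483647) * 48271 +
    as.double(cell_index) * 104729 +
    as.double(member_id) * 1299709
  as.integer(s %% 2147483647)
}

with_rng_stream <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate one cell's daily climate series
#'
#' Simulates a gap-free daily series of `n_years` whole calendar years for
#' one grid cell and ensemble member under a scenario perturbation. The same
#' `(config, perturbation, cell_id, member_id)` always yields the identical
#' series. The warming offset shifts `tmin` and `tmax` additively (ramped
#' linearly over the series when `perturbation$ramp` is `TRUE`); the
#' precipitation scale multiplies wet-day amounts. Neither perturbation
#' changes the underlying random stream, so perturbed series are day-by-day
#' comparable with their baseline.
#'
#' @param config A [weather_gen_config()].
#' @param perturbation A [scenario_perturbation()].
#' @param cell_id Cell to simulate (must appear in `config$cells`).
#' @param member_id Ensemble member index (>= 1).
#' @return A [climate_series()].
#' @export
generate_series <- function(config, perturbation = scenario_perturbation(),
                            cell_id = config$cells$cell_id[1],
                            member_id = 1L) {
  validate_weather_gen_config(config)
  ci <- match(as.character(cell_id), config$cells$cell_id)
  if (is.na(ci)) {
    stop(sprintf("cell_id '%s' is not in the configured grid", cell_id),
         call. = FALSE)
  }
  cell <- config$cells[ci, ]

  dates <- seq(as.Date(sprintf("%d-01-01", config$start_year)),
               as.Date(sprintf("%d-12-31", config$start_year + config$n_years - 1)),
               by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  # warmest near mid-January in the southern hemisphere, mid-July otherwise
  peak_doy <- if (cell$latitude < 0) 15 else 196
  phase <- cos(2 * pi * (doy - peak_doy) / 365.25)

  sim <- with_rng_stream(stream_seed(config$seed, ci, member_id), {
    anom <- as.numeric(stats::filter(stats::rnorm(n, 0, config$noise_sd),
                                     config$ar1, method = "recursive"))
    dr <- pmax(0.5, stats::rnorm(n, config$diurnal_range, config$diurnal_range_sd))
    u_occ <- stats::runif(n)
    wet <- logical(n)
    p11 <- config$p_wet_wet; p01 <- config$p_dry_wet
    state <- FALSE # start dry
    for (i in seq_len(n)) {
      p <- if (state) p11 else p01
      state <- u_occ[i] < p
      wet[i] <- state
    }
    amounts <- numeric(n)
    nwet <- sum(wet)
    if (nwet > 0) {
      amounts[wet] <- stats::rgamma(nwet, shape = config$rain_shape,
                                    scale = config$rain_scale)
    }
    rad_noise <- stats::rnorm(n, 0, config$radiation_sd)
    rh_noise <- stats::rnorm(n, 0, config$rh_sd)
    wind_noise <- stats::rnorm(n, 0, config$wind_sd)
    list(anom = anom, dr = dr, wet = wet, amounts = amounts,
         rad_noise = rad_noise, rh_noise = rh_noise, wind_noise = wind_noise)
  })

  offset <- if (perturbation$ramp && n > 1) {
    perturbation$warming_offset * (seq_len(n) - 1) / (n - 1)
  } else {
    rep(perturbation$warming_offset, n)
  }
  tmean <- cell$temp_mean + cell$temp_amplitude * phase + sim$anom + offset
  rad <- pmax(0, config$radiation_mean + config$radiation_amplitude * phase +
                sim$rad_noise)
  d <- tibble::tibble(
    date = dates,
    tmin = tmean - sim$dr / 2,
    tmax = tmean + sim$dr / 2,
    precip = sim$amounts * perturbation$precip_scale,
    radiation = rad,
    rel_humidity = pmin(100, pmax(0, config$rh_mean + sim$rh_noise)),
    wind = pmax(0, config$wind_mean + sim$wind_noise)
  )
  climate_series(d, cell_id = cell$cell_id, latitude = cell$latitude,
                 scenario_id = perturbation$scenario_id, member_id = member_id)
}

#' Generate a full grid of series across cells and members
#'
#' @param config A [weather_gen_config()].
#' @param perturbation A [scenario_perturbation()]; its `member_count` sets
#'   the default number of members.
#' @param members Number of ensemble members to generate.
#' @return A `climate_grid`: a list of [climate_series()], one per
#'   cell-member combination, with attributes `cells` and `scenario_id`.
#' @export
generate_grid <- function(config, perturbation = scenario_perturbation(),
                          members = perturbation$member_count) {
  out <- vector("list", nrow(config$cells) * members)
  k <- 1L
  for (m in seq_len(members)) {
    for (cid in config$cells$cell_id) {
      out[[k]] <- generate_series(config, perturbation, cid, m)
      k <- k + 1L
    }
  }
  structure(out, class = "climate_grid",
            cells = config$cells, scenario_id = perturbation$scenario_id)
}

#' Markov-chain stationary wet-day frequency
#'
#' Closed-form stationary probability of a wet day for the two-state
#' first-order occurrence chain: `p01 / (1 + p01 - p11)`.
#'
#' @param p_dry_wet,p_wet_wet Transition probabilities P(wet|dry), P(wet|wet).
#' @return Stationary wet-day probability.
#' @export
stationary_wet_frequency <- function(p_dry_wet, p_wet_wet) {
  p_dry_wet / (1 + p_dry_wet - p_wet_wet)
}
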