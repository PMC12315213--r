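#' Run the full risk pipeline on a synthetic grid
#'
#' End-to-end demonstration and integration surface: generates a gridded
#' multi-member daily climate under a transient warming scenario, then runs
#' every model stage — crop hazard counting and change maps, maize
#' phenology and maturity failure by time slice, the staged water-balance
#' PED with monthly demand profiles, fuzzy suitability scoring and change,
#' the facial-eczema-style logistic risk projection, and the dairy THI —
#' and writes each product as CSV into `out_dir` alongside a YAML run
#' configuration. Outputs are deterministic for a fixed seed.
#'
#' Because the scenario ramp runs across the whole series, the first and
#' last 20 years of the one run serve as the "baseline" and "future" time
#' slices; cross-member medians follow [summarize_slice()].
#'
#' @param out_dir Output directory (created; must not exist unless
#'   `overwrite = TRUE`).
#' @param seed Integer seed driving every random stream.
#' @param nx,ny Grid dimensions (default 10 x 10 cells).
#' @param n_years Years of daily weather per member (default 40).
#' @param members Ensemble members (default 3).
#' @param scenario_id One of the RCP labels understood by
#'   [rcp_perturbations()].
#' @param hazard_crops Hazard spec rows to map (default: wheat heat stress
#'   and peas frost).
#' @param overwrite Replace an existing `out_dir`.
#' @return Invisibly, a list with all product tibbles and the written file
#'   paths.
#' @export
run_pipeline <- function(out_dir, seed = 1, nx = 10, ny = 10,
                         n_years = 40, members = 3,
                         scenario_id = "RCP4.5",
                         hazard_crops = c("wheat", "peas"),
                         overwrite = FALSE) {
  if (dir.exists(out_dir)) {
    if (!overwrite) {
      stop(sprintf("'%s' already exists; set overwrite = TRUE", out_dir),
           call. = FALSE)
    }
    unlink(out_dir, recursive = TRUE)
  }
  dir.create(out_dir, recursive = TRUE)

  pert <- rcp_perturbations(member_count = members)[[scenario_id]]
  if (is.null(pert)) stop("unknown scenario_id", call. = FALSE)
  start_year <- 1981
  cfg <- weather_gen_config(seed = seed, n_years = n_years,
                            start_year = start_year,
                            cells = make_grid_cells(nx, ny))
  base_years <- c(start_year, start_year + 19)
  fut_years <- c(start_year + n_years - 20, start_year + n_years - 1)
  base_seasons <- c(start_year + 1, start_year + 19)
  fut_seasons <- c(start_year + n_years - 18, start_year + n_years - 1)

  grid <- generate_grid(cfg, pert, members = members)
  by_member <- split(grid, vapply(grid, function(s) s$member_id, 1L))

  specs <- builtin_hazard_specs()
  wanted <- tibble::tibble(
    crop_name = hazard_crops,
    hazard_kind = ifelse(hazard_crops == "peas", "frost", "heat_stress"))
  spec_rows <- dplyr::semi_join(specs, wanted,
                                by = c("crop_name", "hazard_kind"))

  files <- character()
  save_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files[[name]] <<- p
    p
  }

  # --- hazards: annual event days -> slice summaries -> change maps
  hazard_changes <- list()
  for (i in seq_len(nrow(spec_rows))) {
    sp <- spec_rows[i, ]
    ann <- dplyr::bind_rows(lapply(grid, function(s) {
      r <- hazard_annual_series(s, sp)
      r$member_id <- s$member_id
      r
    }))
    vals <- tibble::tibble(cell_id = ann$cell_id, member_id = ann$member_id,
                           year = ann$season_label, value = ann$event_days)
    b <- summarize_slice(vals, base_seasons)
    f <- summarize_slice(vals, fut_seasons)
    ch <- change_map(b, f, mode = "absolute")
    ch$crop_name <- sp$crop_name
    ch$hazard_kind <- sp$hazard_kind
    hazard_changes[[i]] <- ch
  }
  hazard_change <- dplyr::bind_rows(hazard_changes)
  save_csv(hazard_change, "hazard_change.csv")

  # --- phenology + water balance, per cell x member x season
  params <- crop_phenology_params()
  cells <- cfg$cells
  awc <- 60 + 60 * (seq_len(nrow(cells)) %% 5) / 4 # deterministic 60-120 mm
  soil_by_cell <- stats::setNames(
    lapply(seq_len(nrow(cells)), function(i) {
      soil_params(cells$cell_id[i], awc[i])
    }), cells$cell_id)

  season_rows <- list()
  demand_traces <- list()
  profile_cell <- cells$cell_id[1] # coldest-row sample cell for the profile
  for (s in grid) {
    soil <- soil_by_cell[[s$cell_id]]
    for (y in seq(start_year + 1, start_year + n_years - 1)) {
      res <- run_season_ped(s, params, soil, y)
      season_rows[[length(season_rows) + 1L]] <- tibble::tibble(
        cell_id = s$cell_id, member_id = s$member_id, year = y,
        matured = res$phenology$maturity_reached, ped = res$ped
      )
      if (s$cell_id == profile_cell) {
        slice_id <- if (y >= base_seasons[1] && y <= base_seasons[2]) {
          "baseline"
        } else if (y >= fut_seasons[1] && y <= fut_seasons[2]) {
          "future"
        } else {
          NA_character_
        }
        if (!is.na(slice_id)) {
          demand_traces[[length(demand_traces) + 1L]] <-
            list(slice = slice_id, res = res)
        }
      }
    }
  }
  seasons <- dplyr::bind_rows(season_rows)

  fail_summary <- function(sl, label) {
    v <- tibble::tibble(cell_id = seasons$cell_id,
                        member_id = seasons$member_id,
                        year = seasons$year,
                        value = as.numeric(!seasons$matured))
    out <- summarize_slice(v, sl)
    out$slice <- label
    out
  }
  maturity <- dplyr::bind_rows(fail_summary(base_seasons, "baseline"),
                               fail_summary(fut_seasons, "future"))
  save_csv(maturity[, c("cell_id", "slice", "central", "spread_min",
                        "spread_max", "n_members")], "maturity_failure.csv")

  ped_vals <- tibble::tibble(cell_id = seasons$cell_id,
                             member_id = seasons$member_id,
                             year = seasons$year, value = seasons$ped)
  ped_b <- summarize_slice(ped_vals, base_seasons)
  ped_f <- summarize_slice(ped_vals, fut_seasons)
  ped_change <- change_map(ped_b, ped_f, mode = "absolute")
  save_csv(ped_change, "ped_change.csv")

  prof <- function(slice_id) {
    monthly_demand_profile(
      lapply(Filter(function(t) t$slice == slice_id, demand_traces),
             function(t) t$res))
  }
  profile_b <- prof("baseline")
  profile_f <- prof("future")
  demand_profile <- dplyr::bind_rows(
    tibble::tibble(slice = "baseline", month = profile_b$month,
                   mean_demand = profile_b$mean_demand),
    tibble::tibble(slice = "future", month = profile_f$month,
                   mean_demand = profile_f$mean_demand)
  )
  save_csv(demand_profile, "monthly_demand.csv")

  # --- suitability on member-1 series
  rules <- default_suitability_rules("apple")
  suit <- function(sl) {
    dplyr::bind_rows(lapply(by_member[["1"]], function(s) {
      tibble::tibble(cell_id = s$cell_id, latitude = s$latitude,
                     score = suitability_score(attribute_summaries(s, sl),
                                               rules))
    }))
  }
  suit_b <- suit(base_years)
  suit_f <- suit(fut_years)
  suit_ch <- suitability_change(suit_b[, c("cell_id", "score")],
                                suit_f[, c("cell_id", "score")])
  suit_cells <- dplyr::inner_join(suit_ch$cells,
                                  suit_b[, c("cell_id", "latitude")],
                                  by = "cell_id")
  save_csv(suit_cells, "suitability_change.csv")

  # --- empirical risk: fit on synthetic records, project member-1 series
  records <- simulate_occurrence_records(5000, seed = seed + 101)
  model <- fit_occurrence_model(records)
  risk <- dplyr::bind_rows(lapply(by_member[["1"]], function(s) {
    rb <- project_risk(model, s, base_years)
    rf <- project_risk(model, s, fut_years)
    tibble::tibble(cell_id = s$cell_id,
                   risk_baseline = mean(rb$risk),
                   risk_future = mean(rf$risk))
  }))
  risk$change <- risk$risk_future - risk$risk_baseline
  save_csv(risk, "eczema_risk.csv")

  # --- THI exceedance on member-1 series
  thi_rows <- dplyr::bind_rows(lapply(by_member[["1"]], function(s) {
    ann <- thi_series(s)$annual
    bs <- ann$exceedance_days[ann$year >= base_years[1] &
                                ann$year <= base_years[2]]
    fs <- ann$exceedance_days[ann$year >= fut_years[1] &
                                ann$year <= fut_years[2]]
    tibble::tibble(cell_id = s$cell_id, baseline_days = mean(bs),
                   future_days = mean(fs))
  }))
  thi_rows$change <- thi_rows$future_days - thi_rows$baseline_days
  save_csv(thi_rows, "thi_exceedance.csv")

  run_cfg <- list(seed = seed, nx = nx, ny = ny, n_years = n_years,
                  members = members, scenario_id = scenario_id,
                  start_year = start_year,
                  baseline_years = as.list(base_years),
                  future_years = as.list(fut_years))
  yaml::write_yaml(run_cfg, file.path(out_dir, "run_config.yaml"))
  files[["run_config.yaml"]] <- file.path(out_dir, "run_config.yaml")

  invisible(list(
    hazard_change = hazard_change, maturity = maturity,
    ped_change = ped_change, demand_profile = demand_profile,
    demand_center = c(baseline = demand_weighted_center(profile_b),
                      future = demand_weighted_center(profile_f)),
    suitability = suit_cells, eczema = risk, thi = thi_rows,
    model = model, files = files
  ))
}
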