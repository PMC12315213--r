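#' Daily climate series container
#'
#' A `climate_series` bundles one grid cell's gap-free daily weather record
#' with its coordinates and provenance labels. It is the universal input of
#' every model in the package.
#'
#' @param data A data frame with columns `date` (Date), `tmin`, `tmax` (degC),
#'   `precip` (mm/day), `radiation` (MJ/m2/day), `rel_humidity` (%) and
#'   `wind` (m/s), one row per calendar day, dates strictly increasing and
#'   gap-free.
#' @param cell_id Character or integer identifier of the grid cell.
#' @param latitude Decimal degrees; negative values are southern hemisphere.
#' @param scenario_id Scenario label, e.g. `"RCP4.5"` or `"baseline"`.
#' @param member_id Integer ensemble-member index (pseudo-GCM stream).
#' @param validate Check invariants on construction (default `TRUE`).
#'
#' @return An object of class `climate_series`: a list with elements
#'   `cell_id`, `latitude`, `scenario_id`, `member_id` and `data` (a tibble).
#' @export
climate_series <- function(data, cell_id, latitude,
                           scenario_id = "baseline", member_id = 1L,
                           validate = TRUE) {
  data <- tibble::as_tibble(data)
  obj <- structure(
    list(
      cell_id = as.character(cell_id),
      latitude = as.numeric(latitude),
      scenario_id = as.character(scenario_id),
      member_id = as.integer(member_id),
      data = data
    ),
    class = "climate_series"
  )
  if (validate) validate_climate_series(obj)
  obj
}

series_vars <- function() {
  c("tmin", "tmax", "precip", "radiation", "rel_humidity", "wind")
}

#' Validate a daily climate series
#'
#' Checks the physical record invariants (`tmax >= tmin`, `precip >= 0`,
#' `0 <= rel_humidity <= 100`, `radiation >= 0`, `wind >= 0`) and the series
#' invariants (strictly increasing gap-free daily dates covering whole
#' calendar years).
#'
#' @param x A `climate_series`.
#' @param require_whole_years Require coverage of complete calendar years
#'   (default `TRUE`).
#' @return `x`, invisibly. Errors describe the first violated invariant.
#' @export
validate_climate_series <- function(x, require_whole_years = TRUE) {
  stopifnot(inherits(x, "climate_series"))
  d <- x$data
  needed <- c("date", series_vars())
  missing <- setdiff(needed, names(d))
  if (length(missing) > 0) {
    stop("climate series is missing variable(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!inherits(d$date, "Date")) stop("`date` must be a Date column", call. = FALSE)
  if (nrow(d) == 0) stop("climate series has no records", call. = FALSE)
  gaps <- diff(as.integer(d$date))
  if (any(gaps != 1)) {
    i <- which(gaps != 1)[1]
    stop(sprintf("dates must be gap-free daily; first gap after %s (next is %s)",
                 d$date[i], d$date[i + 1]), call. = FALSE)
  }
  if (require_whole_years) {
    first <- d$date[1]; last <- d$date[nrow(d)]
    if (format(first, "%m-%d") != "01-01" || format(last, "%m-%d") != "12-31") {
      stop("series must cover whole calendar years (01 Jan through 31 Dec)",
           call. = FALSE)
    }
  }
  bad <- function(cond, msg) if (any(cond, na.rm = TRUE)) {
    stop(sprintf("record invariant violated: %s (first on %s)",
                 msg, d$date[which(cond)[1]]), call. = FALSE)
  }
  if (anyNA(d[needed])) stop("climate series contains missing values", call. = FALSE)
  bad(d$tmax < d$tmin, "tmax < tmin")
  bad(d$precip < 0, "precip < 0")
  bad(d$rel_humidity < 0 | d$rel_humidity > 100, "rel_humidity outside [0, 100]")
  bad(d$radiation < 0, "radiation < 0")
  bad(d$wind < 0, "wind < 0")
  invisible(x)
}

#' @export
print.climate_series <- function(x, ...) {
  d <- x$data
  cat(sprintf(
    "<climate_series> cell %s (lat %.2f), %s member %d\n  %s .. %s (%d days)\n",
    x$cell_id, x$latitude, x$scenario_id, x$member_id,
    format(d$date[1]), format(d$date[nrow(d)]), nrow(d)))
  invisible(x)
}

#' Years covered by a series
#' @param x A `climate_series`.
#' @return Integer vector of calendar years present.
#' @export
series_years <- function(x) {
  sort(unique(as.integer(format(x$data$date, "%Y"))))
}

#' Shift the temperature fields of a series
#'
#' Adds a constant offset to `tmin` and `tmax`, leaving all other fields
#' untouched. Used for perturbation experiments; applying offsets `a` then
#' `b` equals a single offset `a + b`.
#'
#' @param x A `climate_series`.
#' @param offset Degrees Celsius to add.
#' @return A new `climate_series`.
#' @export
shift_temperature <- function(x, offset) {
  x$data$tmin <- x$data$tmin + offset
  x$data$tmax <- x$data$tmax + offset
  x
}
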