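#' Monthly climate covariates for occurrence models
#'
#' The default covariate builder for empirical disease-risk models: one row
#' per calendar month with the monthly mean daily temperature
#' (`(tmin + tmax)/2` averaged over days, degC) and total rainfall (mm).
#'
#' @param series A [climate_series()].
#' @param slice Optional integer `c(first, last)` calendar years to keep.
#' @return Tibble: `cell_id`, `period` (`"YYYY-MM"`), `year`, `month`,
#'   `temp`, `rain`.
#' @export
monthly_covariates <- function(series, slice = NULL) {
  d <- series$data
  y <- as.integer(format(d$date, "%Y"))
  if (!is.null(slice)) {
    keep <- y >= slice[1] & y <= slice[2]
    d <- d[keep, ]; y <- y[keep]
  }
  m <- as.integer(format(d$date, "%m"))
  key <- sprintf("%d-%02d", y, m)
  tmean <- (d$tmin + d$tmax) / 2
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(key = key, year = y, month = m,
                                   tmean = tmean, precip = d$precip),
                    .data$key, .data$year, .data$month),
    temp = mean(.data$tmean), rain = sum(.data$precip), .groups = "drop"
  )
  tibble::tibble(cell_id = series$cell_id, period = agg$key,
                 year = agg$year, month = agg$month,
                 temp = agg$temp, rain = agg$rain)
}

#' Fit a logistic occurrence model to climate covariates
#'
#' Maximum-likelihood logistic regression of a binary occurrence outcome
#' (e.g. observed fungal sporulation risk periods) on climate covariates,
#' the structure used for facial-eczema-type animal-health risks. The fit
#' is deterministic given the records and invariant to record order.
#'
#' @param records Data frame with a binary `occurrence` column (0/1 or
#'   logical) and one column per covariate.
#' @param covariates Character vector of covariate column names
#'   (default `c("temp", "rain")`).
#' @return A `risk_model` list: `intercept`, `coefficients` (named),
#'   `se` (standard errors), `link = "logit"`, `deviance`, `n`, and
#'   `training_range` (per-covariate min/max, used to flag extrapolation).
#' @export
fit_occurrence_model <- function(records, covariates = c("temp", "rain")) {
  records <- as.data.frame(records)
  missing <- setdiff(c("occurrence", covariates), names(records))
  if (length(missing) > 0) {
    stop("records are missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  y <- as.numeric(records$occurrence)
  if (!all(y %in% c(0, 1))) {
    stop("occurrence must be binary (0/1)", call. = FALSE)
  }
  if (length(y) < 30) stop("at least 30 records are required", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("both outcome classes must be present in the records", call. = FALSE)
  }
  f <- stats::as.formula(paste("occurrence ~", paste(covariates, collapse = " + ")))
  records$occurrence <- y
  fit <- suppressWarnings(stats::glm(f, family = stats::binomial(), data = records))
  cf <- stats::coef(fit)
  if (any(!is.finite(cf)) || any(abs(cf[covariates]) > 50) || !fit$converged) {
    worst <- covariates[which.max(abs(cf[covariates]))]
    stop(sprintf("degenerate logistic fit (separation or collinearity), covariate '%s'",
                 worst), call. = FALSE)
  }
  se <- sqrt(diag(stats::vcov(fit)))
  rng <- lapply(covariates, function(v) range(records[[v]]))
  names(rng) <- covariates
  structure(
    list(intercept = unname(cf[1]),
         coefficients = cf[covariates],
         se = se[c("(Intercept)", covariates)],
         link = "logit", deviance = stats::deviance(fit),
         n = length(y), training_range = rng),
    class = "risk_model"
  )
}

#' Project occurrence risk onto a climate series
#'
#' Builds the model's covariates from the series over a time slice and
#' returns the per-period risk probability through the logistic link.
#' Covariates far outside the training range (beyond the range widened by
#' its own width on either side) raise an extrapolation warning; the value
#' is still returned.
#'
#' @param model A `risk_model` from [fit_occurrence_model()].
#' @param series A [climate_series()].
#' @param slice Optional integer `c(first, last)` calendar years.
#' @return Tibble from [monthly_covariates()] with an added `risk` column,
#'   probabilities strictly in (0, 1).
#' @export
project_risk <- function(model, series, slice = NULL) {
  cov <- monthly_covariates(series, slice)
  eta <- rep(model$intercept, nrow(cov))
  for (v in names(model$coefficients)) {
    x <- cov[[v]]
    r <- model$training_range[[v]]
    w <- r[2] - r[1]
    if (any(x < r[1] - w | x > r[2] + w)) {
      warning(sprintf("covariate '%s' extrapolates beyond 3x the training range",
                      v), call. = FALSE)
    }
    eta <- eta + model$coefficients[[v]] * x
  }
  cov$risk <- stats::plogis(eta)
  cov
}

#' Temperature-humidity index for livestock heat stress
#'
#' The Davis-lineage daily index
#' `THI = 0.8 T + RH/100 (T - 14.4) + 46.4` computed from daily mean
#' temperature `T = (tmin + tmax)/2` and relative humidity `RH` (%).
#'
#' @param temp Daily mean temperature (degC).
#' @param rel_humidity Relative humidity (%).
#' @return THI (index units), vectorised.
#' @export
thi <- function(temp, rel_humidity) {
  0.8 * temp + rel_humidity / 100 * (temp - 14.4) + 46.4
}

#' Daily THI series and annual exceedance counts
#'
#' @param series A [climate_series()] (must carry `rel_humidity`).
#' @param threshold Heat-stress threshold in THI units (default 68).
#' @return List: `daily` (tibble `date`, `thi`, `exceedance`) and `annual`
#'   (tibble `year`, `exceedance_days`).
#' @export
thi_series <- function(series, threshold = 68) {
  d <- series$data
  v <- thi((d$tmin + d$tmax) / 2, d$rel_humidity)
  daily <- tibble::tibble(date = d$date, thi = v,
                          exceedance = v > threshold)
  yr <- as.integer(format(d$date, "%Y"))
  annual <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(year = yr, exc = daily$exceedance),
                    .data$year),
    exceedance_days = sum(.data$exc), .groups = "drop"
  )
  list(daily = daily, annual = annual)
}

#' Simulate binary occurrence records from known coefficients
#'
#' Synthetic training data for parameter-recovery experiments: covariates
#' are drawn from plausible monthly climate ranges and outcomes from a
#' Bernoulli with logistic probability.
#'
#' @param n Number of records.
#' @param beta0 Intercept.
#' @param beta_temp,beta_rain True covariate coefficients.
#' @param seed Integer seed.
#' @return Tibble: `occurrence`, `temp`, `rain`.
#' @export
simulate_occurrence_records <- function(n, beta0 = -2, beta_temp = 0.3,
                                        beta_rain = 0.01, seed = 1) {
  with_rng_stream(seed, {
    temp <- stats::runif(n, 2, 25)
    rain <- stats::rgamma(n, shape = 2, scale = 40)
    p <- stats::plogis(beta0 + beta_temp * temp + beta_rain * rain)
    tibble::tibble(occurrence = stats::rbinom(n, 1, p), temp = temp,
                   rain = rain)
  })
}
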