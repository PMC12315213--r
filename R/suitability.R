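#' Trapezoidal membership value
#'
#' Piecewise-linear fuzzy membership with breakpoints `a <= b <= c <= d`:
#' 0 outside `[a, d]`, 1 on `[b, c]`, linear in between. One-sided
#' (monotone) memberships are expressed by pushing the unused breakpoints to
#' very large magnitudes.
#'
#' @param x Attribute value(s).
#' @param a,b,c,d Breakpoints in attribute units.
#' @return Membership in `[0, 1]`, vectorised over `x`.
#' @export
membership_trapezoid <- function(x, a, b, c, d) {
  if (!(a <= b && b <= c && c <= d)) {
    stop("breakpoints must satisfy a <= b <= c <= d", call. = FALSE)
  }
  out <- numeric(length(x))
  rising <- x >= a & x < b
  out[rising] <- (x[rising] - a) / (b - a)
  out[x >= b & x <= c] <- 1
  falling <- x > c & x <= d
  out[falling] <- (d - x[falling]) / (d - c)
  out
}

#' Construct a fuzzy suitability rule set
#'
#' One trapezoidal membership per climate attribute plus a combiner:
#' `"min"` (Liebig-style limiting factor, the default), `"product"`, or
#' `"weighted_geometric"` (geometric mean with positive weights summing
#' to 1).
#'
#' @param crop_name Crop label.
#' @param memberships Data frame with columns `attribute`, `a`, `b`, `c`,
#'   `d` (one row per attribute).
#' @param combiner Combiner name.
#' @param weights Named weights (one per attribute), required for
#'   `"weighted_geometric"`.
#' @return A `suitability_rules` list.
#' @export
suitability_rules <- function(crop_name, memberships,
                              combiner = c("min", "product",
                                           "weighted_geometric"),
                              weights = NULL) {
  combiner <- match.arg(combiner)
  memberships <- tibble::as_tibble(memberships)
  if (nrow(memberships) < 1) {
    stop("at least one attribute membership is required", call. = FALSE)
  }
  stopifnot(all(c("attribute", "a", "b", "c", "d") %in% names(memberships)))
  for (i in seq_len(nrow(memberships))) {
    m <- memberships[i, ]
    if (!(m$a <= m$b && m$b <= m$c && m$c <= m$d)) {
      stop(sprintf("membership for '%s' must satisfy a <= b <= c <= d",
                   m$attribute), call. = FALSE)
    }
  }
  if (combiner == "weighted_geometric") {
    if (is.null(weights) ||
        !setequal(names(weights), memberships$attribute)) {
      stop("weighted_geometric needs one named weight per attribute",
           call. = FALSE)
    }
    if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-8) {
      stop("weights must be positive and sum to 1", call. = FALSE)
    }
  }
  structure(list(crop_name = crop_name, memberships = memberships,
                 combiner = combiner, weights = weights),
            class = "suitability_rules")
}

#' Illustrative default rule sets
#'
#' Non-calibrated example rule sets for a pipfruit-style crop (`"apple"`)
#' and a frost-tender vine crop (`"kiwifruit"`), combining seasonal
#' growing-degree-days, frost days, heat-stress days and annual rainfall.
#' They exercise the framework and the qualitative cold-limited /
#' heat-limited behaviour; they are not a published calibration and should
#' be replaced with crop-specific rules for real assessments.
#'
#' @param crop `"apple"` or `"kiwifruit"`.
#' @return A [suitability_rules()] object.
#' @export
default_suitability_rules <- function(crop = c("apple", "kiwifruit")) {
  crop <- match.arg(crop)
  big <- 1e9
  if (crop == "apple") {
    m <- dplyr::bind_rows(
      tibble::tibble(attribute = "gdd", a = 800, b = 1100, c = 1900, d = 2600),
      tibble::tibble(attribute = "frost_days", a = -big, b = -big, c = 15, d = 40),
      tibble::tibble(attribute = "heat_days", a = -big, b = -big, c = 10, d = 35),
      tibble::tibble(attribute = "rainfall", a = 350, b = 550, c = 1600, d = 2800)
    )
  } else {
    m <- dplyr::bind_rows(
      tibble::tibble(attribute = "gdd", a = 1200, b = 1600, c = 2400, d = 3200),
      tibble::tibble(attribute = "frost_days", a = -big, b = -big, c = 5, d = 20),
      tibble::tibble(attribute = "heat_days", a = -big, b = -big, c = 15, d = 45),
      tibble::tibble(attribute = "rainfall", a = 500, b = 800, c = 1800, d = 3000)
    )
  }
  suitability_rules(crop, m)
}

#' Mean-annual climate attribute summaries for suitability scoring
#'
#' Deterministic per-cell summaries over the calendar years of a time
#' slice: annual growing-degree-day sum (`gdd`), frost-day count
#' (`frost_days`, `tmin <` threshold), heat-stress-day count (`heat_days`,
#' `tmax >` threshold) and total rainfall (`rainfall`, mm), each averaged
#' over the slice years.
#'
#' @param series A [climate_series()].
#' @param slice Integer `c(first, last)` calendar years.
#' @param base_temp,upper_cutoff_temp GDD parameters (degC).
#' @param frost_threshold Frost day if `tmin <` this value (degC).
#' @param heat_threshold Heat day if `tmax >` this value (degC).
#' @return Named numeric vector `gdd`, `frost_days`, `heat_days`, `rainfall`.
#' @export
attribute_summaries <- function(series, slice, base_temp = 8,
                                upper_cutoff_temp = 30,
                                frost_threshold = 0, heat_threshold = 30) {
  yrs <- series_years(series)
  want <- seq(slice[1], slice[2])
  if (!all(want %in% yrs)) {
    stop("series does not cover slice years: ",
         paste(setdiff(want, yrs), collapse = ", "), call. = FALSE)
  }
  d <- series$data
  y <- as.integer(format(d$date, "%Y"))
  keep <- y %in% want
  d <- d[keep, ]; y <- y[keep]
  tt <- daily_thermal_time(d$tmin, d$tmax, base_temp, upper_cutoff_temp)
  n <- length(want)
  c(gdd = sum(tt) / n,
    frost_days = sum(d$tmin < frost_threshold) / n,
    heat_days = sum(d$tmax > heat_threshold) / n,
    rainfall = sum(d$precip) / n)
}

#' Fuzzy suitability score
#'
#' Evaluates each attribute's trapezoidal membership and combines them into
#' a single suitability score in `[0, 1]` (0 = poor, 1 = good).
#'
#' @param attributes Named numeric vector; must contain every attribute the
#'   rule set uses.
#' @param rules A [suitability_rules()].
#' @return Score in `[0, 1]`.
#' @export
suitability_score <- function(attributes, rules) {
  m <- rules$memberships
  missing <- setdiff(m$attribute, names(attributes))
  if (length(missing) > 0) {
    stop("missing attribute(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  mu <- vapply(seq_len(nrow(m)), function(i) {
    membership_trapezoid(attributes[[m$attribute[i]]],
                         m$a[i], m$b[i], m$c[i], m$d[i])
  }, 1)
  switch(rules$combiner,
         min = min(mu),
         product = prod(mu),
         weighted_geometric = {
           w <- rules$weights[m$attribute]
           prod(mu^w)
         })
}

#' Discretise a continuous suitability score
#'
#' Left-closed class convention: `[0, 0.25)` unsuited, `[0.25, 0.5)`
#' marginal, `[0.5, 0.75)` suited, `[0.75, 1]` well_suited.
#'
#' @param score Numeric score(s) in `[0, 1]`.
#' @return Factor with the four ordered class levels.
#' @export
suitability_class <- function(score) {
  cut(score, breaks = c(-Inf, 0.25, 0.5, 0.75, Inf),
      labels = c("unsuited", "marginal", "suited", "well_suited"),
      right = FALSE, ordered_result = TRUE)
}

#' Change in suitability between two periods
#'
#' Per-cell score delta (in `[-1, 1]`) plus the class-transition tally
#' between the discretised baseline and future scores.
#'
#' @param baseline,future Tibbles with columns `cell_id` and `score`,
#'   covering the same cells.
#' @return List: `cells` (tibble with `cell_id`, `baseline`, `future`,
#'   `delta`, `class_baseline`, `class_future`) and `transitions` (a
#'   contingency table of baseline vs future classes).
#' @export
suitability_change <- function(baseline, future) {
  extra <- c(setdiff(baseline$cell_id, future$cell_id),
             setdiff(future$cell_id, baseline$cell_id))
  if (length(extra) > 0) {
    stop("baseline and future cover different cells: ",
         paste(sort(unique(extra)), collapse = ", "), call. = FALSE)
  }
  cells <- dplyr::inner_join(
    dplyr::rename(baseline, baseline = "score"),
    dplyr::rename(future, future = "score"),
    by = "cell_id"
  )
  cells$delta <- cells$future - cells$baseline
  cells$class_baseline <- suitability_class(cells$baseline)
  cells$class_future <- suitability_class(cells$future)
  list(cells = cells,
       transitions = table(baseline = cells$class_baseline,
                           future = cells$class_future))
}
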