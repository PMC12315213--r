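#' Two-stage time-slice / ensemble summary
#'
#' The single normative aggregation order used across all products: first a
#' within-slice statistic per ensemble member (mean over the slice years by
#' default), then a cross-member central value (median by convention) with
#' its spread. Every member must cover every slice year for every cell.
#'
#' @param values Tibble with columns `cell_id`, `member_id`, `year`,
#'   `value` (one annual value per cell-member-year).
#' @param slice Integer `c(first, last)` years (>= 2 years; 20 by
#'   convention).
#' @param statistic Within-slice statistic: `"mean"` (default), `"median"`,
#'   or a function.
#' @param central Cross-member central statistic: `"median"` (default) or
#'   `"mean"`.
#' @return Tibble: `cell_id`, `slice_start`, `slice_end`, `statistic_name`,
#'   `central`, `spread_min`, `spread_max`, `n_members`, `member_values`
#'   (list column, one within-slice value per member).
#' @export
summarize_slice <- function(values, slice, statistic = "mean",
                            central = c("median", "mean")) {
  central <- match.arg(central)
  if (length(slice) != 2 || slice[2] - slice[1] + 1 < 2) {
    stop("slice must span at least 2 years", call. = FALSE)
  }
  yrs <- seq(slice[1], slice[2])
  stat_name <- if (is.character(statistic)) statistic else "custom"
  stat_fun <- if (is.character(statistic)) {
    match.fun(statistic)
  } else {
    statistic
  }
  v <- values[values$year %in% yrs, ]
  combos <- unique(v[, c("cell_id", "member_id")])
  for (i in seq_len(nrow(combos))) {
    have <- v$year[v$cell_id == combos$cell_id[i] &
                     v$member_id == combos$member_id[i]]
    miss <- setdiff(yrs, have)
    if (length(miss) > 0) {
      stop(sprintf("member %s of cell %s is missing year(s) %s",
                   combos$member_id[i], combos$cell_id[i],
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  per_member <- dplyr::summarise(
    dplyr::group_by(v, .data$cell_id, .data$member_id),
    member_value = stat_fun(.data$value), .groups = "drop"
  )
  cen_fun <- match.fun(central)
  out <- dplyr::summarise(
    dplyr::group_by(per_member, .data$cell_id),
    central = cen_fun(.data$member_value),
    spread_min = min(.data$member_value),
    spread_max = max(.data$member_value),
    n_members = dplyr::n(),
    member_values = list(.data$member_value),
    .groups = "drop"
  )
  out$slice_start <- slice[1]
  out$slice_end <- slice[2]
  out$statistic_name <- stat_name
  out[, c("cell_id", "slice_start", "slice_end", "statistic_name",
          "central", "spread_min", "spread_max", "n_members",
          "member_values")]
}

#' Per-cell change map between two time-slice summaries
#'
#' `absolute` mode returns `future - baseline`; `proportional` returns
#' `100 * (future - baseline) / baseline` (%), flagging cells with a zero
#' baseline as undefined (`NA` change, `undefined = TRUE`) rather than
#' returning infinities.
#'
#' @param baseline,future [summarize_slice()] outputs over the same cells
#'   and statistic.
#' @param mode `"absolute"` or `"proportional"`.
#' @return Tibble: `cell_id`, `baseline`, `future`, `change`, `undefined`.
#' @export
change_map <- function(baseline, future,
                       mode = c("absolute", "proportional")) {
  mode <- match.arg(mode)
  extra <- c(setdiff(baseline$cell_id, future$cell_id),
             setdiff(future$cell_id, baseline$cell_id))
  if (length(extra) > 0) {
    stop("baseline and future cover different cells: ",
         paste(sort(unique(extra)), collapse = ", "), call. = FALSE)
  }
  if (!identical(baseline$statistic_name[1], future$statistic_name[1])) {
    stop("baseline and future summarise different statistics", call. = FALSE)
  }
  b <- baseline[, c("cell_id", "central")]
  names(b)[2] <- "baseline"
  f <- future[, c("cell_id", "central")]
  names(f)[2] <- "future"
  out <- dplyr::inner_join(b, f, by = "cell_id")
  if (mode == "absolute") {
    out$change <- out$future - out$baseline
    out$undefined <- FALSE
  } else {
    out$undefined <- out$baseline == 0
    out$change <- ifelse(out$undefined, NA_real_,
                         100 * (out$future - out$baseline) / out$baseline)
  }
  out
}
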