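#' Write daily climate series to disk
#'
#' Two plain-text dialects are supported:
#'
#' * `"csv"` — long format, one row per cell-day, with the mandatory columns
#'   `cell_id, date, tmin, tmax, precip, radiation, rel_humidity, wind`
#'   (ISO-8601 dates) plus provenance columns `latitude, scenario_id,
#'   member_id`.
#' * `"grid"` — a gridded dialect: a directory holding one CSV matrix per
#'   variable and member (rows = dates, columns = cells) and a `meta.yaml`
#'   file carrying dimensions, cell latitudes, units, scenario and member
#'   ids. This is the package's text analogue of a CF-style gridded file.
#'
#' Both dialects round-trip exactly: `read_series(write_series(x))`
#' reproduces every value, and the two dialects of the same data read back
#' identical.
#'
#' @param x A [climate_series()] or a list of them (e.g. a `climate_grid`).
#' @param path Output file (`csv`) or directory (`grid`).
#' @param format `"csv"` or `"grid"`.
#' @param overwrite Allow replacing an existing file/directory
#'   (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path, format = c("csv", "grid"),
                         overwrite = FALSE) {
  format <- match.arg(format)
  if (inherits(x, "climate_series")) x <- list(x)
  if (file.exists(path) && !overwrite) {
    stop(sprintf("'%s' already exists; set overwrite = TRUE to replace it", path),
         call. = FALSE)
  }
  if (format == "csv") {
    rows <- lapply(x, function(s) {
      d <- s$data
      tibble::tibble(
        cell_id = s$cell_id, date = format(d$date, "%Y-%m-%d"),
        tmin = d$tmin, tmax = d$tmax, precip = d$precip,
        radiation = d$radiation, rel_humidity = d$rel_humidity, wind = d$wind,
        latitude = s$latitude, scenario_id = s$scenario_id,
        member_id = s$member_id
      )
    })
    utils::write.csv(dplyr::bind_rows(rows), path, row.names = FALSE,
                     quote = FALSE)
  } else {
    if (file.exists(path) && overwrite) unlink(path, recursive = TRUE)
    dir.create(path, recursive = TRUE)
    key <- vapply(x, function(s) paste0(s$cell_id, "\r", s$member_id), "")
    if (anyDuplicated(key)) {
      stop("grid dialect requires unique (cell_id, member_id) pairs", call. = FALSE)
    }
    dates <- x[[1]]$data$date
    for (s in x) {
      if (!identical(s$data$date, dates)) {
        stop("grid dialect requires all series to share the same dates",
             call. = FALSE)
      }
    }
    members <- sort(unique(vapply(x, function(s) s$member_id, 1L)))
    cells <- unique(dplyr::bind_rows(lapply(x, function(s) {
      tibble::tibble(cell_id = s$cell_id, latitude = s$latitude)
    })))
    meta <- list(
      dialect = "agroclimr-grid-1",
      scenario_id = x[[1]]$scenario_id,
      start_date = format(dates[1], "%Y-%m-%d"),
      n_days = length(dates),
      members = as.list(members),
      units = list(tmin = "degC", tmax = "degC", precip = "mm/day",
                   radiation = "MJ/m2/day", rel_humidity = "%", wind = "m/s"),
      cells = lapply(seq_len(nrow(cells)), function(i) {
        list(cell_id = cells$cell_id[i], latitude = cells$latitude[i])
      })
    )
    yaml::write_yaml(meta, file.path(path, "meta.yaml"))
    for (m in members) {
      sel <- x[vapply(x, function(s) s$member_id == m, TRUE)]
      ids <- vapply(sel, function(s) s$cell_id, "")
      for (v in series_vars()) {
        mat <- vapply(sel, function(s) s$data[[v]], numeric(length(dates)))
        df <- as.data.frame(mat)
        names(df) <- ids
        df <- cbind(date = format(dates, "%Y-%m-%d"), df)
        utils::write.csv(df, file.path(path, sprintf("%s_m%d.csv", v, m)),
                         row.names = FALSE, quote = FALSE)
      }
    }
  }
  invisible(path)
}

#' Read daily climate series from disk
#'
#' Counterpart of [write_series()]. Errors name any missing mandatory
#' variable column and report the first date gap if the stored series is not
#' contiguous.
#'
#' @param path File (`csv` dialect) or directory (`grid` dialect).
#' @param format `"csv"` or `"grid"`; guessed from `path` when omitted.
#' @return A list of [climate_series()] (class `climate_grid`), ordered by
#'   member then cell.
#' @export
read_series <- function(path, format = NULL) {
  if (is.null(format)) format <- if (dir.exists(path)) "grid" else "csv"
  format <- match.arg(format, c("csv", "grid"))
  if (!file.exists(path)) stop(sprintf("'%s' does not exist", path), call. = FALSE)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    needed <- c("cell_id", "date", series_vars())
    missing <- setdiff(needed, names(df))
    if (length(missing) > 0) {
      stop("file is missing required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (!"latitude" %in% names(df)) df$latitude <- NA_real_
    if (!"scenario_id" %in% names(df)) df$scenario_id <- "unknown"
    if (!"member_id" %in% names(df)) df$member_id <- 1L
    df$date <- as.Date(df$date)
    parts <- split(df, list(df$member_id, df$cell_id), drop = TRUE)
    out <- lapply(parts, function(p) {
      p <- p[order(p$date), ]
      s <- climate_series(
        p[, c("date", series_vars())],
        cell_id = p$cell_id[1], latitude = p$latitude[1],
        scenario_id = p$scenario_id[1], member_id = p$member_id[1],
        validate = FALSE
      )
      validate_climate_series(s, require_whole_years = FALSE)
      s
    })
    ord <- order(vapply(out, function(s) s$member_id, 1L),
                 vapply(out, function(s) s$cell_id, ""))
    structure(out[ord], class = "climate_grid")
  } else {
    meta <- yaml::read_yaml(file.path(path, "meta.yaml"))
    dates <- seq(as.Date(meta$start_date), by = "day", length.out = meta$n_days)
    lat <- stats::setNames(
      vapply(meta$cells, function(c) as.numeric(c$latitude), 1),
      vapply(meta$cells, function(c) as.character(c$cell_id), "")
    )
    out <- list()
    for (m in unlist(meta$members)) {
      vals <- lapply(series_vars(), function(v) {
        f <- file.path(path, sprintf("%s_m%d.csv", v, m))
        if (!file.exists(f)) {
          stop(sprintf("grid dialect is missing required column(s): %s (file %s)",
                       v, basename(f)), call. = FALSE)
        }
        utils::read.csv(f, check.names = FALSE, stringsAsFactors = FALSE)
      })
      names(vals) <- series_vars()
      ids <- setdiff(names(vals[[1]]), "date")
      for (cid in ids) {
        d <- tibble::tibble(date = dates)
        for (v in series_vars()) d[[v]] <- vals[[v]][[cid]]
        s <- climate_series(d, cell_id = cid, latitude = lat[[cid]],
                            scenario_id = meta$scenario_id, member_id = m,
                            validate = FALSE)
        validate_climate_series(s, require_whole_years = FALSE)
        out[[length(out) + 1L]] <- s
      }
    }
    structure(out, class = "climate_grid")
  }
}
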