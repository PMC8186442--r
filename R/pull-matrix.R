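#' Construct and validate a pull matrix
#'
#' A pull matrix is the central container of rsvstab: a wide tibble with one
#' row per geographic series (city, region or country) and one column per
#' collection day, holding the relative search volume (RSV, 0-100) that the
#' series showed when the same query/period/geography dataset was downloaded
#' on that day. Missing cells (`NA`) mean the series did not appear in that
#' day's pull; they are evidence of instability and are never imputed.
#'
#' @param x A data frame whose first column (`unit`) holds unique series
#'   names and whose remaining columns are named with ISO-8601 dates
#'   (`YYYY-MM-DD`) and hold numeric RSVs in `[0, 100]` or `NA`.
#' @param query,geo_scope Free-text metadata: the search query and geography
#'   the pulls were made for (e.g. `"IT"`, `"world"`).
#' @param unit_level One of `"city"`, `"region"`, `"country"`, or `NA`.
#' @param period_start,period_end The investigation period the RSVs cover
#'   (the fixed time window of the query, not the collection days).
#'
#' @return A tibble of subclass `pull_matrix` carrying the metadata as
#'   attributes.
#' @examples
#' pm <- as_pull_matrix(data.frame(
#'   unit = c("A", "B"),
#'   `2020-12-14` = c(100, 80),
#'   `2020-12-15` = c(97, NA),
#'   check.names = FALSE
#' ))
#' collection_dates(pm)
#' @export
as_pull_matrix <- function(x, query = NULL, geo_scope = NULL, unit_level = NULL,
                           period_start = NULL, period_end = NULL) {
  if (inherits(x, "pull_matrix") && is.null(query) && is.null(geo_scope) &&
      is.null(unit_level) && is.null(period_start) && is.null(period_end)) {
    return(x)
  }
  if (!is.data.frame(x) || ncol(x) < 2L) {
    stop_rsvstab("a pull matrix needs a unit column plus at least one collection date",
                 "format")
  }
  old <- if (inherits(x, "pull_matrix")) pull_meta(x) else NULL

  x <- as_tibble(x)
  names(x)[1L] <- "unit"
  x$unit <- trimws(as.character(x$unit))

  dates <- parse_iso_date(names(x)[-1L])
  if (anyNA(dates)) {
    stop_rsvstab(
      paste0("collection-date headers must be ISO-8601 dates; offending: ",
             paste(names(x)[-1L][is.na(dates)], collapse = ", ")),
      "format")
  }
  if (is.unsorted(dates, strictly = TRUE)) {
    stop_rsvstab("collection dates must be strictly increasing with no duplicates",
                 "validation")
  }
  if (any(!nzchar(x$unit)) || anyNA(x$unit)) {
    stop_rsvstab("every series needs a non-empty unit name", "validation")
  }
  if (anyDuplicated(x$unit)) {
    stop_rsvstab(
      paste0("duplicate unit name(s): ",
             paste(unique(x$unit[duplicated(x$unit)]), collapse = ", ")),
      "validation")
  }
  for (j in seq_along(x)[-1L]) {
    v <- x[[j]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(as.character(v)))
      if (anyNA(v) & !anyNA(x[[j]])) {
        stop_rsvstab(paste0("non-numeric RSV cell in column ", names(x)[j]), "validation")
      }
      x[[j]] <- v
    }
    bad <- which(!is.na(v) & (v < 0 | v > 100))
    if (length(bad)) {
      stop_rsvstab(
        paste0("RSV out of [0, 100]: unit '", x$unit[bad[1L]], "', column ",
               names(x)[j], " (value ", v[bad[1L]], ")"),
        "validation")
    }
  }

  meta <- list(
    query        = query        %||% old$query        %||% NA_character_,
    geo_scope    = geo_scope    %||% old$geo_scope    %||% NA_character_,
    unit_level   = unit_level   %||% old$unit_level   %||% NA_character_,
    period_start = period_start %||% old$period_start %||% as.Date(NA),
    period_end   = period_end   %||% old$period_end   %||% as.Date(NA)
  )
  if (!is.na(meta$unit_level) &&
      !meta$unit_level %in% c("city", "region", "country")) {
    stop_rsvstab("unit_level must be one of city, region, country", "validation")
  }

  structure(x,
            class = c("pull_matrix", class(as_tibble(x))),
            rsv_meta = meta)
}

pull_meta <- function(pm) attr(pm, "rsv_meta", exact = TRUE)

#' Collection dates and unit names of a pull matrix
#'
#' @param pm A [as_pull_matrix()] object (or a data frame coercible to one).
#' @return `collection_dates()`: the ordered `Date` vector of pull days.
#'   `pull_units()`: the character vector of series names, in row order.
#' @export
collection_dates <- function(pm) {
  pm <- as_pull_matrix(pm)
  parse_iso_date(names(pm)[-1L])
}

#' @rdname collection_dates
#' @export
pull_units <- function(pm) as_pull_matrix(pm)$unit

# numeric matrix view, units x dates
rsv_matrix <- function(pm) {
  m <- as.matrix(as.data.frame(pm)[-1L])
  rownames(m) <- pm$unit
  m
}

#' @export
print.pull_matrix <- function(x, ...) {
  meta <- pull_meta(x)
  n_miss <- sum(is.na(rsv_matrix(x)))
  cat(sprintf("# pull_matrix: %d series x %d collection days (%d missing cells)\n",
              nrow(x), ncol(x) - 1L, n_miss))
  if (!is.na(meta$query)) {
    cat(sprintf("# query: %s | geo: %s | level: %s\n",
                meta$query, meta$geo_scope, meta$unit_level))
  }
  print(as_tibble(x), ...)
  invisible(x)
}

#' Tidiers for pull matrices
#'
#' `tidy()` pivots the wide series-by-day grid into a long tibble (one row
#' per series and collection day, missing cells kept as `NA`), the natural
#' input for further dplyr/ggplot2 work. `glance()` gives a one-row summary.
#'
#' @param x A `pull_matrix`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pull_matrix <- function(x, ...) {
  out <- tidyr::pivot_longer(as_tibble(x), -"unit",
                             names_to = "date", values_to = "rsv")
  out$date <- parse_iso_date(out$date)
  out
}

#' @rdname tidy.pull_matrix
#' @export
glance.pull_matrix <- function(x, ...) {
  m <- rsv_matrix(x)
  meta <- pull_meta(x)
  tibble(
    n_series = nrow(x),
    n_days = ncol(m),
    n_missing_cells = sum(is.na(m)),
    n_complete_series = sum(rowSums(is.na(m)) == 0L),
    query = meta$query,
    geo_scope = meta$geo_scope
  )
}

#' Plot a pull matrix
#'
#' `type = "series"` draws each series' RSV across collection days (gaps
#' where a pull omitted the series); `type = "missingness"` draws the
#' presence/absence grid, the pattern the anomaly audit quantifies.
#'
#' @param object A `pull_matrix`.
#' @param type `"series"` or `"missingness"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pull_matrix <- function(object, type = c("series", "missingness"), ...) {
  type <- match.arg(type)
  long <- tidy(object)
  if (type == "series") {
    ggplot2::ggplot(long, ggplot2::aes(.data$date, .data$rsv, colour = .data$unit)) +
      ggplot2::geom_line(na.rm = TRUE) +
      ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
      ggplot2::labs(x = "collection day", y = "RSV", colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    long$present <- !is.na(long$rsv)
    ggplot2::ggplot(long, ggplot2::aes(.data$date, .data$unit, fill = .data$present)) +
      ggplot2::geom_tile(colour = "grey80") +
      ggplot2::scale_fill_manual(values = c(`TRUE` = "grey25", `FALSE` = "white"),
                                 labels = c(`TRUE` = "present", `FALSE` = "missing")) +
      ggplot2::labs(x = "collection day", y = NULL, fill = NULL) +
      ggplot2::theme_minimal()
  }
}
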