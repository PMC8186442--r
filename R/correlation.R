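#' Percentage increase between two values
#'
#' \eqn{\Delta = (u_f - u_0)/u_0 \cdot 100}, the statistic used throughout
#' the package to quantify how much a correlation (or any other quantity)
#' drifts with the collection day.
#'
#' @param u0 Baseline value; must be non-zero.
#' @param uf Final value.
#' @return The signed percentage increase.
#' @examples
#' percent_increase(-0.29, -0.36) # |Delta| = 24.1%
#' @export
percent_increase <- function(u0, uf) {
  if (!is.numeric(u0) || !is.numeric(uf) || length(u0) != 1L || length(uf) != 1L) {
    stop_rsvstab("u0 and uf must be single numbers", "validation")
  }
  if (u0 == 0) {
    stop_rsvstab("percentage increase is undefined for baseline u0 = 0",
                 "baseline")
  }
  (uf - u0) / u0 * 100
}

#' Percentage increase across an unordered interval
#'
#' For a variability interval `[a, b]` (e.g. the min/max of day-by-day
#' correlations) the baseline \eqn{u_0} is the endpoint of smaller
#' magnitude and \eqn{u_f} the other, so the statistic measures how much
#' the quantity can grow in magnitude across collection days. Ties pick
#' `a` as baseline.
#'
#' @param a,b Interval endpoints.
#' @return A one-row tibble: `u0`, `uf`, `delta_pct` (signed),
#'   `abs_delta_pct`.
#' @examples
#' interval_delta(0.04, 0.29) # +625%
#' @export
interval_delta <- function(a, b) {
  if (abs(b) < abs(a)) {
    u0 <- b; uf <- a
  } else {
    u0 <- a; uf <- b
  }
  d <- percent_increase(u0, uf)
  tibble(u0 = u0, uf = uf, delta_pct = d, abs_delta_pct = abs(d))
}

as_external_series <- function(ext, label = NULL) {
  if (is.numeric(ext) && !is.null(names(ext))) {
    ext <- tibble(unit = names(ext), value = unname(ext))
  }
  if (!is.data.frame(ext) || ncol(ext) < 2L) {
    stop_rsvstab("external series must be a two-column data frame (unit, value) or named vector",
                 "validation")
  }
  out <- as_tibble(ext[, 1:2])
  names(out) <- c("unit", "value")
  out$unit <- trimws(as.character(out$unit))
  out$value <- as.numeric(out$value)
  if (any(!is.finite(out$value))) {
    stop_rsvstab("external series values must be finite", "validation")
  }
  if (anyDuplicated(norm_unit(out$unit))) {
    stop_rsvstab("duplicate unit in external series", "validation")
  }
  attr(out, "label") <- label %||% attr(ext, "label", exact = TRUE) %||% "external"
  out
}

#' Day-by-day correlation between RSVs and an external series
#'
#' For every collection day, correlates the RSVs present in that day's pull
#' with a fixed external value per unit (typically cumulative epidemic case
#' counts over the investigation period), joined case-insensitively on the
#' unit name. If the correlations were trustworthy, the coefficient would
#' barely depend on which day the pull happened; the trace quantifies how
#' far that fails, through the min/max range and its percentage increase
#' ([interval_delta()]).
#'
#' Days where fewer than `min_units` units join, or where either joined
#' vector is constant (correlation undefined), are skipped and listed with
#' a reason.
#'
#' @param pm A `pull_matrix`.
#' @param ext External series: a two-column data frame `(unit, value)` or a
#'   named numeric vector.
#' @param method `"pearson"` or `"spearman"` (ties use average ranks).
#' @param min_units Minimum joined units per day (default 3).
#' @return A `correlation_trace`: `per_day` tibble (`date`, `coefficient`,
#'   `n_units`), skipped days with reasons, the coefficient `range` and its
#'   `delta_pct`/`abs_delta_pct`. Outlier fields are filled by
#'   [flag_outlier_days()].
#' @export
correlation_by_day <- function(pm, ext, method = c("pearson", "spearman"),
                               min_units = 3L) {
  pm <- as_pull_matrix(pm)
  method <- match.arg(method)
  ext <- as_external_series(ext)
  m <- rsv_matrix(pm)
  key <- norm_unit(rownames(m))
  ev <- setNames(ext$value, norm_unit(ext$unit))[key]

  dates <- collection_dates(pm)
  rows <- purrr::map(seq_along(dates), function(j) {
    x <- m[, j]
    ok <- !is.na(x) & !is.na(ev)
    n <- sum(ok)
    if (n < min_units) {
      return(tibble(date = dates[j], coefficient = NA_real_, n_units = n,
                    skipped = TRUE, reason = sprintf("only %d units joined", n)))
    }
    if (sd(x[ok]) == 0 || sd(ev[ok]) == 0) {
      return(tibble(date = dates[j], coefficient = NA_real_, n_units = n,
                    skipped = TRUE, reason = "constant values; correlation undefined"))
    }
    tibble(date = dates[j],
           coefficient = cor(x[ok], ev[ok], method = method),
           n_units = n, skipped = FALSE, reason = NA_character_)
  })
  all_days <- dplyr::bind_rows(rows)
  per_day <- dplyr::select(all_days[!all_days$skipped, ], "date", "coefficient", "n_units")
  skipped <- dplyr::select(all_days[all_days$skipped, ], "date", "n_units", "reason")
  if (nrow(per_day) == 0L) {
    stop_rsvstab(paste0("no collection day joins at least ", min_units,
                        " units with the external series"),
                 "insufficient_overlap")
  }
  rng <- range(per_day$coefficient)
  dl <- if (rng[1L] == 0 && rng[2L] == 0) {
    tibble(u0 = 0, uf = 0, delta_pct = NA_real_, abs_delta_pct = NA_real_)
  } else if (min(abs(rng)) == 0) {
    # baseline endpoint is exactly zero: drift in percent is undefined
    tibble(u0 = rng[which.min(abs(rng))], uf = rng[which.max(abs(rng))],
           delta_pct = NA_real_, abs_delta_pct = NA_real_)
  } else {
    interval_delta(rng[1L], rng[2L])
  }
  structure(
    list(
      method = method,
      ext_label = attr(ext, "label", exact = TRUE),
      per_day = per_day,
      skipped_days = skipped,
      range = rng,
      delta_pct = dl$delta_pct,
      abs_delta_pct = dl$abs_delta_pct,
      outlier_k = NA_real_,
      outlier_days = as.Date(character()),
      trimmed_range = NULL,
      trimmed_delta_pct = NA_real_,
      trimmed_abs_delta_pct = NA_real_
    ),
    class = "correlation_trace"
  )
}

#' Flag outlier collection days in a correlation trace
#'
#' A day's coefficient is an outlier when it lies more than `k` scaled
#' median absolute deviations (MAD, consistency constant 1.4826) from the
#' median of the retained coefficients. This median +/- k MAD rule is the
#' package's own operationalization - a robust convention - used to report
#' a trimmed, more representative variability range alongside the raw one.
#' Flagging needs at least 5 retained days; with fewer, the trace is
#' returned unchanged with a notice.
#'
#' @param trace A [correlation_by_day()] result.
#' @param k MAD multiplier (default 3).
#' @return The trace with `outlier_days`, `trimmed_range` and
#'   `trimmed_delta_pct` filled in.
#' @export
flag_outlier_days <- function(trace, k = 3) {
  if (!inherits(trace, "correlation_trace")) {
    stop_rsvstab("trace must come from correlation_by_day()", "validation")
  }
  co <- trace$per_day$coefficient
  if (length(co) < 5L) {
    rlang::inform(sprintf(
      "outlier flagging skipped: only %d retained days (need 5)", length(co)))
    return(trace)
  }
  med <- median(co)
  dev <- abs(co - med)
  cut <- k * mad(co) # mad() already applies the 1.4826 consistency constant
  out <- dev > cut
  trace$outlier_k <- k
  trace$outlier_days <- trace$per_day$date[out]
  kept <- co[!out]
  trace$trimmed_range <- range(kept)
  if (min(abs(trace$trimmed_range)) == 0) {
    trace$trimmed_delta_pct <- NA_real_
    trace$trimmed_abs_delta_pct <- NA_real_
  } else {
    dl <- interval_delta(trace$trimmed_range[1L], trace$trimmed_range[2L])
    trace$trimmed_delta_pct <- dl$delta_pct
    trace$trimmed_abs_delta_pct <- dl$abs_delta_pct
  }
  trace
}

#' @export
print.correlation_trace <- function(x, ...) {
  cat(sprintf("# day-by-day %s correlation vs %s (%d days retained, %d skipped)\n",
              x$method, x$ext_label, nrow(x$per_day), nrow(x$skipped_days)))
  cat(sprintf("# range [%.2f, %.2f]", x$range[1L], x$range[2L]))
  if (!is.na(x$abs_delta_pct)) cat(sprintf(", |Delta| = %.1f%%", x$abs_delta_pct))
  cat("\n")
  if (length(x$outlier_days)) {
    cat(sprintf("# outlier days (median +/- %g MAD, package extension): %s\n",
                x$outlier_k, paste(format(x$outlier_days), collapse = ", ")))
    cat(sprintf("# trimmed range [%.2f, %.2f], |Delta| = %.1f%%\n",
                x$trimmed_range[1L], x$trimmed_range[2L], x$trimmed_abs_delta_pct))
  }
  d <- x$per_day
  d$coefficient <- round(d$coefficient, 2L)
  print(d, n = Inf)
  invisible(x)
}

#' Tidiers for correlation traces
#'
#' `tidy()` returns the per-day coefficients with an `outlier` flag column;
#' `glance()` the one-row range/drift summary.
#'
#' @param x A `correlation_trace`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.correlation_trace <- function(x, ...) {
  d <- x$per_day
  d$outlier <- d$date %in% x$outlier_days
  d
}

#' @rdname tidy.correlation_trace
#' @export
glance.correlation_trace <- function(x, ...) {
  tibble(
    method = x$method,
    n_days = nrow(x$per_day),
    n_skipped = nrow(x$skipped_days),
    min = x$range[1L],
    max = x$range[2L],
    delta_pct = x$delta_pct,
    abs_delta_pct = x$abs_delta_pct,
    n_outlier_days = length(x$outlier_days),
    trimmed_min = if (is.null(x$trimmed_range)) NA_real_ else x$trimmed_range[1L],
    trimmed_max = if (is.null(x$trimmed_range)) NA_real_ else x$trimmed_range[2L],
    trimmed_abs_delta_pct = x$trimmed_abs_delta_pct
  )
}

#' @export
autoplot.correlation_trace <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$date, .data$coefficient)) +
    ggplot2::geom_hline(yintercept = object$range, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey25", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "collection day",
                  y = sprintf("%s coefficient vs %s", object$method, object$ext_label),
                  colour = "outlier") +
    ggplot2::theme_minimal()
}
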