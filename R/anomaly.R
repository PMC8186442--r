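#' Audit a pull matrix for anomalies
#'
#' An anomaly is a geographic series that failed to appear in at least one
#' daily pull of the otherwise identical dataset: its row has one or more
#' missing cells. Because the query, period and geography never changed
#' between pulls, such appearance/disappearance is evidence that single-day
#' snapshots of the ranking are unstable. A series with *no* present cell at
#' all is additionally flagged `unusable` (no statistics can be computed for
#' it). When the fraction of anomalous series exceeds `threshold` (strictly;
#' exactly 20% is tolerated) the whole dataset is marked excluded from
#' downstream statistical analysis.
#'
#' @param pm A `pull_matrix` (or data frame coercible to one).
#' @param threshold Exclusion threshold on the anomalous fraction
#'   (default `0.20`).
#' @return An `anomaly_report`: per-series missing/present counts and flags,
#'   plus `n_series`, `n_anomalous`, `anomaly_rate` and the
#'   `dataset_excluded` verdict. Use [tidy()]/[glance()] for tibble views.
#' @examples
#' detect_anomalies(load_fixture("table2"))
#' @export
detect_anomalies <- function(pm, threshold = 0.20) {
  pm <- as_pull_matrix(pm)
  m <- rsv_matrix(pm)
  if (nrow(m) < 1L || ncol(m) < 1L) {
    stop_rsvstab("pull matrix must have at least one series and one collection date",
                 "validation")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0 || threshold > 1) {
    stop_rsvstab("threshold must be a single fraction in [0, 1]", "validation")
  }
  missing_count <- rowSums(is.na(m))
  per_series <- tibble(
    unit = pm$unit,
    missing_count = as.integer(missing_count),
    present_count = as.integer(ncol(m) - missing_count),
    is_anomalous = missing_count >= 1L,
    unusable = missing_count == ncol(m)
  )
  n_anomalous <- sum(per_series$is_anomalous)
  rate <- n_anomalous / nrow(per_series)
  structure(
    list(
      per_series = per_series,
      n_series = nrow(per_series),
      n_anomalous = as.integer(n_anomalous),
      anomaly_rate = rate,
      threshold = threshold,
      dataset_excluded = rate > threshold
    ),
    class = "anomaly_report"
  )
}

#' Drop anomalous series from a pull matrix
#'
#' Removes every series the report marks anomalous, preserving row order and
#' leaving all remaining cells untouched. Running [detect_anomalies()] on
#' the result always gives an anomaly rate of zero.
#'
#' @param pm The `pull_matrix` the report was computed from.
#' @param report An [detect_anomalies()] report; recomputed from `pm` when
#'   omitted.
#' @return A `pull_matrix` containing only the complete series.
#' @export
drop_anomalous <- function(pm, report = NULL) {
  pm <- as_pull_matrix(pm)
  if (is.null(report)) report <- detect_anomalies(pm)
  if (!inherits(report, "anomaly_report")) {
    stop_rsvstab("report must come from detect_anomalies()", "consistency")
  }
  if (!identical(sort(norm_unit(report$per_series$unit)), sort(norm_unit(pm$unit)))) {
    stop_rsvstab("report and matrix describe different unit sets", "consistency")
  }
  keep_units <- report$per_series$unit[!report$per_series$is_anomalous]
  out <- pm[norm_unit(pm$unit) %in% norm_unit(keep_units), , drop = FALSE]
  attr(out, "rsv_meta") <- pull_meta(pm)
  class(out) <- class(pm)
  out
}

#' @export
print.anomaly_report <- function(x, ...) {
  cat(sprintf("# anomaly audit: %d/%d series anomalous (%.1f%%), threshold %.0f%% -> %s\n",
              x$n_anomalous, x$n_series, 100 * x$anomaly_rate, 100 * x$threshold,
              if (x$dataset_excluded) "DATASET EXCLUDED" else "dataset retained"))
  print(x$per_series, n = Inf)
  invisible(x)
}

#' Tidiers for anomaly reports
#'
#' `tidy()` returns the per-series table (missing/present counts, flags);
#' `glance()` the one-row verdict.
#'
#' @param x An `anomaly_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.anomaly_report <- function(x, ...) x$per_series

#' @rdname tidy.anomaly_report
#' @export
glance.anomaly_report <- function(x, ...) {
  tibble(
    n_series = x$n_series,
    n_anomalous = x$n_anomalous,
    anomaly_rate = x$anomaly_rate,
    threshold = x$threshold,
    dataset_excluded = x$dataset_excluded
  )
}

#' @export
autoplot.anomaly_report <- function(object, ...) {
  d <- dplyr::arrange(object$per_series, dplyr::desc(.data$missing_count))
  d$unit <- factor(d$unit, levels = rev(d$unit))
  ggplot2::ggplot(d, ggplot2::aes(.data$missing_count, .data$unit,
                                  fill = .data$is_anomalous)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "missing pull days", y = NULL, fill = "anomalous",
                  title = sprintf("%d/%d series anomalous (%.1f%%)",
                                  object$n_anomalous, object$n_series,
                                  100 * object$anomaly_rate)) +
    ggplot2::theme_minimal()
}
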