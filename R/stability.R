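#' Per-series Gaussian stability summaries
#'
#' Models each series' day-to-day RSV variation as a Gaussian
#' \eqn{X_i = X(\sigma_i, \bar{x}_i)} over its present pull-day values and
#' reports mean, sample SD (n-1 denominator), SEM \eqn{= \sigma_i/\sqrt{n}},
#' a 95% confidence interval (mean +/- 1.96 SEM, clipped to the RSV scale
#' \[0, 100\]), and a Shapiro-Wilk normality screen at level `alpha`.
#' The normality boolean uses a strict `p < alpha`; p-values falling in the
#' `borderline` band are additionally flagged, since the screening level is
#' indicative rather than inferential.
#'
#' Series with fewer than 2 present cells get `NA` dispersion fields; the
#' Shapiro-Wilk p-value is only defined for `n >= 3` with non-zero SD.
#' Series with zero present cells are a contract violation - remove them
#' first with [drop_anomalous()].
#'
#' @param pm A `pull_matrix`.
#' @param alpha Normality screening level (default `0.05`).
#' @param borderline Two p-value bounds flagged as borderline
#'   (default `c(0.04, 0.06)`).
#' @return A tibble of subclass `series_stability`, one row per series:
#'   `unit`, `n`, `mean`, `sd`, `sem`, `ci_low`, `ci_high`, `shapiro_p`,
#'   `non_normal`, `borderline_normality`.
#' @examples
#' load_fixture("table5") |> drop_anomalous() |> summarize_series()
#' @export
summarize_series <- function(pm, alpha = 0.05, borderline = c(0.04, 0.06)) {
  pm <- as_pull_matrix(pm)
  m <- rsv_matrix(pm)
  if (nrow(m) < 1L) stop_rsvstab("pull matrix has no series", "validation")
  n_present <- rowSums(!is.na(m))
  if (any(n_present == 0L)) {
    stop_rsvstab(
      paste0("series with no present cells: ",
             paste(pm$unit[n_present == 0L], collapse = ", "),
             " - run drop_anomalous() first"),
      "contract")
  }
  rows <- purrr::map(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    v <- v[!is.na(v)]
    n <- length(v)
    mu <- mean(v)
    if (n >= 2L) {
      s <- sd(v)
      sem <- s / sqrt(n)
      ci_low <- max(0, mu - 1.96 * sem)
      ci_high <- min(100, mu + 1.96 * sem)
    } else {
      s <- NA_real_; sem <- NA_real_; ci_low <- NA_real_; ci_high <- NA_real_
    }
    p <- if (n >= 3L && !is.na(s) && s > 0 && n <= 5000L) {
      shapiro.test(v)$p.value
    } else {
      NA_real_
    }
    tibble(
      unit = pm$unit[i], n = n, mean = mu, sd = s, sem = sem,
      ci_low = ci_low, ci_high = ci_high,
      shapiro_p = p,
      non_normal = if (is.na(p)) NA else p < alpha,
      borderline_normality = !is.na(p) & p >= borderline[1L] & p <= borderline[2L]
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
            class = c("series_stability", class(as_tibble(out))),
            alpha = alpha)
}

#' @export
glance.series_stability <- function(x, ...) {
  tibble(
    n_series = nrow(x),
    grand_mean = mean(x$mean),
    mean_sem = mean(x$sem, na.rm = TRUE),
    sem_min = suppressWarnings(min(x$sem, na.rm = TRUE)),
    sem_max = suppressWarnings(max(x$sem, na.rm = TRUE)),
    sd_min = suppressWarnings(min(x$sd, na.rm = TRUE)),
    sd_max = suppressWarnings(max(x$sd, na.rm = TRUE)),
    n_non_normal = sum(x$non_normal %in% TRUE)
  )
}

#' @export
autoplot.series_stability <- function(object, ...) {
  d <- dplyr::arrange(as_tibble(object), .data$mean)
  d$unit <- factor(d$unit, levels = d$unit)
  ggplot2::ggplot(d, ggplot2::aes(.data$mean, .data$unit)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                             na.rm = TRUE) +
    ggplot2::labs(x = "mean RSV (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

stability_row <- function(x, what) {
  if (inherits(x, "series_stability") && nrow(x) == 1L) return(x)
  if (is.data.frame(x) && nrow(x) == 1L &&
      all(c("unit", "n", "mean", "sem") %in% names(x))) {
    return(x)
  }
  stop_rsvstab(paste0(what, " must be a single series_stability row ",
                      "(columns unit, n, mean, sem)"), "validation")
}

#' Welch-t confidence between two series
#'
#' Compares the mean RSVs of two series with the Welch statistic
#' \eqn{t = |\bar{x}_a - \bar{x}_b| / \tilde{\sigma}}, where
#' \eqn{\tilde{\sigma} = \sqrt{SEM_a^2 + SEM_b^2}} is the Welch standard
#' error (no equal-variance assumption). The pair is *confident* -
#' statistically indistinguishable under the screening criterion - when
#' `t < t_threshold`. Two zero-variance series with equal means are
#' perfectly confident (`t = 0`); with different means they are perfectly
#' distinguishable (`t = Inf`).
#'
#' @param a,b Single rows of a [summarize_series()] table. Each needs
#'   `n >= 2`.
#' @param t_threshold Confidence cut (default `1.5`).
#' @return A one-row tibble: `unit_a`, `unit_b`, `mean_diff`, `sigma_tilde`,
#'   `t`, `confident`.
#' @export
welch_pair <- function(a, b, t_threshold = 1.5) {
  a <- stability_row(a, "a"); b <- stability_row(b, "b")
  for (s in list(a, b)) {
    if (is.na(s$n) || s$n < 2L) {
      stop_rsvstab(paste0("unit '", s$unit, "' has n = ", s$n,
                          " present pulls; need at least 2"),
                   "insufficient_data")
    }
  }
  sigma_tilde <- sqrt(a$sem^2 + b$sem^2)
  diff <- abs(a$mean - b$mean)
  t <- if (sigma_tilde == 0) {
    if (diff == 0) 0 else Inf
  } else {
    diff / sigma_tilde
  }
  tibble(unit_a = a$unit, unit_b = b$unit,
         mean_diff = diff, sigma_tilde = sigma_tilde,
         t = t, confident = t < t_threshold)
}

#' Pairwise confidence classification and reliability verdict
#'
#' Evaluates the Welch-t confidence criterion (see [welch_pair()]) on every
#' unordered pair of series and, for each series, the fraction of its
#' partners it is confident (indistinguishable) with. A dataset is deemed
#' *unreliable* when any series is confident with strictly more than
#' `confidence_threshold` of its partners: too much of the ranking is then
#' statistical coincidence for single-day snapshots to be trusted.
#'
#' @param x A `pull_matrix` (summarized internally) or a
#'   [summarize_series()] table. Every series must have `n >= 2` present
#'   pulls; audit and [drop_anomalous()] first.
#' @param t_threshold Welch-t confidence cut (default `1.5`).
#' @param confidence_threshold Unreliability cut on the per-series confident
#'   fraction (default `0.20`, strict).
#' @return A `confidence_report`: `pairs` (all N(N-1)/2 [welch_pair()]
#'   rows), `fractions` (per-series confident fraction), `max_fraction_unit`,
#'   and the `dataset_unreliable` verdict.
#' @examples
#' load_fixture("table2") |> drop_anomalous() |> confidence_report()
#' @export
confidence_report <- function(x, t_threshold = 1.5, confidence_threshold = 0.20) {
  stab <- if (inherits(x, "series_stability")) x else summarize_series(x)
  low_n <- stab$unit[stab$n < 2L]
  if (length(low_n)) {
    stop_rsvstab(paste0("series with fewer than 2 present pulls: ",
                        paste(low_n, collapse = ", "),
                        " - drop anomalous series first"),
                 "insufficient_data")
  }
  if (nrow(stab) < 2L) {
    stop_rsvstab("need at least 2 eligible series for pairwise confidence",
                 "insufficient_data")
  }
  idx <- combn(nrow(stab), 2L)
  pairs <- purrr::map(seq_len(ncol(idx)), function(k) {
    welch_pair(stab[idx[1L, k], ], stab[idx[2L, k], ], t_threshold = t_threshold)
  })
  pairs <- dplyr::bind_rows(pairs)

  frac <- purrr::map_dbl(stab$unit, function(u) {
    mine <- pairs[pairs$unit_a == u | pairs$unit_b == u, ]
    mean(mine$confident)
  })
  fractions <- tibble(unit = stab$unit, confident_fraction = frac)
  structure(
    list(
      pairs = pairs,
      fractions = fractions,
      max_fraction_unit = fractions$unit[which.max(fractions$confident_fraction)],
      max_fraction = max(fractions$confident_fraction),
      t_threshold = t_threshold,
      confidence_threshold = confidence_threshold,
      dataset_unreliable = any(fractions$confident_fraction > confidence_threshold)
    ),
    class = "confidence_report"
  )
}

#' @export
print.confidence_report <- function(x, ...) {
  cat(sprintf(
    "# confidence report: |t| < %.2f on %d pairs; max confident fraction %.0f%% (%s); threshold %.0f%% -> %s\n",
    x$t_threshold, nrow(x$pairs), 100 * x$max_fraction, x$max_fraction_unit,
    100 * x$confidence_threshold,
    if (x$dataset_unreliable) "DATASET UNRELIABLE" else "dataset reliable"))
  print(x$fractions, n = Inf)
  invisible(x)
}

#' Tidiers for confidence reports
#'
#' `tidy()` returns either the per-series confident fractions or, with
#' `type = "pairs"`, the full pairwise Welch-t table; `glance()` the one-row
#' verdict.
#'
#' @param x A `confidence_report`.
#' @param type `"fractions"` (default) or `"pairs"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.confidence_report <- function(x, type = c("fractions", "pairs"), ...) {
  switch(match.arg(type), fractions = x$fractions, pairs = x$pairs)
}

#' @rdname tidy.confidence_report
#' @export
glance.confidence_report <- function(x, ...) {
  tibble(
    n_pairs = nrow(x$pairs),
    n_confident_pairs = sum(x$pairs$confident),
    max_fraction = x$max_fraction,
    max_fraction_unit = x$max_fraction_unit,
    t_threshold = x$t_threshold,
    confidence_threshold = x$confidence_threshold,
    dataset_unreliable = x$dataset_unreliable
  )
}

#' @export
autoplot.confidence_report <- function(object, ...) {
  p <- object$pairs
  both <- dplyr::bind_rows(
    p,
    dplyr::rename(p, unit_a = "unit_b", unit_b = "unit_a")
  )
  units <- object$fractions$unit
  both$unit_a <- factor(both$unit_a, levels = units)
  both$unit_b <- factor(both$unit_b, levels = rev(units))
  ggplot2::ggplot(both, ggplot2::aes(.data$unit_a, .data$unit_b,
                                     fill = .data$confident)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey92", `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = NULL, fill = sprintf("|t| < %.1f", object$t_threshold)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1))
}
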