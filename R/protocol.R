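#' Robust-collection protocol engine
#'
#' Implements the recommended four-step criterion for collecting
#' Google-Trends-style RSVs robustly, as an incremental decision engine fed
#' one daily pull at a time:
#'
#' 1. monitor the pull stream daily for stability - no anomalies (every
#'    unit present) and no dramatic RSV changes;
#' 2. once stable for at least `min_stable_days` consecutive days, keep
#'    collecting until the series' mean RSVs become statistically
#'    incompatible (Welch |t| above the confidence cut for enough pairs);
#'    non-normal series require at least `min_extractions_nonnormal` pulls;
#' 3. publish per-series mean RSVs with 95% confidence intervals rather
#'    than any single-day snapshot;
#' 4. report correlations with external quantities day by day (delegated to
#'    [correlation_by_day()] when an external series is supplied to
#'    [conclude()]).
#'
#' A change is "dramatic" when a unit's new RSV differs from its running
#' mean (over its previous present pulls) by strictly more than
#' `drama_threshold` RSV units - an operationalization chosen because
#' routine day-to-day fluctuation in stable pull grids stays within about
#' half that.
#'
#' @param units Character vector: the universe of geographic units expected
#'   in every pull.
#' @param min_stable_days Consecutive stable days required before the
#'   extension phase (default 7).
#' @param min_extractions_nonnormal Minimum pulls before concluding when any
#'   series screens non-normal (default 30).
#' @param drama_threshold Dramatic-change cut in RSV units (default 10).
#' @param t_threshold,confidence_threshold,alpha Passed to
#'   [confidence_report()] and [summarize_series()] at conclusion.
#' @return A `protocol_state` in phase `"monitoring"`.
#' @examples
#' st <- protocol_init(c("A", "B"))
#' st <- ingest_day(st, "2021-01-01", c(A = 100, B = 60))
#' st$stable_streak
#' @export
protocol_init <- function(units,
                          min_stable_days = 7L,
                          min_extractions_nonnormal = 30L,
                          drama_threshold = 10,
                          t_threshold = 1.5,
                          confidence_threshold = 0.20,
                          alpha = 0.05) {
  units <- trimws(as.character(units))
  if (!length(units) || any(!nzchar(units)) || anyDuplicated(norm_unit(units))) {
    stop_rsvstab("units must be non-empty and unique", "validation")
  }
  structure(
    list(
      units = units,
      matrix_so_far = tibble(unit = units),
      days_observed = 0L,
      stable_streak = 0L,
      phase = "monitoring",
      params = list(min_stable_days = as.integer(min_stable_days),
                    min_extractions_nonnormal = as.integer(min_extractions_nonnormal),
                    drama_threshold = drama_threshold,
                    t_threshold = t_threshold,
                    confidence_threshold = confidence_threshold,
                    alpha = alpha),
      log = tibble(date = as.Date(character()), complete = logical(),
                   dramatic = logical(), streak = integer(), phase = character())
    ),
    class = "protocol_state"
  )
}

#' Feed one daily pull into the protocol
#'
#' Appends a new collection day. The stability streak resets to zero when
#' the column misses any unit of the universe or when any unit's RSV jumps
#' by more than the dramatic-change threshold relative to its running mean;
#' otherwise it increments. Reaching `min_stable_days` consecutive stable
#' days moves the phase from `"monitoring"` to `"extending"` (phases only
#' ever move forward).
#'
#' @param state A [protocol_init()] state in phase `"monitoring"` or
#'   `"extending"`.
#' @param date The collection date (coercible to `Date`); must be later
#'   than every date already ingested.
#' @param values The day's pull: a named numeric vector or two-column data
#'   frame `(unit, rsv)`; unit names must belong to the universe
#'   (case-insensitive). Units absent from `values`, or present with `NA`,
#'   count as missing.
#' @return The updated `protocol_state`.
#' @export
ingest_day <- function(state, date, values) {
  if (!inherits(state, "protocol_state")) {
    stop_rsvstab("state must come from protocol_init()", "validation")
  }
  if (startsWith(state$phase, "concluded")) {
    stop_rsvstab("protocol already concluded; start a new state", "state")
  }
  date <- as.Date(date)
  if (is.na(date)) stop_rsvstab("date must be a valid calendar date", "validation")
  prev_dates <- parse_iso_date(names(state$matrix_so_far)[-1L])
  if (any(date == prev_dates)) {
    stop_rsvstab(paste0("collection date ", format(date), " already ingested"),
                 "validation")
  }
  if (length(prev_dates) && date < max(prev_dates)) {
    stop_rsvstab("collection dates must be ingested in increasing order", "validation")
  }

  if (is.data.frame(values)) {
    values <- setNames(as.numeric(values[[2L]]), as.character(values[[1L]]))
  }
  if (is.null(names(values))) {
    stop_rsvstab("values must be named by unit", "validation")
  }
  extra <- setdiff(norm_unit(names(values)), norm_unit(state$units))
  if (length(extra)) {
    stop_rsvstab(paste0("unknown unit(s) in pull: ", paste(extra, collapse = ", ")),
                 "validation")
  }
  bad <- !is.na(values) & (values < 0 | values > 100)
  if (any(bad)) {
    stop_rsvstab(paste0("RSV out of [0, 100] for unit ", names(values)[bad][1L]),
                 "validation")
  }
  col <- setNames(values, norm_unit(names(values)))[norm_unit(state$units)]
  col <- unname(col)

  prior <- as.matrix(as.data.frame(state$matrix_so_far)[-1L])
  run_mean <- if (ncol(prior)) rowMeans(prior, na.rm = TRUE) else rep(NaN, length(col))
  has_prior <- if (ncol(prior)) rowSums(!is.na(prior)) > 0L else rep(FALSE, length(col))

  complete <- !anyNA(col)
  dramatic <- any(!is.na(col) & has_prior &
                    abs(col - run_mean) > state$params$drama_threshold)

  state$matrix_so_far[[format(date, "%Y-%m-%d")]] <- col
  state$days_observed <- state$days_observed + 1L
  state$stable_streak <- if (complete && !dramatic) state$stable_streak + 1L else 0L
  if (state$phase == "monitoring" &&
      state$stable_streak >= state$params$min_stable_days) {
    state$phase <- "extending"
  }
  state$log <- dplyr::bind_rows(state$log, tibble(
    date = date, complete = complete, dramatic = dramatic,
    streak = state$stable_streak, phase = state$phase))
  state
}

#' Conclude the collection protocol
#'
#' Only callable once the stream has been stable long enough (phase
#' `"extending"`). The dataset concludes *reliable* when the pairwise
#' confidence verdict on everything collected so far is reliable (no series
#' confident with more than the confidence threshold of its partners) and
#' either all series screen normal or at least
#' `min_extractions_nonnormal` pulls have been made. The report carries the
#' per-series means with 95% confidence intervals - the values recommended
#' for publication in place of single-day RSVs - and, when an external
#' series is supplied, the day-by-day correlation trace.
#'
#' @param state A `protocol_state` in phase `"extending"`.
#' @param ext Optional external series for step 4 (see
#'   [correlation_by_day()]).
#' @param method Correlation method when `ext` is given.
#' @return A `protocol_report` with `verdict`
#'   (`"concluded_reliable"`/`"concluded_unreliable"`), `reasons`, the
#'   stability table, the confidence report, the optional correlation
#'   trace, and the concluded `state`.
#' @export
conclude <- function(state, ext = NULL, method = c("spearman", "pearson")) {
  if (!inherits(state, "protocol_state")) {
    stop_rsvstab("state must come from protocol_init()", "validation")
  }
  if (state$phase == "monitoring") {
    stop_rsvstab(paste0("cannot conclude while monitoring: stable streak is ",
                        state$stable_streak, " of ",
                        state$params$min_stable_days, " required days"),
                 "state")
  }
  if (startsWith(state$phase, "concluded")) {
    stop_rsvstab("protocol already concluded", "state")
  }
  method <- match.arg(method)
  pm <- as_pull_matrix(state$matrix_so_far)
  reasons <- character()

  audit <- detect_anomalies(pm, threshold = state$params$confidence_threshold)
  usable <- audit$per_series$present_count >= 2L
  if (!all(usable)) {
    reasons <- c(reasons, paste0(
      "series with fewer than 2 present pulls: ",
      paste(audit$per_series$unit[!usable], collapse = ", ")))
    stab <- NULL; conf <- NULL
  } else {
    stab <- summarize_series(pm, alpha = state$params$alpha)
    conf <- confidence_report(stab,
                              t_threshold = state$params$t_threshold,
                              confidence_threshold = state$params$confidence_threshold)
    if (conf$dataset_unreliable) {
      reasons <- c(reasons, sprintf(
        "confidence threshold exceeded: %s confident with %.0f%% of partners (> %.0f%%)",
        conf$max_fraction_unit, 100 * conf$max_fraction,
        100 * conf$confidence_threshold))
    }
    any_non_normal <- any(stab$non_normal %in% TRUE)
    if (any_non_normal &&
        state$days_observed < state$params$min_extractions_nonnormal) {
      reasons <- c(reasons, sprintf(
        "non-normal series present (%s) with only %d extractions (< %d required)",
        paste(stab$unit[stab$non_normal %in% TRUE], collapse = ", "),
        state$days_observed, state$params$min_extractions_nonnormal))
    }
  }

  reliable <- length(reasons) == 0L
  state$phase <- if (reliable) "concluded_reliable" else "concluded_unreliable"

  trace <- if (!is.null(ext)) correlation_by_day(pm, ext, method = method) else NULL

  structure(
    list(
      verdict = state$phase,
      reasons = reasons,
      days_observed = state$days_observed,
      stability = stab,
      confidence = conf,
      correlation = trace,
      state = state
    ),
    class = "protocol_report"
  )
}

#' @export
print.protocol_state <- function(x, ...) {
  cat(sprintf("# protocol state: phase %s | %d days observed | stable streak %d/%d\n",
              x$phase, x$days_observed, x$stable_streak,
              x$params$min_stable_days))
  if (nrow(x$log)) print(x$log, n = Inf)
  invisible(x)
}

#' @export
print.protocol_report <- function(x, ...) {
  cat(sprintf("# protocol conclusion after %d daily pulls: %s\n",
              x$days_observed, x$verdict))
  for (r in x$reasons) cat("#  - ", r, "\n", sep = "")
  if (!is.null(x$stability)) {
    cat("# recommended published values (mean RSV with 95% CI):\n")
    print(dplyr::select(as_tibble(x$stability), "unit", "n", "mean",
                        "ci_low", "ci_high"), n = Inf)
  }
  invisible(x)
}

#' Tidiers for protocol reports
#'
#' `tidy()` returns the per-series published values (mean and 95% CI);
#' `glance()` the one-row verdict.
#'
#' @param x A `protocol_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.protocol_report <- function(x, ...) {
  if (is.null(x$stability)) {
    return(tibble(unit = character(), n = integer(), mean = numeric(),
                  ci_low = numeric(), ci_high = numeric()))
  }
  dplyr::select(as_tibble(x$stability), "unit", "n", "mean", "ci_low", "ci_high")
}

#' @rdname tidy.protocol_report
#' @export
glance.protocol_report <- function(x, ...) {
  tibble(
    verdict = x$verdict,
    days_observed = x$days_observed,
    n_reasons = length(x$reasons),
    max_confident_fraction = if (is.null(x$confidence)) NA_real_ else x$confidence$max_fraction
  )
}
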