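#' Ground-truth configuration for synthetic pull matrices
#'
#' Describes the generative model the package uses to emulate repeated
#' daily pulls: each unit i has a true pre-normalization interest level
#' \eqn{\mu_i > 0} and daily SD \eqn{\sigma_i \ge 0}; on every pull day the
#' raw interests are drawn independently as \eqn{N(\mu_i, \sigma_i)},
#' floored at 0, and the day's column is rescaled so its maximum is exactly
#' 100 (per-day max-normalization - the mechanism that makes single-day
#' snapshots unstable). Each cell is then deleted with probability
#' `anomaly_prob` (the missing-series anomaly process), and optionally
#' quantized to integers as served RSVs are.
#'
#' @param n_units,n_days Grid dimensions (both >= 1).
#' @param mu True interest levels, recycled to `n_units`; all > 0.
#' @param sigma True daily SDs, recycled; all >= 0.
#' @param anomaly_prob Per-cell deletion probability in `[0, 1)`, recycled
#'   per unit.
#' @param seed Integer seed; the same seed and config always reproduce the
#'   same matrix bit for bit.
#' @param quantize Round RSVs to integers after normalization
#'   (default `TRUE`).
#' @param unit_names Optional unit names (default `U01`, `U02`, ...).
#' @param start_date First collection date.
#' @param external_link Optional strictly monotone function mapping `mu` to
#'   a true external value per unit (e.g. case counts), used by
#'   [synthetic_external()].
#' @return A `synthetic_truth` configuration list.
#' @export
synthetic_truth <- function(n_units, n_days, mu, sigma,
                            anomaly_prob = 0, seed = 1L,
                            quantize = TRUE, unit_names = NULL,
                            start_date = as.Date("2020-12-08"),
                            external_link = NULL) {
  n_units <- as.integer(n_units); n_days <- as.integer(n_days)
  if (is.na(n_units) || n_units < 1L || is.na(n_days) || n_days < 1L) {
    stop_rsvstab("n_units and n_days must be at least 1", "config")
  }
  mu <- rep_len(as.numeric(mu), n_units)
  sigma <- rep_len(as.numeric(sigma), n_units)
  anomaly_prob <- rep_len(as.numeric(anomaly_prob), n_units)
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    stop_rsvstab("all mu must be finite and > 0", "config")
  }
  if (any(!is.finite(sigma)) || any(sigma < 0)) {
    stop_rsvstab("all sigma must be finite and >= 0", "config")
  }
  if (any(anomaly_prob < 0 | anomaly_prob >= 1)) {
    stop_rsvstab("anomaly_prob must lie in [0, 1)", "config")
  }
  unit_names <- unit_names %||% sprintf("U%02d", seq_len(n_units))
  if (length(unit_names) != n_units || anyDuplicated(unit_names)) {
    stop_rsvstab("unit_names must be unique and match n_units", "config")
  }
  structure(
    list(n_units = n_units, n_days = n_days, mu = mu, sigma = sigma,
         anomaly_prob = anomaly_prob, seed = as.integer(seed),
         quantize = isTRUE(quantize), unit_names = unit_names,
         start_date = as.Date(start_date), external_link = external_link),
    class = "synthetic_truth"
  )
}

# run code under the truth's seed without disturbing the caller's RNG state
with_truth_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic pull matrix
#'
#' Draws the series-by-day grid described by a [synthetic_truth()]
#' configuration. The pseudo-random stream is consumed in a documented
#' order - for each day in sequence: unit values, then that day's deletion
#' draws - so one seed always reproduces one matrix within this
#' implementation. Before deletion, every day's column maximum is exactly
#' 100.
#'
#' @param truth A `synthetic_truth`.
#' @return A `pull_matrix` carrying `truth` as the `"truth"` attribute
#'   (see [pull_truth()]).
#' @examples
#' pm <- simulate_pulls(scenario("coincident"))
#' @export
simulate_pulls <- function(truth) {
  if (!inherits(truth, "synthetic_truth")) {
    stop_rsvstab("truth must come from synthetic_truth() or scenario()", "config")
  }
  m <- with_truth_seed(truth$seed, {
    cols <- vector("list", truth$n_days)
    for (j in seq_len(truth$n_days)) {
      raw <- pmax(0, rnorm(truth$n_units, truth$mu, truth$sigma))
      mx <- max(raw)
      if (mx <= 0) {
        stop_rsvstab("degenerate pull day: all raw interests are zero", "config")
      }
      col <- raw * (100 / mx)
      col[which.max(raw)] <- 100 # exact despite floating-point scaling
      if (truth$quantize) col <- round(col)
      drop <- runif(truth$n_units) < truth$anomaly_prob
      col[drop] <- NA_real_
      cols[[j]] <- col
    }
    do.call(cbind, cols)
  })
  dates <- seq(truth$start_date, by = 1L, length.out = truth$n_days)
  df <- as_tibble(as.data.frame(m))
  names(df) <- format(dates, "%Y-%m-%d")
  df <- dplyr::bind_cols(tibble(unit = truth$unit_names), df)
  pm <- as_pull_matrix(df, query = "synthetic", geo_scope = "synthetic")
  attr(pm, "truth") <- truth
  pm
}

#' @rdname simulate_pulls
#' @param pm A pull matrix produced by `simulate_pulls()`.
#' @export
pull_truth <- function(pm) attr(pm, "truth", exact = TRUE)

#' True external series of a synthetic configuration
#'
#' Applies the configuration's monotone link to the true interest levels,
#' giving a per-unit external value (emulating, e.g., cumulative case
#' counts) whose rank order matches the true interest exactly. Default
#' link: `round(1500 * mu)`.
#'
#' @param truth A `synthetic_truth`.
#' @return A tibble `(unit, value)` usable as `ext` in
#'   [correlation_by_day()].
#' @export
synthetic_external <- function(truth) {
  if (!inherits(truth, "synthetic_truth")) {
    stop_rsvstab("truth must come from synthetic_truth() or scenario()", "config")
  }
  link <- truth$external_link %||% function(mu) round(1500 * mu)
  out <- tibble(unit = truth$unit_names, value = as.numeric(link(truth$mu)))
  attr(out, "label") <- "synthetic cases"
  out
}

#' Named generator scenarios
#'
#' Ready-made [synthetic_truth()] configurations mirroring the kinds of
#' datasets the audit is designed for:
#'
#' * `regions_p1` - 20 regional series over 15 pull days, daily SDs spread
#'   over 6.6-7.6 RSV units and high interest levels, no missingness: a
#'   high-variance but anomaly-free regional panel.
#' * `regions_p2` - 20 regions over 19 days with much smaller daily SDs
#'   (1.3-2.1), no missingness.
#' * `cities_p1` - 24 city series over 13 days with per-cell missingness
#'   probability 0.25: a heavily anomalous city panel.
#' * `world_p1` - 62 country series over 13 days; the first unit's true
#'   interest dominates all others so it pins the per-day maximum (RSV 100
#'   every pull, zero observed SD), wide spread of lower means, small
#'   per-cell missingness (about 9.7% of series anomalous over 13 days).
#' * `two_cluster` - two clusters of 3 series (true levels 20 vs 80,
#'   within-cluster SD 1, 10 days): within-cluster pairs are confident by
#'   construction, so the confidence verdict is designed to be unreliable.
#' * `coincident` - 8 series with identical true level and SD: every pair
#'   confident, maximally unreliable.
#' * `separated` - 5 series with pairwise mean gaps far exceeding the
#'   Welch standard error: designed reliable.
#'
#' @param name Scenario name.
#' @param seed Optional seed override.
#' @param n_days Optional number-of-days override (e.g. to lengthen a
#'   scenario for parameter-recovery studies).
#' @return A `synthetic_truth`.
#' @export
scenario <- function(name, seed = NULL, n_days = NULL) {
  cfg <- switch(
    tolower(trimws(name)),
    regions_p1 = list(n_units = 20L, n_days = 15L,
                      mu = seq(82, 100, length.out = 20),
                      sigma = seq(6.6, 7.6, length.out = 20),
                      anomaly_prob = 0, seed = 101L,
                      start_date = as.Date("2020-12-08")),
    regions_p2 = list(n_units = 20L, n_days = 19L,
                      mu = seq(86, 100, length.out = 20),
                      sigma = seq(1.3, 2.1, length.out = 20),
                      anomaly_prob = 0, seed = 102L,
                      start_date = as.Date("2020-12-08")),
    cities_p1 = list(n_units = 24L, n_days = 13L,
                     mu = seq(75, 100, length.out = 24),
                     sigma = seq(1.5, 3, length.out = 24),
                     anomaly_prob = 0.25, seed = 103L,
                     start_date = as.Date("2020-12-14")),
    world_p1 = list(n_units = 62L, n_days = 13L,
                    mu = c(140, seq(15, 105, length.out = 61)),
                    sigma = c(3, seq(0.5, 5, length.out = 61)),
                    anomaly_prob = 0.0078, seed = 104L,
                    start_date = as.Date("2020-12-14")),
    two_cluster = list(n_units = 6L, n_days = 10L,
                       mu = rep(c(20, 80), each = 3),
                       sigma = 1, anomaly_prob = 0, seed = 105L,
                       start_date = as.Date("2020-12-08")),
    coincident = list(n_units = 8L, n_days = 10L,
                      mu = 90, sigma = 3, anomaly_prob = 0, seed = 106L,
                      start_date = as.Date("2020-12-08")),
    separated = list(n_units = 5L, n_days = 10L,
                     mu = c(20, 40, 60, 80, 100),
                     sigma = 2.5, anomaly_prob = 0, seed = 107L,
                     start_date = as.Date("2020-12-08")),
    stop_rsvstab(paste0("unknown scenario '", name, "'"), "lookup")
  )
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(n_days)) cfg$n_days <- as.integer(n_days)
  synthetic_truth(n_units = cfg$n_units, n_days = cfg$n_days, mu = cfg$mu,
                  sigma = cfg$sigma, anomaly_prob = cfg$anomaly_prob,
                  seed = cfg$seed, start_date = cfg$start_date)
}
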