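# build a pull_matrix from a numeric matrix (rows = units, NA = missing)
make_pm <- function(m, units = NULL, start = as.Date("2020-12-14")) {
  if (is.vector(m)) m <- matrix(m, nrow = 1L)
  dimnames(m) <- NULL
  units <- units %||% sprintf("S%02d", seq_len(nrow(m)))
  dates <- seq(start, by = 1L, length.out = ncol(m))
  df <- tibble::as_tibble(as.data.frame(m))
  names(df) <- format(dates, "%Y-%m-%d")
  as_pull_matrix(dplyr::bind_cols(tibble::tibble(unit = units), df))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# fabricate a correlation_trace with given retained coefficients
make_trace <- function(coefs, start = as.Date("2020-12-08")) {
  dates <- seq(start, by = 1L, length.out = length(coefs))
  rng <- range(coefs)
  dl <- interval_delta(rng[1L], rng[2L])
  structure(
    list(method = "spearman", ext_label = "test",
         per_day = tibble::tibble(date = dates, coefficient = coefs,
                                  n_units = rep(10L, length(coefs))),
         skipped_days = tibble::tibble(date = as.Date(character()),
                                       n_units = integer(), reason = character()),
         range = rng, delta_pct = dl$delta_pct, abs_delta_pct = dl$abs_delta_pct,
         outlier_k = NA_real_, outlier_days = as.Date(character()),
         trimmed_range = NULL, trimmed_delta_pct = NA_real_,
         trimmed_abs_delta_pct = NA_real_),
    class = "correlation_trace")
}

# independent base-R oracle for the pairwise confidence classification
brute_confidence <- function(m, t_threshold = 1.5, confidence_threshold = 0.20) {
  N <- nrow(m)
  means <- numeric(N); sems <- numeric(N)
  for (i in seq_len(N)) {
    v <- m[i, ][!is.na(m[i, ])]
    means[i] <- sum(v) / length(v)
    s2 <- sum((v - means[i])^2) / (length(v) - 1L)
    sems[i] <- sqrt(s2 / length(v))
  }
  conf <- matrix(FALSE, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    st <- sqrt(sems[i]^2 + sems[j]^2)
    d <- abs(means[i] - means[j])
    t <- if (st == 0) (if (d == 0) 0 else Inf) else d / st
    conf[i, j] <- t < t_threshold
  }
  fractions <- rowSums(conf) / (N - 1L)
  list(fractions = fractions,
       unreliable = any(fractions > confidence_threshold))
}

random_small_pm <- function(seed) {
  set.seed(seed)
  N <- sample(2:8, 1L)
  D <- sample(3:6, 1L)
  m <- matrix(round(runif(N * D, 0, 100), 1L), nrow = N)
  # occasionally a constant series, to exercise the zero-variance branches
  if (runif(1) < 0.3) m[1L, ] <- round(runif(1, 0, 100))
  if (runif(1) < 0.1 && N >= 2L) m[2L, ] <- m[1L, ]
  make_pm(m)
}
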