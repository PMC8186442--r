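# case-insensitive, whitespace-trimmed key used whenever unit names are joined
norm_unit <- function(x) tolower(trimws(x))

stop_rsvstab <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("rsvstab_error_", class), "rsvstab_error"), ...)
}

# strictly ISO-8601 dates; anything else is NA
parse_iso_date <- function(x) {
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
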