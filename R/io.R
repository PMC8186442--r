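#' Read and write pull matrices as wide CSV
#'
#' The on-disk dialect is UTF-8 comma-separated: first column header `unit`,
#' remaining headers ISO-8601 collection dates, empty string for a missing
#' cell. This round-trips the missingness pattern that the anomaly audit
#' treats as evidence.
#'
#' @param path CSV file path.
#' @param ... Passed to [as_pull_matrix()] (metadata such as `query`).
#' @return `read_pull_matrix()`: a validated `pull_matrix`.
#'   `write_pull_matrix()`: `path`, invisibly.
#' @export
read_pull_matrix <- function(path, ...) {
  if (!file.exists(path)) {
    stop_rsvstab(paste0("no such file: ", path), "io")
  }
  df <- tryCatch(
    readr::read_csv(path, na = "", col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE),
    error = function(e) stop_rsvstab(paste0("cannot parse CSV: ", conditionMessage(e)), "format")
  )
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop_rsvstab("file holds no pull matrix (need a unit column, date columns and rows)",
                 "format")
  }
  if (tolower(names(df)[1L]) != "unit") {
    stop_rsvstab(paste0("first column header must be 'unit', got '", names(df)[1L], "'"),
                 "format")
  }
  as_pull_matrix(df, ...)
}

#' @rdname read_pull_matrix
#' @param pm A `pull_matrix`.
#' @export
write_pull_matrix <- function(pm, path) {
  pm <- as_pull_matrix(pm)
  readr::write_csv(as_tibble(pm), path, na = "")
  invisible(path)
}

fixture_registry <- function() {
  tibble(
    canonical = c("table2", "table3", "table4", "table5"),
    alias = c("italian_cities_p1", "italian_cities_p2",
              "world_cities_p1", "world_cities_p2"),
    file = c("italian-cities-p1.csv", "italian-cities-p2.csv",
             "world-cities-p1.csv", "world-cities-p2.csv"),
    geo_scope = c("IT", "IT", "world", "world"),
    period_start = as.Date(c("2020-02-01", "2020-02-20", "2020-02-01", "2020-02-20")),
    period_end = as.Date(c("2020-12-04", "2020-05-18", "2020-12-04", "2020-05-18"))
  )
}

#' Bundled repeated-pull datasets
#'
#' Four city-level RSV grids for the query *coronavirus + covid*, each
#' downloaded once a day in December 2020 for a fixed investigation period:
#' Italian cities over 1 Feb-4 Dec 2020 (`table2`) and 20 Feb-18 May 2020
#' (`table3`), and cities worldwide over the same two periods (`table4`,
#' `table5`). Blank cells are pulls in which the city did not appear at all
#' - the anomalies this package audits. Descriptive aliases
#' (`italian_cities_p1` ... `world_cities_p2`) are accepted too.
#'
#' @param name One of `"table2"`, `"table3"`, `"table4"`, `"table5"` or a
#'   descriptive alias.
#' @return A `pull_matrix`.
#' @examples
#' load_fixture("table2")
#' @export
load_fixture <- function(name) {
  reg <- fixture_registry()
  i <- match(tolower(trimws(name)), reg$canonical)
  if (is.na(i)) i <- match(tolower(trimws(name)), reg$alias)
  if (is.na(i)) {
    stop_rsvstab(paste0("unknown fixture '", name, "'; choose one of: ",
                        paste(c(reg$canonical, reg$alias), collapse = ", ")),
                 "lookup")
  }
  path <- system.file("extdata", reg$file[i], package = "rsvstab", mustWork = TRUE)
  read_pull_matrix(path,
                   query = "coronavirus + covid",
                   geo_scope = reg$geo_scope[i],
                   unit_level = "city",
                   period_start = reg$period_start[i],
                   period_end = reg$period_end[i])
}

# recursively turn report objects into JSON-friendly plain lists
sanitize_for_json <- function(x) {
  if (inherits(x, "Date")) return(format(x, "%Y-%m-%d"))
  if (is.data.frame(x)) {
    x <- as.data.frame(x)
    x[] <- lapply(x, sanitize_for_json)
    return(x)
  }
  if (is.function(x)) return(NULL)
  if (is.list(x)) {
    x <- unclass(x)
    return(lapply(x, sanitize_for_json))
  }
  x
}

#' Serialize an audit report
#'
#' Writes any rsvstab report object (anomaly report, stability table,
#' confidence report, correlation trace, protocol report) to disk. JSON
#' keeps full numeric precision so that [read_report()] reproduces every
#' numeric field exactly; the text format is the human-readable table the
#' print method shows.
#'
#' @param report An rsvstab report object.
#' @param path Output file path.
#' @param format `"json"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "text")) {
  format <- match.arg(format)
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop_rsvstab(paste0("directory does not exist: ", dirname(path)), "io")
  if (format == "json") {
    payload <- list(
      report_class = class(report)[1L],
      generated_by = "rsvstab",
      body = sanitize_for_json(report)
    )
    # 17 significant digits: doubles survive the round-trip bit for bit
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                         na = "null", null = "null", pretty = TRUE)
  } else {
    txt <- utils::capture.output(print(report))
    writeLines(txt, path, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_rsvstab(paste0("no such file: ", path), "io")
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
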