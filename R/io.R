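#' Read a compositional time series from CSV/TSV
#'
#' Expects the first column to hold timestamps (integers, or ISO-8601
#' datetimes on a regular grid) and the remaining columns the strictly
#' positive parts. Datetime stamps are converted to grid-step indices
#' using `grid` (e.g. `"10 min"`); missing timestamps are simply absent
#' rows and are handled downstream by valid-pair moment estimation.
#'
#' @param path file path; delimiter inferred from extension
#'   (`.tsv` -> tab, otherwise comma).
#' @param grid grid spacing for datetime stamps, as accepted by
#'   [base::difftime()] units, e.g. `"10 min"`, `"1 hour"`; ignored for
#'   integer stamps.
#' @param impute_nonpositive if TRUE, nonpositive entries are repaired via
#'   [replace_nonpositive()] instead of raising an error.
#' @return A [composition_series()].
#' @export
read_composition_csv <- function(path, grid = NULL, impute_nonpositive = FALSE) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 3) stop("expected a timestamp column plus >= 2 part columns")
  ts_raw <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (is.character(ts_raw)) {
    tt <- as.POSIXct(ts_raw, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                    "%Y-%m-%d"))
    if (anyNA(tt)) stop("unparseable timestamps in first column")
    if (is.null(grid)) stop("datetime timestamps require a declared grid spacing")
    gp <- parse_grid(grid)
    steps <- as.numeric(difftime(tt, tt[1], units = "secs")) / gp
    if (max(abs(steps - round(steps))) > 1e-6)
      stop("timestamps do not lie on the declared grid")
    ts <- round(steps) + 1
  } else {
    ts <- as.numeric(ts_raw)
  }
  if (impute_nonpositive) vals <- replace_nonpositive(vals)
  composition_series(vals, ts, parts = colnames(vals))
}

## internal: grid spec like "10 min" / "1 hour" / "30 sec" -> seconds
parse_grid <- function(grid) {
  if (is.numeric(grid)) return(grid)
  m <- regmatches(grid, regexec("^([0-9.]+)\\s*([a-zA-Z]+)$", grid))[[1]]
  if (length(m) != 3) stop("cannot parse grid spacing: ", grid)
  mult <- switch(tolower(substr(m[3], 1, 3)),
                 sec = 1, min = 60, hou = 3600, day = 86400,
                 stop("unknown grid unit: ", m[3]))
  as.numeric(m[2]) * mult
}

#' Write a compositional or coordinate series to CSV
#'
#' Coordinate series additionally get a sidecar JSON (`<path>.json`)
#' recording the space (clr/ilr) and, for ilr, the contrast matrix used,
#' so the coordinates can be mapped back later.
#'
#' @param x a `cts` or `cts_coord` object.
#' @param path output CSV path.
#' @export
write_series_csv <- function(x, path) {
  s <- as_series(x)
  df <- data.frame(timestamp = s$timestamps, s$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (inherits(x, "cts_coord")) {
    side <- list(space = x$space)
    if (!is.null(x$basis)) {
      side$basis <- unclass(x$basis)
      side$basis_kind <- attr(x$basis, "kind")
    }
    jsonlite::write_json(side, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
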