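#' Read and write length-frequency tables
#'
#' CSV interchange format with header `year,bin_lower_mm,count`. Rows
#' with zero counts are retained; malformed files (overlapping or
#' off-grid bins, negative or non-integer counts, duplicate rows) are
#' rejected rather than coerced. The bin width is inferred as the
#' smallest spacing between edges (10 mm in the fishery these tools were
#' built for) unless given.
#'
#' @param path CSV file path.
#' @param bin_width bin width in mm; `NULL` to infer.
#' @return [read_length_frequency()]: a [length_frequency] table.
#' @export
read_length_frequency <- function(path, bin_width = NULL) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("year", "bin_lower_mm", "count")
  if (!all(need %in% names(df)))
    stop_format("expected header year,bin_lower_mm,count in ", path)
  num <- function(v, name) {
    x <- suppressWarnings(as.numeric(v))
    if (anyNA(x)) stop_format("non-numeric ", name, " in ", path)
    x
  }
  out <- data.frame(year = as.integer(num(df$year, "year")),
                    bin_lower = num(df$bin_lower_mm, "bin_lower_mm"),
                    count = num(df$count, "count"))
  if (is.null(bin_width)) {
    u <- sort(unique(out$bin_lower))
    bin_width <- if (length(u) > 1) min(diff(u)) else 10
  }
  as_length_frequency(out, bin_width = bin_width)
}

#' @param table a [length_frequency] table.
#' @rdname read_length_frequency
#' @export
write_length_frequency <- function(table, path) {
  if (!inherits(table, "length_frequency")) stop_data("table must be a length_frequency")
  utils::write.csv(data.frame(year = table$year,
                              bin_lower_mm = table$bin_lower,
                              count = table$count),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write fishing logbooks
#'
#' CSV with header `date,lat,lon,nets,catch_t`; dates ISO-8601. Records
#' with zero nets are rejected (CPUE undefined), as are non-numeric
#' coordinates.
#'
#' @param path CSV file path.
#' @return [read_logbook()]: data frame with `date` (Date), `lat`,
#'   `lon`, `nets` (integer), `catch` (tonnes).
#' @export
read_logbook <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("date", "lat", "lon", "nets", "catch_t")
  if (!all(need %in% names(df)))
    stop_format("expected header date,lat,lon,nets,catch_t in ", path)
  num <- function(v, name) {
    x <- suppressWarnings(as.numeric(v))
    if (anyNA(x)) stop_format("non-numeric ", name, " in ", path)
    x
  }
  date <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(date)) stop_format("dates must be ISO-8601 (YYYY-MM-DD) in ", path)
  out <- data.frame(date = date, lat = num(df$lat, "lat"),
                    lon = num(df$lon, "lon"),
                    nets = as.integer(num(df$nets, "nets")),
                    catch = num(df$catch_t, "catch_t"))
  if (any(!is.finite(out$lat)) || any(!is.finite(out$lon)))
    stop_format("non-finite coordinates in ", path)
  if (any(out$nets < 1)) stop_format("nets must be >= 1 (CPUE undefined) in ", path)
  if (any(out$catch < 0)) stop_format("negative catch in ", path)
  out
}

#' @param records a logbook data frame.
#' @rdname read_logbook
#' @export
write_logbook <- function(records, path) {
  utils::write.csv(data.frame(date = format(as.Date(records$date), "%Y-%m-%d"),
                              lat = records$lat, lon = records$lon,
                              nets = records$nets, catch_t = records$catch),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read length-weight records
#'
#' CSV with header `fork_length_mm,weight_g` and optional `year`, `sex`.
#'
#' @param path CSV file path.
#' @return data frame with `fork_length`, `weight` (+ `year`, `sex`).
#' @export
read_length_weight <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("fork_length_mm", "weight_g") %in% names(df)))
    stop_format("expected header fork_length_mm,weight_g in ", path)
  out <- data.frame(fork_length = as.numeric(df$fork_length_mm),
                    weight = as.numeric(df$weight_g))
  if (anyNA(out)) stop_format("non-numeric lengths/weights in ", path)
  if ("year" %in% names(df)) out$year <- as.integer(df$year)
  if ("sex" %in% names(df)) out$sex <- as.character(df$sex)
  out
}
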