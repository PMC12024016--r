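#' Length-frequency tables
#'
#' The pipeline's central input: counts of fish per fork-length bin and
#' year. Bins are half-open intervals `[bin_lower, bin_lower + bin_width)`
#' in millimetres, uniform within a table (default 10 mm).
#'
#' @param year integer vector of sampling years.
#' @param bin_lower lower bin edges (mm).
#' @param count non-negative integer counts per bin.
#' @param bin_width common bin width (mm).
#' @return a `data.frame` of class `length_frequency` with columns
#'   `year`, `bin_lower`, `count` and attribute `bin_width`.
#' @examples
#' lf <- length_frequency(2016L, c(200, 210, 220), c(5L, 9L, 2L))
#' lf_midpoints(lf)
#' @export
length_frequency <- function(year, bin_lower, count, bin_width = 10) {
  df <- data.frame(year = as.integer(year), bin_lower = as.numeric(bin_lower),
                   count = count)
  as_length_frequency(df, bin_width = bin_width)
}

#' Validate a data frame as a length-frequency table
#'
#' @param df data frame with columns `year`, `bin_lower`, `count`.
#' @param bin_width bin width (mm).
#' @rdname length_frequency
#' @export
as_length_frequency <- function(df, bin_width = 10) {
  check_positive(bin_width, "bin_width")
  need <- c("year", "bin_lower", "count")
  if (!all(need %in% names(df)))
    stop_format("length-frequency table needs columns ", paste(need, collapse = ", "))
  df <- df[need]
  if (anyNA(df)) stop_format("length-frequency table contains missing values")
  if (any(df$count < 0)) stop_format("negative counts in length-frequency table")
  if (any(df$count != round(df$count)))
    stop_format("counts must be integers")
  if (anyDuplicated(df[c("year", "bin_lower")]))
    stop_format("duplicate (year, bin_lower) rows: bins would overlap")
  # uniform, non-overlapping bins: lower edges must sit on a common lattice
  off <- df$bin_lower %% bin_width
  if (max(off) - min(off) > 1e-9)
    stop_format("bin_lower edges are not on a uniform grid of width ", bin_width)
  for (y in unique(df$year)) {
    if (sum(df$count[df$year == y] > 0) < 2L)
      stop_format("year ", y, ": fewer than 2 non-empty bins")
  }
  df <- df[order(df$year, df$bin_lower), , drop = FALSE]
  rownames(df) <- NULL
  df$count <- as.integer(round(df$count))
  structure(df, bin_width = bin_width,
            class = c("length_frequency", "data.frame"))
}

#' @rdname length_frequency
#' @param lf a `length_frequency` table.
#' @export
lf_bin_width <- function(lf) attr(lf, "bin_width")

#' Bin midpoints of a length-frequency table (mm)
#' @rdname length_frequency
#' @export
lf_midpoints <- function(lf) lf$bin_lower + lf_bin_width(lf) / 2

#' Subset one year of a length-frequency table
#' @rdname length_frequency
#' @export
lf_year <- function(lf, year) {
  out <- lf[lf$year == year, , drop = FALSE]
  if (nrow(out) == 0L) stop_data("no rows for year ", year)
  rownames(out) <- NULL
  structure(out, bin_width = lf_bin_width(lf),
            class = c("length_frequency", "data.frame"))
}

#' @export
print.length_frequency <- function(x, ...) {
  yrs <- unique(x$year)
  cat(sprintf("Length-frequency table: %d bins (%g mm), %d fish, year%s %s\n",
              nrow(x), lf_bin_width(x), sum(x$count),
              if (length(yrs) > 1) "s" else "",
              if (length(yrs) > 1) paste(range(yrs), collapse = "-")
              else as.character(yrs)))
  NextMethod()
  invisible(x)
}

#' @export
plot.length_frequency <- function(x, year = NULL, ...) {
  if (!is.null(year)) x <- lf_year(x, year)
  graphics::barplot(x$count, names.arg = x$bin_lower, space = 0,
                    xlab = "fork length bin lower edge (mm)", ylab = "count",
                    ...)
  invisible(x)
}
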