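#' CPUE of a fishing operation
#'
#' Catch per unit effort, defined here as catch (tonnes) per net
#' deployment — the natural unit for purse-seine logbooks that record
#' nets and catch per operation.
#'
#' @param catch catch (tonnes), non-negative.
#' @param nets net deployments (>= 1).
#' @return tonnes per net (vectorized).
#' @export
cpue_per_operation <- function(catch, nets) {
  if (any(nets < 1)) stop_param("nets must be >= 1 (CPUE undefined)")
  if (any(catch < 0)) stop_param("catch must be non-negative")
  catch / nets
}

#' Aggregate logbook records onto a regular grid
#'
#' Each operation is assigned to the half-open cell
#' `[k * cell_deg, (k+1) * cell_deg)` in both latitude and longitude
#' (cells indexed by their lower-left corner, so boundary points belong
#' to exactly one cell). Catches, nets and operations are summed per
#' (cell, year); cell CPUE is total catch over total nets (a total-ratio,
#' not a mean of per-operation ratios).
#'
#' @param records logbook data frame (`date`, `lat`, `lon`, `nets`,
#'   `catch`).
#' @param cell_deg cell size in degrees (default 0.5).
#' @return data frame with `cell_lat`, `cell_lon`, `year`,
#'   `total_catch`, `total_nets`, `n_ops`, `cpue`; empty input gives an
#'   empty frame.
#' @export
grid_aggregate <- function(records, cell_deg = 0.5) {
  check_positive(cell_deg, "cell_deg")
  if (nrow(records) == 0L)
    return(data.frame(cell_lat = numeric(0), cell_lon = numeric(0),
                      year = integer(0), total_catch = numeric(0),
                      total_nets = numeric(0), n_ops = integer(0),
                      cpue = numeric(0)))
  cell_lat <- floor(records$lat / cell_deg) * cell_deg
  cell_lon <- floor(records$lon / cell_deg) * cell_deg
  year <- as.integer(format(as.Date(records$date), "%Y"))
  key <- interaction(cell_lat, cell_lon, year, drop = TRUE)
  agg <- function(v, f) as.numeric(tapply(v, key, f))
  out <- data.frame(
    cell_lat = as.numeric(tapply(cell_lat, key, `[`, 1)),
    cell_lon = as.numeric(tapply(cell_lon, key, `[`, 1)),
    year = as.integer(tapply(year, key, `[`, 1)),
    total_catch = agg(records$catch, sum),
    total_nets = agg(records$nets, sum),
    n_ops = as.integer(tapply(records$catch, key, length)))
  out$cpue <- out$total_catch / out$total_nets
  out <- out[order(out$year, out$cell_lat, out$cell_lon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Catch-weighted gravity center of the fishing ground
#'
#' Planar catch-weighted arithmetic mean of operation positions —
#' adequate at the ~10-degree span of a regional fishing ground and the
#' convention in fisheries practice.
#'
#' @param records logbook data frame.
#' @param year the year to summarize (all records if `NULL`).
#' @return list with `year`, `lat`, `lon`.
#' @export
center_of_gravity <- function(records, year = NULL) {
  r <- records
  if (!is.null(year)) {
    yrs <- as.integer(format(as.Date(r$date), "%Y"))
    r <- r[yrs == year, , drop = FALSE]
  }
  if (nrow(r) == 0L) stop_data("no records", if (!is.null(year)) paste0(" for year ", year))
  w <- r$catch
  if (sum(w) <= 0) stop_data("zero total catch: gravity center undefined")
  list(year = year, lat = sum(r$lat * w) / sum(w),
       lon = sum(r$lon * w) / sum(w))
}

#' Spearman rank correlation with mid-rank ties
#'
#' Pearson correlation of mid-ranks, with a large-sample t approximation
#' for the two-sided p-value: `t = rho * sqrt((n-2)/(1-rho^2))` on
#' `n - 2` degrees of freedom. Invariant under strictly monotone
#' transforms of either input.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho` and `p_value`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_param("x and y must have equal length >= 3")
  if (anyNA(x) || anyNA(y)) stop_data("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_data("constant input: rank correlation undefined")
  rho <- stats::cor(x, y, method = "spearman")
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = p)
}
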