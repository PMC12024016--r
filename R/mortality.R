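#' Length-converted catch curve
#'
#' Estimates total mortality Z from a length-frequency sample of the
#' catch and von Bertalanffy growth parameters. Each bin `[L1, L2)` is
#' mapped to relative age by the inverse growth curve
#' `t(L) = t0 - log(1 - L/Linf) / K`; the regression
#' `ln(N_i / dt_i) = c + d * t_i'` over the descending limb gives
#' `Z = -d`. The `dt_i` division corrects for the longer time slow-growing
#' large fish spend in a bin.
#'
#' Descending-limb rule (the classical convention, configurable): bins up
#' to and including the maximal `ln(N/dt)` point plus `extra_drop` more
#' are excluded as incompletely selected, and bins with midpoint above
#' `drop_above * Linf` are excluded as unstable under the age conversion.
#' Bins whose upper edge reaches Linf are always excluded (with a
#' warning), as their age is undefined.
#'
#' @param table a single-year [length_frequency] table (bins in mm).
#' @param params [vbgf_params()] in cm.
#' @param drop_above drop bins with midpoint above this fraction of Linf.
#' @param extra_drop extra bins dropped after the modal point.
#' @return a `catch_curve` object: `z`, `intercept_c`, `slope_d`,
#'   `r_squared`, and `points` (relative age, `ln(N/dt)`, `used` flag).
#' @export
length_converted_catch_curve <- function(table, params, drop_above = 0.95,
                                         extra_drop = 1) {
  if (!inherits(table, "length_frequency")) stop_data("table must be a length_frequency")
  if (!inherits(params, "vbgf_params")) stop_param("params must be vbgf_params")
  w_cm <- lf_bin_width(table) / 10
  l1 <- table$bin_lower / 10
  l2 <- l1 + w_cm
  mid <- l1 + w_cm / 2
  ok <- l2 < params$linf
  if (any(!ok))
    warning(sum(!ok), " bin(s) at or above Linf excluded from the catch curve")
  t_of <- function(l) params$t0 - log(1 - l / params$linf) / params$k
  y <- rep(NA_real_, nrow(table))
  t_rel <- rep(NA_real_, nrow(table))
  dt <- t_of(pmin(l2, params$linf * 0.999999)) - t_of(pmin(l1, params$linf * 0.999999))
  t_rel[ok] <- t_of(mid[ok])
  usable <- ok & table$count > 0
  y[usable] <- log(table$count[usable] / dt[usable])
  used <- usable & mid <= drop_above * params$linf
  # descending limb: drop up to and including the modal point, plus extras
  if (any(used)) {
    imode <- which(y == max(y[used], na.rm = TRUE) & used)[1]
    used[seq_len(min(imode + extra_drop, length(used)))] <- FALSE
  }
  if (sum(used) < 3L)
    stop_data("fewer than 3 usable points on the descending limb")
  fit <- stats::lm(y[used] ~ t_rel[used])
  slope <- unname(stats::coef(fit)[2])
  structure(list(z = -slope, intercept_c = unname(stats::coef(fit)[1]),
                 slope_d = slope, r_squared = summary(fit)$r.squared,
                 points = data.frame(t_rel = t_rel, log_n_dt = y,
                                     used = used)),
            class = "catch_curve")
}

#' @export
print.catch_curve <- function(x, ...) {
  cat(sprintf("Length-converted catch curve: Z = %.3f /yr (R^2 = %.3f, %d points)\n",
              x$z, x$r_squared, sum(x$points$used)))
  invisible(x)
}

#' @export
plot.catch_curve <- function(x, ...) {
  p <- x$points[is.finite(x$points$log_n_dt), ]
  graphics::plot(p$t_rel, p$log_n_dt, pch = ifelse(p$used, 19, 1),
                 xlab = "relative age (yr)", ylab = "ln(N / dt)", ...)
  graphics::abline(x$intercept_c, x$slope_d)
  invisible(x)
}

#' Pauly's empirical natural mortality
#'
#' `ln M = -0.0152 - 0.279 ln(Linf) + 0.654 ln(K) + 0.463 ln(T)` with `T`
#' the mean water temperature (deg C) of the stock's habitat. Increasing
#' in K and T, decreasing in Linf.
#'
#' @param linf asymptotic length (cm).
#' @param k growth coefficient (1/year).
#' @param temp_c mean habitat temperature (deg C).
#' @return natural mortality M (1/year).
#' @examples
#' pauly_natural_mortality(39.05, 0.65, 23.61)
#' @export
pauly_natural_mortality <- function(linf, k, temp_c) {
  check_pos_vec(linf, "linf")
  check_pos_vec(k, "k")
  check_pos_vec(temp_c, "temp_c")
  exp(-0.0152 - 0.279 * log(linf) + 0.654 * log(k) + 0.463 * log(temp_c))
}

#' Fishing mortality by subtraction
#'
#' `F = Z - M`. A negative result (estimation noise) is returned as-is
#' with a warning rather than clipped.
#'
#' @param z total mortality (1/year).
#' @param m natural mortality (1/year).
#' @return fishing mortality F (1/year).
#' @export
fishing_mortality <- function(z, m) {
  if (any(!is.finite(z)) || any(!is.finite(m)))
    stop_param("z and m must be finite")
  f <- z - m
  if (any(f < 0)) warning("negative fishing mortality (Z < M); reporting as-is")
  f
}

#' Exploitation rate
#'
#' `E = F / Z`; the classical heuristic reads E < 0.5 (F < M) as not
#' overfished.
#'
#' @param f fishing mortality (1/year).
#' @param z total mortality (1/year), positive.
#' @return exploitation rate (dimensionless).
#' @export
exploitation_rate <- function(f, z) {
  if (any(!is.finite(z)) || any(z <= 0)) stop_param("z must be positive")
  f / z
}

#' One-call mortality summary
#'
#' Runs the length-converted catch curve, Pauly's M, and the derived F
#' and E for one year of data.
#'
#' @inheritParams length_converted_catch_curve
#' @param temp_c mean habitat temperature (deg C).
#' @param ... passed to [length_converted_catch_curve()].
#' @return list with `z`, `m`, `f`, `e`, `mean_temp`, and the
#'   `catch_curve` fit.
#' @export
estimate_mortality <- function(table, params, temp_c, ...) {
  cc <- length_converted_catch_curve(table, params, ...)
  m <- pauly_natural_mortality(params$linf, params$k, temp_c)
  f <- fishing_mortality(cc$z, m)
  list(z = cc$z, m = m, f = f, e = exploitation_rate(f, cc$z),
       mean_temp = temp_c, catch_curve = cc)
}
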