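#' Length of maximum unexploited cohort biomass
#'
#' `Lopt = Linf * 3 / (3 + M/K)`: the length at which the biomass of an
#' unfished cohort peaks; approaches Linf as M/K tends to zero.
#'
#' @param linf asymptotic length (cm).
#' @param mk relative natural mortality M/K.
#' @return Lopt (cm).
#' @examples
#' l_opt(39.7, 1.58)  # ~26 cm
#' @export
l_opt <- function(linf, mk) {
  check_pos_vec(linf, "linf")
  check_pos_vec(mk, "mk")
  linf * 3 / (3 + mk)
}

#' Optimal length at first capture
#'
#' `Lc-opt = Linf (2 + 3 F/M) / ((1 + F/M)(3 + M/K))`: the 50%-retention
#' length that maximizes yield for the given fishing pressure while
#' preserving large spawners. Always below [l_opt()] for positive F/M.
#'
#' @param linf asymptotic length (cm).
#' @param fm relative fishing pressure F/M.
#' @param mk relative natural mortality M/K.
#' @return Lc-opt (cm).
#' @export
lc_opt <- function(linf, fm, mk) {
  check_pos_vec(linf, "linf")
  check_nonneg_vec(fm, "fm")
  check_pos_vec(mk, "mk")
  linf * (2 + 3 * fm) / ((1 + fm) * (3 + mk))
}

#' Beverton-Holt relative per-recruit quantities
#'
#' With `x = 1 - Lc/Linf`, `Z/K = M/K + F/K` and `F/M = (F/K)/(M/K)`:
#' \describe{
#'   \item{`ypr`}{relative yield per recruit,
#'     `F/M/(1+F/M) * x^(M/K) * B(Z/K)` where
#'     `B(d) = 1 - 3x/(1 + 1/d) + 3x^2/(1 + 2/d) - x^3/(1 + 3/d)`.}
#'   \item{`cpue_r`}{relative catch rate per recruit, `ypr / (F/M)`
#'     (by continuity `x^(M/K) B(Z/K)` when F = 0).}
#'   \item{`b0_r`}{relative unfished biomass per recruit,
#'     `x^(M/K) * B(M/K)`.}
#'   \item{`bb0`}{exploited over unexploited biomass,
#'     `cpue_r / b0_r`; equal to 1 when F = 0.}
#' }
#'
#' @param linf asymptotic length (cm).
#' @param lc 50%-retention length (cm), `0 < lc < linf`.
#' @param mk relative natural mortality M/K (> 0).
#' @param fk relative fishing mortality F/K (>= 0).
#' @return list with `ypr`, `cpue_r`, `b0_r`, `bb0`.
#' @examples
#' relative_yield_per_recruit(39.5, 24.4, 1.24, 0.26)$bb0  # ~0.77
#' @export
relative_yield_per_recruit <- function(linf, lc, mk, fk) {
  check_positive(linf, "linf")
  check_positive(lc, "lc")
  if (lc >= linf) stop_param("lc must lie below linf")
  check_positive(mk, "mk")
  check_nonneg(fk, "fk")
  x <- 1 - lc / linf
  zk <- mk + fk
  fm <- fk / mk
  bracket <- function(d)
    1 - 3 * x / (1 + 1 / d) + 3 * x^2 / (1 + 2 / d) - x^3 / (1 + 3 / d)
  cpue_r <- x^mk * bracket(zk) / (1 + fm)
  ypr <- fm * cpue_r
  b0_r <- x^mk * bracket(mk)
  list(ypr = ypr, cpue_r = cpue_r, b0_r = b0_r, bb0 = cpue_r / b0_r)
}

#' Relative biomass at maximum sustainable yield
#'
#' The proxy `Bmsy/B0` obtained by evaluating the per-recruit chain at
#' `F = M` (so `F/K = M/K`, `F/M = 1`) and the corresponding optimal
#' first-capture length `Lc = lc_opt(linf, 1, mk)`.
#'
#' @inheritParams l_opt
#' @return Bmsy/B0 (dimensionless).
#' @export
bmsy_proxy <- function(linf, mk) {
  relative_yield_per_recruit(linf, lc_opt(linf, 1, mk), mk, mk)$bb0
}

#' Current biomass relative to the MSY level
#'
#' `B/Bmsy = (B/B0) / (Bmsy/B0)`.
#'
#' @param bb0 current relative biomass B/B0.
#' @param bmsy_b0 MSY relative biomass Bmsy/B0 (> 0).
#' @return B/Bmsy (dimensionless).
#' @export
b_over_bmsy <- function(bb0, bmsy_b0) {
  if (!is.numeric(bmsy_b0) || bmsy_b0 <= 0) stop_param("bmsy_b0 must be positive")
  bb0 / bmsy_b0
}

#' Full reference-point set from LBB parameters
#'
#' Convenience wrapper chaining [l_opt()], [lc_opt()],
#' [relative_yield_per_recruit()], [bmsy_proxy()] and [b_over_bmsy()].
#'
#' @inheritParams relative_yield_per_recruit
#' @return list of class `reference_points` with `l_opt`, `lc_opt`,
#'   `ypr`, `cpue_r`, `b0_r`, `bb0`, `bmsy_b0`, `bbmsy`.
#' @export
reference_points <- function(linf, lc, mk, fk) {
  pr <- relative_yield_per_recruit(linf, lc, mk, fk)
  fm <- fk / mk
  out <- c(list(l_opt = l_opt(linf, mk), lc_opt = lc_opt(linf, fm, mk)),
           pr)
  out$bmsy_b0 <- bmsy_proxy(linf, mk)
  out$bbmsy <- b_over_bmsy(out$bb0, out$bmsy_b0)
  structure(out, class = "reference_points")
}

#' @export
print.reference_points <- function(x, ...) {
  cat(sprintf("Reference points: Lopt = %.1f, Lc-opt = %.1f cm\n",
              x$l_opt, x$lc_opt))
  cat(sprintf("  B/B0 = %.2f, Bmsy/B0 = %.3f, B/Bmsy = %.1f, Y'/R = %.3f\n",
              x$bb0, x$bmsy_b0, x$bbmsy, x$ypr))
  invisible(x)
}

# type-7 quantile of the sample formed by repeating each value by weight
weighted_quantile7 <- function(x, w, p) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  n <- sum(w)
  h <- (n - 1) * p + 1
  cw <- cumsum(w)
  lo <- x[which(cw >= floor(h))[1]]
  hi <- x[which(cw >= ceiling(h))[1]]
  lo + (h - floor(h)) * (hi - lo)
}

#' Length indicators of the catch
#'
#' `L95th` is the count-weighted 95th percentile of bin midpoints (linear
#' interpolation within the sample, type-7); `Lmean` is the
#' count-weighted mean length over bins with midpoint above the estimated
#' Lc. Ratios against Linf and Lc-opt diagnose whether large individuals
#' persist and the first-capture length is well placed.
#'
#' @param table a single-year [length_frequency] table (mm bins).
#' @param posterior an `lbb_fit` (or any list with `linf` and `lc` in cm
#'   under `$estimates` or at top level).
#' @param refpts a [reference_points()] result (needs `lc_opt`).
#' @return list with `l95th`, `lmean` (cm), `l95_over_linf`,
#'   `lmean_over_lcopt`, `lc_over_lcopt`.
#' @export
length_indicators <- function(table, posterior, refpts) {
  if (!inherits(table, "length_frequency")) stop_data("table must be a length_frequency")
  if (sum(table$count) == 0) stop_data("all counts are zero")
  est <- posterior$estimates %||% posterior
  mids <- lf_midpoints(table) / 10
  nz <- table$count > 0
  l95 <- weighted_quantile7(mids[nz], table$count[nz], 0.95)
  above <- mids > est$lc & nz
  lmean <- if (any(above))
    sum(mids[above] * table$count[above]) / sum(table$count[above])
  else NA_real_
  list(l95th = l95, lmean = lmean,
       l95_over_linf = l95 / est$linf,
       lmean_over_lcopt = lmean / refpts$lc_opt,
       lc_over_lcopt = est$lc / refpts$lc_opt)
}

#' Classify stock status
#'
#' Rule-based label from relative biomass and fishing pressure:
#' `healthy` when `B/Bmsy >= 1` and `F/M <= 1` (boundary inclusive);
#' `fully exploited` when `0.5 <= B/Bmsy < 1` (or biomass is above the
#' MSY level but overfishing is under way, `F/M > 1`); `overfished` when
#' `0.2 <= B/Bmsy < 0.5`; `collapsed` below 0.2.
#'
#' @param bb0 relative biomass B/B0 (reported alongside, not used by the
#'   default thresholds).
#' @param bbmsy relative biomass B/Bmsy.
#' @param fm fishing pressure F/M.
#' @param thresholds named vector `c(healthy = 1, fully = 0.5,
#'   overfished = 0.2)` of B/Bmsy cut points.
#' @return one of `"healthy"`, `"fully exploited"`, `"overfished"`,
#'   `"collapsed"`.
#' @export
classify_status <- function(bb0, bbmsy, fm,
                            thresholds = c(healthy = 1, fully = 0.5,
                                           overfished = 0.2)) {
  if (!all(is.finite(c(bb0, bbmsy, fm)))) stop_param("inputs must be finite")
  if (bbmsy >= thresholds["healthy"])
    return(if (fm <= 1) "healthy" else "fully exploited")
  if (bbmsy >= thresholds["fully"]) return("fully exploited")
  if (bbmsy >= thresholds["overfished"]) return("overfished")
  "collapsed"
}
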