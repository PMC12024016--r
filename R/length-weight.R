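#' Fit the allometric length-weight relationship
#'
#' Ordinary least squares on `(log10 L, log10 W)`, the universal fisheries
#' convention for the power law `W = a * L^b`. The coefficient `a` is
#' reported in the units of the supplied lengths (here mm, so g per mm^b);
#' refitting in cm changes `a` by exactly `10^b` and leaves `b` and R^2
#' unchanged. A two-sided t-test of `slope = 3` feeds the allometry
#' classification: `b` near 3 means weight grows isometrically with
#' length.
#'
#' @param records data frame with positive `fork_length` (mm) and
#'   `weight` (g) columns, at least 3 rows.
#' @return an object of class `lw_fit`: list with `a`, `b`, `r_squared`,
#'   `n`, `se_b`, `p_value_b_eq_3`, `growth_type`.
#' @examples
#' rec <- data.frame(fork_length = c(150, 200, 250, 300),
#'                   weight = 1e-5 * c(150, 200, 250, 300)^3)
#' fit_length_weight(rec)
#' @export
fit_length_weight <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("fork_length", "weight") %in% names(records)))
    stop_data("records must have fork_length and weight columns")
  l <- records$fork_length; w <- records$weight
  if (length(l) < 3L) stop_data("need at least 3 records")
  if (any(!is.finite(l)) || any(!is.finite(w)) || any(l <= 0) || any(w <= 0))
    stop_data("lengths and weights must be positive and finite")
  x <- log10(l); y <- log10(w)
  if (stats::var(x) == 0)
    stop_data("degenerate input: zero variance in length")
  fit <- stats::lm(y ~ x)
  b <- unname(stats::coef(fit)[2])
  a <- 10^unname(stats::coef(fit)[1])
  sfit <- suppressWarnings(summary(fit))  # noiseless data fit perfectly
  se_b <- sfit$coefficients[2, 2]
  # t-test of slope == 3 (isometry), two-sided
  tt <- (b - 3) / se_b
  p <- if (is.finite(tt)) 2 * stats::pt(-abs(tt), df = length(l) - 2) else 1
  out <- structure(list(a = a, b = b,
                        r_squared = sfit$r.squared,
                        n = length(l), se_b = se_b, p_value_b_eq_3 = p),
                   class = "lw_fit")
  out$growth_type <- classify_allometry(out)
  out
}

#' Classify the growth type of a length-weight fit
#'
#' Isometric when the exponent is not significantly different from 3 at
#' `alpha_level`; otherwise positive allometric (`b > 3`, weight outpaces
#' length) or negative allometric (`b < 3`).
#'
#' @param fit an `lw_fit` object.
#' @param alpha_level significance level of the `b = 3` t-test.
#' @return one of `"isometric"`, `"positive allometric"`,
#'   `"negative allometric"`.
#' @export
classify_allometry <- function(fit, alpha_level = 0.05) {
  if (!inherits(fit, "lw_fit")) stop_param("fit must be an lw_fit")
  if (fit$p_value_b_eq_3 >= alpha_level) return("isometric")
  if (fit$b > 3) "positive allometric" else "negative allometric"
}

#' @export
format.lw_fit <- function(x, ...) {
  # render as "W = 2.67e-07 * L^3.00 (R^2 = 0.9974, n = 1236)"
  sprintf("W = %.2e * L^%.2f (R^2 = %.4f, n = %d)",
          x$a, x$b, x$r_squared, x$n)
}

#' @export
print.lw_fit <- function(x, ...) {
  cat("Length-weight fit:", format(x), "\n")
  cat(sprintf("  growth type: %s (p[b=3] = %.3g)\n",
              x$growth_type, x$p_value_b_eq_3))
  invisible(x)
}
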