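#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(errorCondition(paste0(...), class = c("lenstock_param_error", "lenstock_error")))
stop_data <- function(...) stop(errorCondition(paste0(...), class = c("lenstock_data_error", "lenstock_error")))
stop_format <- function(...) stop(errorCondition(paste0(...), class = c("lenstock_format_error", "lenstock_error")))

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_param(name, " must be a single positive finite number")
  invisible(x)
}

check_pos_vec <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)) || any(x <= 0))
    stop_param(name, " must be positive and finite")
  invisible(x)
}

check_nonneg_vec <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)) || any(x < 0))
    stop_param(name, " must be non-negative and finite")
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop_param(name, " must be a single non-negative finite number")
  invisible(x)
}

#' Logistic gear-selection ogive
#'
#' Probability that a fish of length `l` is retained by the gear, under a
#' logistic ogive with 50% retention at `lc` and steepness `alpha`.
#'
#' @param l length (cm).
#' @param lc length at 50% retention (cm).
#' @param alpha ogive steepness (1/cm); large values approach a knife edge.
#' @return retention probability in (0, 1).
#' @export
selectivity_ogive <- function(l, lc, alpha) {
  1 / (1 + exp(-alpha * (l - lc)))
}
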