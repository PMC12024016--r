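#' Define a simulated fish-population scenario
#'
#' Bundles the parameters of the equilibrium length-structured population
#' model that drives the synthetic-data generators: von Bertalanffy growth
#' (`linf_mean`, `k`, `t0`) with individual variability in asymptotic length
#' (`linf_cv`), relative natural and fishing mortality (`m_over_k`,
#' `f_over_k`), a logistic gear-selection ogive (`lc`, `alpha`), and an
#' allometric length-weight relationship (`lw_a`, `lw_b`, length in mm,
#' weight in g).
#'
#' Defaults describe a chub-mackerel-like small pelagic: asymptotic fork
#' length around 40 cm, K near 0.6/yr, M/K at the classical 1.5, moderate
#' fishing pressure (F/K = 0.5), 50% gear retention at 20 cm.
#'
#' @param linf_mean mean asymptotic fork length (cm).
#' @param linf_cv coefficient of variation of individual asymptotic length.
#' @param k von Bertalanffy growth coefficient (1/year).
#' @param t0 theoretical age at length zero (year).
#' @param m_over_k natural mortality relative to growth, M/K.
#' @param f_over_k fishing mortality relative to growth, F/K.
#' @param lc length at 50% gear retention (cm).
#' @param alpha steepness of the selection ogive (1/cm).
#' @param lw_a allometric coefficient (g per mm^b).
#' @param lw_b allometric exponent.
#' @param n_fish number of recruits to simulate.
#' @param seed integer seed; all randomness in the generators flows from it.
#' @return an object of class `population_scenario` (a validated list).
#' @examples
#' sc <- population_scenario(seed = 1)
#' sc
#' @export
population_scenario <- function(linf_mean = 40, linf_cv = 0.05, k = 0.6,
                                t0 = -0.25, m_over_k = 1.5, f_over_k = 0.5,
                                lc = 20, alpha = 2, lw_a = 6.4e-6,
                                lw_b = 3.1, n_fish = 5000, seed = 1L) {
  check_positive(linf_mean, "linf_mean")
  check_nonneg(linf_cv, "linf_cv")
  check_positive(k, "k")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop_param("t0 must be a single finite number")
  check_positive(m_over_k, "m_over_k")
  check_nonneg(f_over_k, "f_over_k")
  check_positive(lc, "lc")
  if (lc >= linf_mean) stop_param("lc must lie below linf_mean")
  check_positive(alpha, "alpha")
  check_positive(lw_a, "lw_a")
  check_positive(lw_b, "lw_b")
  if (!is.numeric(n_fish) || length(n_fish) != 1L || n_fish < 1 ||
      n_fish != round(n_fish))
    stop_param("n_fish must be a positive integer")
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed))
    stop_param("seed must be a single integer")
  structure(list(linf_mean = linf_mean, linf_cv = linf_cv, k = k, t0 = t0,
                 m_over_k = m_over_k, f_over_k = f_over_k, lc = lc,
                 alpha = alpha, lw_a = lw_a, lw_b = lw_b,
                 n_fish = as.integer(n_fish), seed = as.integer(seed)),
            class = "population_scenario")
}

#' @export
print.population_scenario <- function(x, ...) {
  cat("Population scenario\n")
  cat(sprintf("  growth:    Linf = %.2f cm (CV %.2f), K = %.2f/yr, t0 = %.2f\n",
              x$linf_mean, x$linf_cv, x$k, x$t0))
  cat(sprintf("  mortality: M/K = %.2f, F/K = %.2f  (Z/K = %.2f)\n",
              x$m_over_k, x$f_over_k, x$m_over_k + x$f_over_k))
  cat(sprintf("  selection: Lc = %.1f cm, alpha = %.1f /cm\n", x$lc, x$alpha))
  cat(sprintf("  allometry: W = %.3g * L^%.2f (L in mm, W in g)\n",
              x$lw_a, x$lw_b))
  cat(sprintf("  n_fish = %d, seed = %d\n", x$n_fish, x$seed))
  invisible(x)
}
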