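#' Simulate a length-frequency sample from a population scenario
#'
#' Generates binned fork-length counts with the statistical structure the
#' length-based assessment assumes. Each recruit draws an individual
#' asymptotic length `Linf_i ~ Normal(linf_mean, linf_cv * linf_mean)` and
#' is walked through the length bins; survival across bin `[L1, L2)` has
#' probability `((Linf_i - L2)/(Linf_i - L1))^(M/K + F/K * S(L1))` where
#' `S` is the logistic selection ogive.
#'
#' Two sampling conventions are offered. `"survey"` (default) records each
#' fish in every bin it survives into, retained with probability `S(L)`:
#' expected counts are proportional to standing numbers times selectivity,
#' exactly the quantity the equilibrium length-structure model of
#' [expected_catch_proportions()] predicts. `"catch"` records a fish once,
#' in the bin where it dies to fishing (a removals sample); this is the
#' convention under which the length-converted catch curve estimates Z.
#'
#' `recruitment = "continuous"` gives the smooth equilibrium structure of
#' the Bayesian biomass model. `recruitment = "pulsed"` places annual
#' cohorts on the growth trajectory (phase `t_anchor`) with survivorship
#' weights, producing the modal peaks ELEFAN needs to resolve K.
#'
#' @param scenario a [population_scenario()].
#' @param bin_width bin width in mm (default 10).
#' @param year year label written into the table.
#' @param recruitment `"continuous"` (equilibrium) or `"pulsed"` (annual
#'   cohorts).
#' @param sample `"survey"` (standing stock times selectivity) or
#'   `"catch"` (fishing removals).
#' @param t_anchor birth phase of the pulsed cohorts as a fraction of a
#'   year before the sampling instant.
#' @return a [length_frequency] table; counts sum to the number of
#'   retained fish. Deterministic given `scenario$seed`.
#' @examples
#' lf <- simulate_length_frequency(population_scenario(n_fish = 2000, seed = 7))
#' sum(lf$count)
#' @export
simulate_length_frequency <- function(scenario, bin_width = 10, year = 1L,
                                      recruitment = c("continuous", "pulsed"),
                                      sample = c("survey", "catch"),
                                      t_anchor = 0.4) {
  if (!inherits(scenario, "population_scenario"))
    stop_param("scenario must be a population_scenario")
  check_positive(bin_width, "bin_width")
  recruitment <- match.arg(recruitment)
  sample <- match.arg(sample)
  set.seed(scenario$seed)
  n <- scenario$n_fish
  linf_i <- scenario$linf_mean *
    pmax(0.3, 1 + scenario$linf_cv * stats::rnorm(n))
  w_cm <- bin_width / 10
  nb <- ceiling(max(linf_i) / w_cm) + 1L
  edges <- seq(0, by = w_cm, length.out = nb + 1L)

  lengths_cm <- if (recruitment == "continuous") {
    sim_walk(scenario, linf_i, edges, sample)
  } else {
    sim_pulsed(scenario, linf_i, t_anchor, sample)
  }
  counts <- tabulate(findInterval(lengths_cm, edges), nbins = nb)
  nz <- which(counts > 0)
  if (length(nz) < 2L)
    stop_data("simulated sample has fewer than 2 non-empty bins; ",
              "increase n_fish or check the scenario")
  keep <- nz[1]:nz[length(nz)]
  length_frequency(year = rep(as.integer(year), length(keep)),
                   bin_lower = edges[keep] * 10,
                   count = counts[keep], bin_width = bin_width)
}

# bin-by-bin survival walk; returns lengths (cm) of retained fish
sim_walk <- function(sc, linf_i, edges, sample) {
  n <- length(linf_i)
  alive <- rep(TRUE, n)
  out <- vector("list", length(edges) - 1L)
  for (i in seq_len(length(edges) - 1L)) {
    idx <- which(alive)
    if (length(idx) == 0L) break
    l1 <- edges[i]; l2 <- edges[i + 1L]
    s <- selectivity_ogive(l1, sc$lc, sc$alpha)
    if (sample == "survey") {
      ret <- idx[stats::runif(length(idx)) < s]
      if (length(ret)) out[[i]] <- rep((l1 + l2) / 2, length(ret))
    }
    can_pass <- linf_i[idx] > l2
    p_surv <- numeric(length(idx))
    p_surv[can_pass] <- ((linf_i[idx][can_pass] - l2) /
                         (linf_i[idx][can_pass] - l1))^
      (sc$m_over_k + sc$f_over_k * s)
    dies <- stats::runif(length(idx)) >= p_surv
    if (sample == "catch" && any(dies)) {
      zk_bin <- sc$m_over_k + sc$f_over_k * s
      p_caught <- sc$f_over_k * s / zk_bin
      dead <- idx[dies]
      caught <- dead[stats::runif(length(dead)) < p_caught]
      if (length(caught)) out[[i]] <- rep((l1 + l2) / 2, length(caught))
    }
    alive[idx[dies]] <- FALSE
  }
  unlist(out)
}

# annual cohorts on the VBGF trajectory, survivorship-weighted
sim_pulsed <- function(sc, linf_i, t_anchor, sample) {
  dt <- 1 / 24
  amax <- min(20, 3 / sc$k)   # longevity by the tmax ~ 3/K rule of thumb
  agrid <- seq(0, amax, by = dt)
  lgrid <- sc$linf_mean * (1 - exp(-sc$k * agrid))
  zgrid <- sc$k * (sc$m_over_k +
                   sc$f_over_k * selectivity_ogive(lgrid, sc$lc, sc$alpha))
  surv <- exp(-cumsum(zgrid * dt))
  ages <- t_anchor + 0:floor(amax - t_anchor)
  w <- surv[pmax(1L, round(ages / dt))]
  keep <- w > 1e-6
  ages <- ages[keep]; w <- w[keep]
  a_i <- ages[sample.int(length(ages), length(linf_i), replace = TRUE,
                         prob = w)]
  l_i <- linf_i * (1 - exp(-sc$k * a_i))
  p_ret <- selectivity_ogive(l_i, sc$lc, sc$alpha)
  if (sample == "catch") {
    zk_l <- sc$m_over_k + sc$f_over_k * p_ret
    p_ret <- p_ret * sc$f_over_k / zk_l
  }
  l_i[stats::runif(length(l_i)) < p_ret]
}

#' Simulate length-weight records
#'
#' Draws fish from the scenario's population (ages approximately
#' exponential under total mortality Z = K(M/K + F/K), lengths from the
#' growth curve with individual Linf) and assigns weights by the
#' allometric relationship `W = a * L^b * exp(eps)` with
#' `eps ~ Normal(0, noise_sd^2)`; lengths in mm, weights in g.
#'
#' @param scenario a [population_scenario()].
#' @param n number of records (>= 2).
#' @param noise_sd standard deviation of the multiplicative log-scale
#'   weight noise (>= 0).
#' @return a `data.frame` with columns `fork_length` (mm), `weight` (g),
#'   `age` (year), `sex` (`"F"`, `"M"`). Deterministic given
#'   `scenario$seed`.
#' @export
simulate_length_weight <- function(scenario, n = 1000, noise_sd = 0.05) {
  if (!inherits(scenario, "population_scenario"))
    stop_param("scenario must be a population_scenario")
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop_param("n must be at least 2")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop_param("noise_sd must be non-negative")
  set.seed(scenario$seed)
  n <- as.integer(n)
  z <- scenario$k * (scenario$m_over_k + scenario$f_over_k)
  age <- stats::rexp(n, rate = z) + 0.3
  linf_i <- scenario$linf_mean *
    pmax(0.3, 1 + scenario$linf_cv * stats::rnorm(n))
  l_mm <- 10 * linf_i * (1 - exp(-scenario$k * age))
  eps <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  w <- scenario$lw_a * l_mm^scenario$lw_b * exp(eps)
  sex <- base::sample(c("F", "M"), n, replace = TRUE, prob = c(0.6, 0.4))
  data.frame(fork_length = l_mm, weight = w, age = age, sex = sex)
}

#' Simulate a purse-seine fishing logbook
#'
#' Operation positions are bivariate normal around an annually drifting
#' centroid, truncated to the study box (default 35-45 N, 145-160 E);
#' catches are lognormal with a median that declines geometrically by year
#' (emulating a falling CPUE), and net deployments are `1 + Poisson`.
#'
#' @param years integer vector of years (non-empty).
#' @param ops_per_year operations per year.
#' @param centroid_path list of `c(lat, lon)` per year (recycled if a
#'   single centroid); each must lie inside `box`.
#' @param spread_deg standard deviation (degrees) of positions around the
#'   centroid; 0 puts every operation at the centroid.
#' @param seed integer seed.
#' @param catch_median first-year median catch per operation (tonnes).
#' @param catch_decline proportional decline of the median per year.
#' @param catch_sdlog lognormal sdlog of catches.
#' @param nets_lambda Poisson mean of extra net deployments per operation.
#' @param box study box `c(lat_min, lat_max, lon_min, lon_max)`.
#' @return a `data.frame` with columns `date`, `lat`, `lon`, `nets`,
#'   `catch` (tonnes).
#' @export
simulate_logbook <- function(years, ops_per_year = 1000,
                             centroid_path = list(c(40, 151)),
                             spread_deg = 1, seed = 1L,
                             catch_median = 3, catch_decline = 0.1,
                             catch_sdlog = 0.8, nets_lambda = 1,
                             box = c(35, 45, 145, 160)) {
  if (length(years) == 0L) stop_param("years must be non-empty")
  if (!is.list(centroid_path)) centroid_path <- list(centroid_path)
  if (length(centroid_path) == 1L)
    centroid_path <- rep(centroid_path, length(years))
  if (length(centroid_path) != length(years))
    stop_param("centroid_path must have one centroid per year")
  for (ctr in centroid_path) {
    if (length(ctr) != 2L || ctr[1] < box[1] || ctr[1] > box[2] ||
        ctr[2] < box[3] || ctr[2] > box[4])
      stop_param("centroids must be c(lat, lon) inside the study box")
  }
  check_nonneg(spread_deg, "spread_deg")
  check_positive(ops_per_year, "ops_per_year")
  set.seed(seed)
  out <- vector("list", length(years))
  for (yi in seq_along(years)) {
    ctr <- centroid_path[[yi]]
    m <- as.integer(ops_per_year)
    lat <- rep(ctr[1], m); lon <- rep(ctr[2], m)
    if (spread_deg > 0) {
      todo <- seq_len(m)
      while (length(todo)) {  # resample outside-box draws (truncation)
        lat[todo] <- stats::rnorm(length(todo), ctr[1], spread_deg)
        lon[todo] <- stats::rnorm(length(todo), ctr[2], spread_deg)
        todo <- todo[lat[todo] < box[1] | lat[todo] > box[2] |
                     lon[todo] < box[3] | lon[todo] > box[4]]
      }
    }
    nets <- 1L + stats::rpois(m, nets_lambda)
    med <- catch_median * (1 - catch_decline)^(yi - 1)
    catch <- stats::rlnorm(m, meanlog = log(med), sdlog = catch_sdlog)
    month <- base::sample(5:11, m, replace = TRUE)
    day <- base::sample(1:28, m, replace = TRUE)
    out[[yi]] <- data.frame(
      date = as.Date(sprintf("%d-%02d-%02d", years[yi], month, day)),
      lat = lat, lon = lon, nets = nets, catch = catch)
  }
  do.call(rbind, out)
}
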