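test_that("scenario constructor validates its fields", {
  expect_s3_class(test_scenario(), "population_scenario")
  expect_error(test_scenario(linf_mean = -1), class = "lenstock_param_error")
  expect_error(test_scenario(m_over_k = 0), class = "lenstock_param_error")
  expect_error(test_scenario(lc = 50), class = "lenstock_param_error")
  expect_error(test_scenario(n_fish = 0), class = "lenstock_param_error")
  expect_error(test_scenario(f_over_k = -0.1), class = "lenstock_param_error")
})

test_that("length-frequency simulation is deterministic given the seed", {
  sc <- test_scenario(n_fish = 2000, seed = 11)
  expect_identical(simulate_length_frequency(sc),
                   simulate_length_frequency(sc))
  expect_identical(simulate_length_frequency(sc, recruitment = "pulsed"),
                   simulate_length_frequency(sc, recruitment = "pulsed"))
  expect_identical(simulate_length_frequency(sc, sample = "catch"),
                   simulate_length_frequency(sc, sample = "catch"))
})

test_that("simulated counts are non-negative integers summing to the catch", {
  lf <- simulate_length_frequency(test_scenario(n_fish = 3000, seed = 2))
  expect_true(all(lf$count >= 0))
  expect_identical(lf$count, as.integer(round(lf$count)))
  expect_gt(sum(lf$count), 0)
})

test_that("survey-mode proportions converge to the survivorship recursion", {
  # full selection, no fishing, no Linf spread: the standing-stock sample
  # must reproduce the closed-form recursion within binomial noise
  sc <- test_scenario(linf_cv = 0, f_over_k = 0, lc = 1e-3, alpha = 1000,
                      n_fish = 50000, seed = 3)
  lf <- simulate_length_frequency(sc)
  edges <- c(lf$bin_lower, max(lf$bin_lower) + 10) / 10
  edges <- pmin(edges, sc$linf_mean - 1e-9)
  p_exp <- oracle_catch_props(sc$linf_mean, sc$lc, sc$alpha,
                              sc$m_over_k, 0, edges)
  p_obs <- lf$count / sum(lf$count)
  expect_lt(max(abs(p_obs - p_exp)), 0.005)
})

test_that("selection ogive keeps small fish out of the catch", {
  sc <- test_scenario(lc = 20, alpha = 2, n_fish = 20000, seed = 4)
  lf <- simulate_length_frequency(sc)
  below <- lf$bin_lower + 5 < 150   # midpoints under 15 cm
  expect_lt(sum(lf$count[below]) / sum(lf$count), 0.02)
})

test_that("higher fishing pressure shifts the catch toward smaller fish", {
  mean_len <- vapply(c(0, 0.5, 1.5), function(fk) {
    sc <- test_scenario(f_over_k = fk, n_fish = 50000, seed = 5)
    lf <- simulate_length_frequency(sc)
    sum(lf_midpoints(lf) * lf$count) / sum(lf$count)
  }, numeric(1))
  expect_true(all(diff(mean_len) < 0))
})

test_that("length-weight records follow the allometry exactly when noiseless", {
  sc <- test_scenario(lw_a = 1e-5, lw_b = 3, seed = 6)
  rec <- simulate_length_weight(sc, n = 200, noise_sd = 0)
  expect_equal(rec$weight, 1e-5 * rec$fork_length^3, tolerance = 1e-12)
  # closed form at L = 200 mm: W = 1e-5 * 200^3 = 80 g
  expect_equal(1e-5 * 200^3, 80)
  expect_error(simulate_length_weight(sc, n = 1), class = "lenstock_param_error")
  expect_error(simulate_length_weight(sc, n = 10, noise_sd = -1),
               class = "lenstock_param_error")
})

test_that("logbook simulation respects the box, the centroid and the seed", {
  yrs <- 2016:2018
  path <- list(c(40, 150), c(41, 151), c(42, 152))
  lb <- simulate_logbook(yrs, ops_per_year = 200, centroid_path = path,
                         spread_deg = 1, seed = 9)
  expect_true(all(lb$lat >= 35 & lb$lat <= 45))
  expect_true(all(lb$lon >= 145 & lb$lon <= 160))
  expect_true(all(lb$nets >= 1))
  expect_true(all(lb$catch >= 0))
  expect_identical(lb, simulate_logbook(yrs, ops_per_year = 200,
                                        centroid_path = path,
                                        spread_deg = 1, seed = 9))
  # zero spread pins every operation at the centroid
  lb0 <- simulate_logbook(2016, ops_per_year = 50,
                          centroid_path = list(c(40, 150)),
                          spread_deg = 0, seed = 1)
  expect_true(all(lb0$lat == 40) && all(lb0$lon == 150))
  expect_error(simulate_logbook(integer(0)), class = "lenstock_param_error")
  expect_error(simulate_logbook(2016, centroid_path = list(c(50, 150))),
               class = "lenstock_param_error")
})

test_that("gravity centers of simulated logbooks recover the specified path", {
  yrs <- 2016:2017
  path <- list(c(39, 150), c(42, 155))
  lb <- simulate_logbook(yrs, ops_per_year = 5000, centroid_path = path,
                         spread_deg = 0.8, seed = 13)
  for (i in seq_along(yrs)) {
    g <- center_of_gravity(lb, yrs[i])
    expect_equal(g$lat, path[[i]][1], tolerance = 0.05)
    expect_equal(g$lon, path[[i]][2], tolerance = 0.05)
  }
})
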