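test_that("expected catch proportions normalize and match the oracle", {
  edges <- seq(10, 38, 1)
  set.seed(17)
  for (i in 1:20) {
    linf <- runif(1, 39, 45); lc <- runif(1, 12, 25)
    alpha <- runif(1, 0.5, 30); mk <- runif(1, 0.8, 2.5)
    fk <- runif(1, 0, 2)
    p <- expected_catch_proportions(linf, lc, alpha, mk, fk, edges)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
    expect_equal(p, oracle_catch_props(linf, lc, alpha, mk, fk, edges),
                 tolerance = 1e-12)
  }
  # no fishing, fully selected: pure survivorship recursion
  p0 <- expected_catch_proportions(40, 1e-6, 1000, 1.5, 0, edges)
  nb <- length(edges) - 1
  n_at <- c(1, cumprod(((40 - edges[-1]) /
                        (40 - edges[-length(edges)]))^1.5))[seq_len(nb)]
  expect_equal(p0, n_at / sum(n_at), tolerance = 1e-9)
  expect_error(expected_catch_proportions(30, 15, 2, 1.5, 0.5, edges),
               class = "lenstock_param_error")
})

test_that("fishing pressure drains the large-fish tail of the catch", {
  edges <- seq(10, 38, 1)
  topq <- function(fk) {
    p <- expected_catch_proportions(40, 20, 2, 1.5, fk, edges)
    sum(p[(length(p) - length(p) %/% 4):length(p)])
  }
  v <- vapply(c(0, 0.5, 1.5), topq, numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("optimal-length reference points reproduce the published table", {
  linf <- c(39.7, 36.8, 39.5, 36.2, 41.3, 38.9)
  mk <- c(1.58, 1.48, 1.24, 1.64, 1.71, 1.27)
  fk <- c(0.52, 0.58, 0.26, 0.47, 0.57, 0.61)
  expect_equal(round(l_opt(linf, mk)), c(26, 25, 28, 23, 26, 27))
  expect_equal(round(lc_opt(linf, fk / mk, mk)), c(19, 19, 20, 17, 20, 21))
  expect_equal(l_opt(40, 1e-9), 40, tolerance = 1e-6)     # mk -> 0 limit
  expect_equal(lc_opt(24, 1, 3), 24 * 5 / 12)             # closed form
})

test_that("the per-recruit chain reproduces the published relative biomass", {
  expect_equal(round(relative_yield_per_recruit(39.5, 24.4, 1.24, 0.26)$bb0, 2),
               0.77)
  expect_equal(round(relative_yield_per_recruit(38.9, 22.0, 1.27, 0.61)$bb0, 2),
               0.57)
  # without fishing the exploited and unexploited biomass coincide
  for (lc in c(10, 18, 26))
    expect_equal(relative_yield_per_recruit(40, lc, 1.5, 0)$bb0, 1,
                 tolerance = 1e-12)
  expect_equal(round(bmsy_proxy(39.5, 1.24), 3), 0.377)
  rp18 <- reference_points(39.5, 24.4, 1.24, 0.26)
  expect_equal(round(rp18$bbmsy, 1), 2.0)
  rp16 <- reference_points(39.7, 19.8, 1.58, 0.52)
  expect_equal(round(rp16$bbmsy, 1), 1.8)
  expect_equal(b_over_bmsy(0.4, 0.4), 1)
  expect_error(b_over_bmsy(0.5, 0), class = "lenstock_param_error")
})

test_that("reference-point identities hold across the parameter space", {
  set.seed(23)
  for (i in 1:50) {
    linf <- runif(1, 30, 45); mk <- runif(1, 0.5, 2.5)
    fm <- runif(1, 0.05, 3); fk <- fm * mk
    expect_lt(lc_opt(linf, fm, mk), l_opt(linf, mk))
    expect_lt(l_opt(linf, mk), linf)
    # E = F/Z equals (F/M) / (1 + F/M) identically
    expect_equal(fk / (mk + fk), fm / (1 + fm), tolerance = 1e-12)
  }
  # bb0 decreases with fishing and increases with Lc
  bb0_f <- vapply(seq(0, 2, 0.25),
                  function(fk) relative_yield_per_recruit(40, 20, 1.5, fk)$bb0,
                  numeric(1))
  expect_true(all(diff(bb0_f) < 0))
  bb0_lc <- vapply(seq(12, 34, 2),
                   function(lc) relative_yield_per_recruit(40, lc, 1.5, 0.6)$bb0,
                   numeric(1))
  expect_true(all(diff(bb0_lc) > 0))
  # Bmsy/B0 declines as natural turnover rises
  bmsy <- vapply(seq(0.5, 2.5, 0.25), function(mk) bmsy_proxy(39.5, mk),
                 numeric(1))
  expect_true(all(diff(bmsy) < 0))
})

test_that("length indicators match a brute-force percentile oracle", {
  cts <- c(3L, 10L, 25L, 12L, 4L)
  lf <- length_frequency(1L, seq(200, 240, 10), cts)
  mids <- lf_midpoints(lf) / 10
  est <- list(linf = 26, lc = 21.4)
  rp <- reference_points(26, 21.4, 1.5, 0.5)
  ind <- length_indicators(lf, est, rp)
  expect_equal(ind$l95th, unname(quantile(rep(mids, cts), 0.95)),
               tolerance = 1e-12)
  above <- mids > est$lc
  expect_equal(ind$lmean, sum(mids[above] * cts[above]) / sum(cts[above]))
  expect_equal(ind$lc_over_lcopt, est$lc / rp$lc_opt)
  # every fish essentially at Linf: the L95/Linf indicator reaches 1
  lf_top <- length_frequency(1L, c(240, 250), c(1L, 1000L))
  ind_top <- length_indicators(lf_top, list(linf = 25.5, lc = 20),
                               reference_points(25.5, 20, 1.5, 0.5))
  expect_equal(ind_top$l95_over_linf, 1, tolerance = 1e-3)
})

test_that("status labels follow the biomass and pressure thresholds", {
  expect_equal(classify_status(0.65, 1.8, 0.33), "healthy")
  expect_equal(classify_status(0.4, 0.3, 0.5), "overfished")
  expect_equal(classify_status(0.5, 1.0, 1.0), "healthy")   # inclusive boundary
  expect_equal(classify_status(0.4, 0.7, 0.5), "fully exploited")
  expect_equal(classify_status(0.6, 1.2, 1.5), "fully exploited")
  expect_equal(classify_status(0.1, 0.1, 2), "collapsed")
})

test_that("near-degenerate priors pin the posterior at the prior medians", {
  sc <- test_scenario(n_fish = 4000, seed = 19)
  lf <- simulate_length_frequency(sc)
  pr <- lbb_priors(40, 20, 2, 1.5, 0.5,
                   prior_cvs = c(linf = 1e-4, lc = 1e-4, alpha = 1e-4,
                                 mk = 1e-4, fk = 1e-4))
  fit <- suppressWarnings(
    fit_lbb(lf, priors = pr, mcmc = lbb_mcmc_control(chains = 1,
                                                     iter = 3000, burn = 1000),
            seed = 5))
  e <- fit$estimates
  expect_equal(e$linf, 40, tolerance = 0.005)
  expect_equal(e$lc, 20, tolerance = 0.005)
  expect_equal(e$mk, 1.5, tolerance = 0.005)
  expect_equal(e$fk, 0.5, tolerance = 0.005)
  expect_equal(e$zk, e$mk + e$fk, tolerance = 1e-9)
  expect_equal(e$e, e$fk / e$zk, tolerance = 1e-9)
})

test_that("the LBB fit is deterministic given the seed and flags short runs", {
  sc <- test_scenario(n_fish = 4000, seed = 25)
  lf <- simulate_length_frequency(sc)
  pr <- suppressMessages(default_lbb_priors(lf))
  ctl <- lbb_mcmc_control(chains = 2, iter = 3000, burn = 1000)
  f1 <- suppressWarnings(fit_lbb(lf, priors = pr, mcmc = ctl, seed = 77))
  f2 <- suppressWarnings(fit_lbb(lf, priors = pr, mcmc = ctl, seed = 77))
  expect_identical(f1$estimates, f2$estimates)
  expect_warning(
    fit_lbb(lf, priors = pr,
            mcmc = lbb_mcmc_control(chains = 1, iter = 400, burn = 200,
                                    thin = 1, ess_floor = 1e6), seed = 1),
    "unconverged")
  # too-sparse tables are refused
  lf_small <- length_frequency(1L, seq(200, 240, 10), c(5L, 9L, 7L, 3L, 1L))
  expect_error(fit_lbb(lf_small), class = "lenstock_data_error")
})

test_that("fixing Linf externally holds it fixed in the posterior", {
  sc <- test_scenario(n_fish = 4000, seed = 29)
  lf <- simulate_length_frequency(sc)
  pr <- suppressMessages(default_lbb_priors(lf))
  fit <- suppressWarnings(
    fit_lbb(lf, priors = pr, linf_fixed = 40.2,
            mcmc = lbb_mcmc_control(chains = 1, iter = 2000, burn = 500),
            seed = 3))
  expect_equal(fit$estimates$linf, 40.2)
  expect_equal(unname(fit$ci["97.5%", "linf"]), 40.2)
})
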