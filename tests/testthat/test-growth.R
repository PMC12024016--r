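test_that("Pauly's t0 formula reproduces the annual growth-table values", {
  # (Linf, K) pairs with their published t0, reproducible under rounding
  cases <- rbind(c(39.05, 0.65, -0.23), c(39.01, 0.88, -0.17),
                 c(36.30, 0.42, -0.37), c(42.35, 0.58, -0.25),
                 c(38.08, 0.55, -0.28))
  for (i in seq_len(nrow(cases)))
    expect_equal(round(estimate_t0(cases[i, 1], cases[i, 2]), 2), cases[i, 3])
  expect_equal(round(estimate_t0(40, 0.5), 3), -0.302)
  expect_lt(estimate_t0(30, 0.3), 0)   # always negative
  expect_error(estimate_t0(-1, 0.5), class = "lenstock_param_error")
})

test_that("growth performance index matches its closed form", {
  expect_equal(growth_performance(10, 1), 2)
  expect_equal(round(growth_performance(36.30, 0.42), 2), 2.74)
  expect_equal(round(growth_performance(38.08, 0.55), 2), 2.90)
  expect_error(growth_performance(0, 1), class = "lenstock_param_error")
})

test_that("predicted length is zero at t0, increasing, and bounded by Linf", {
  vb <- vbgf_params(39.05, 0.65, -0.23)
  expect_equal(predict_length(vb, vb$t0), 0)
  expect_equal(predict_length(vb, 1), 21.50, tolerance = 5e-3)
  t <- seq(-0.2, 12, by = 0.1)
  l <- predict_length(vb, t)
  expect_true(all(diff(l) > 0))
  expect_true(all(l < vb$linf))
  expect_error(predict_length(vb, -1), class = "lenstock_param_error")
})

test_that("restructuring matches a step-by-step oracle", {
  # hand-sized example with a spike, a shoulder and interior zeros
  counts <- c(0L, 2L, 30L, 8L, 0L, 1L, 12L)
  lf <- length_frequency(rep(1L, 7), seq(100, 160, 10), counts)
  rs <- restructure_lf(lf)
  expect_equal(rs$score, oracle_restructure(counts), tolerance = 1e-12)
  # randomized property: oracle equality across shapes and window sizes
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(7:25, 1)
    cts <- as.integer(rpois(n, lambda = sample(c(2, 8, 40), 1)))
    if (sum(cts > 0) < 2) cts[1:2] <- c(5L, 7L)
    w <- sample(c(3, 5, 7), 1)
    if (n < w) next
    lf <- length_frequency(rep(1L, n), seq(100, by = 10, length.out = n), cts)
    expect_equal(restructure_lf(lf, w)$score, oracle_restructure(cts, w),
                 tolerance = 1e-12)
  }
})

test_that("restructured scores are zero for uniform counts, one at a spike", {
  lf_u <- length_frequency(rep(1L, 9), seq(100, 180, 10), rep(4L, 9))
  expect_true(all(abs(restructure_lf(lf_u)$score) < 1e-12))
  cts <- c(0L, 0L, 0L, 50L, 0L, 0L, 2L)
  lf_s <- length_frequency(rep(1L, 7), seq(100, 160, 10), cts)
  rs <- restructure_lf(lf_s)
  expect_equal(max(rs$score), 1)
  expect_equal(which.max(rs$score), 4L)
  expect_equal(rs$score[c(3, 5)], c(-1, -1))  # flanking zeros penalized
  expect_error(restructure_lf(lf_s, ma_window = 9), class = "lenstock_data_error")
})

test_that("curve scoring spans the Rn range and respects its bounds", {
  cts <- c(0L, 40L, 0L, 0L, 0L, 35L, 0L, 0L, 30L, 0L)
  lf <- length_frequency(rep(1L, 10), seq(150, 240, 10), cts)
  rs <- restructure_lf(lf)
  expect_error(score_growth_curve(rs, 20, 0.5), class = "lenstock_param_error")
  # sweep candidates: esp <= asp and rn in (0.1, 1] throughout
  for (linf in c(26, 30, 40)) for (k in c(0.3, 0.6, 1.2)) {
    s <- score_growth_curve(rs, linf, k, 0.25)
    expect_lte(s$esp, s$asp + 1e-12)
    expect_gte(s$rn_score, 0.1)
    expect_lte(s$rn_score, 1)
  }
  # a curve threading every peak explains the full ASP
  best <- 0
  for (linf in seq(25, 45, 0.5)) for (k in seq(0.2, 1.5, 0.05))
    for (a in seq(0, 0.96, 1 / 24)) {
      s <- score_growth_curve(rs, linf, k, a)
      best <- max(best, s$rn_score)
    }
  expect_equal(best, 1)
})

test_that("ESP agrees with an exhaustive bin-walk oracle", {
  cts <- c(2L, 25L, 3L, 0L, 14L, 1L, 0L, 9L, 2L)
  lf <- length_frequency(rep(1L, 9), seq(120, 200, 10), cts)
  rs <- restructure_lf(lf)
  edges <- seq(12, 21, 1)
  oracle_esp <- function(linf, k, anchor) {
    w <- 1
    l_stop <- min(max(edges), linf - w / (1 - exp(-k)))
    hits <- integer(0)
    for (j in 0:40) {
      a <- anchor + j
      l <- linf * (1 - exp(-k * a))
      if (l > l_stop) break
      b <- findInterval(l, edges)
      if (b >= 1 && b < length(edges)) hits <- union(hits, b)
    }
    esp <- 0
    for (r in unique(rs$run_id[hits])) {
      in_r <- hits[rs$run_id[hits] == r]
      esp <- esp + if (r == 0) sum(rs$score[in_r]) else max(rs$score[in_r])
    }
    esp
  }
  for (linf in c(22, 25, 30)) for (k in c(0.4, 0.8)) for (a in c(0, 0.3, 0.7))
    expect_equal(score_growth_curve(rs, linf, k, a)$esp,
                 oracle_esp(linf, k, a), tolerance = 1e-12)
})

test_that("ELEFAN recovers the generating growth parameters", {
  sc <- test_scenario(linf_cv = 0.02, n_fish = 50000, seed = 21)
  lf <- simulate_length_frequency(sc, recruitment = "pulsed", t_anchor = 0.7)
  ef <- fit_elefan(lf, c(35, 46), c(0.3, 1.0), resolution = 60)
  expect_lt(abs(ef$params$linf - 40) / 40, 0.05)
  expect_lt(abs(ef$params$k - 0.6) / 0.6, 0.10)
  expect_identical(fit_elefan(lf, c(35, 46), c(0.3, 1.0), resolution = 60),
                   ef)   # deterministic
  expect_error(fit_elefan(lf, c(46, 35), c(0.3, 1.0)),
               class = "lenstock_param_error")
})
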