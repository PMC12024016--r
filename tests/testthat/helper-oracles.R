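# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementations they check.

# survivorship recursion and expected catch proportions, bin by bin
oracle_catch_props <- function(linf, lc, alpha, mk, fk, edges) {
  nb <- length(edges) - 1
  n_at <- numeric(nb)
  n_at[1] <- 1
  s <- numeric(nb)
  for (i in seq_len(nb)) {
    s[i] <- 1 / (1 + exp(-alpha * (edges[i] - lc)))
    if (i < nb) {
      ratio <- (linf - edges[i + 1]) / (linf - edges[i])
      n_at[i + 1] <- n_at[i] * ratio^(mk + fk * s[i])
    }
  }
  ci <- n_at * s
  ci / sum(ci)
}

# step-by-step restructuring following the documented rules
oracle_restructure <- function(counts, w = 5) {
  n <- length(counts)
  h <- (w - 1) / 2
  score <- numeric(n)
  for (i in 1:n) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    ma <- mean(counts[lo:hi])
    score[i] <- if (ma > 0) counts[i] / ma - 1 else 0
  }
  pos <- score > 0
  i <- 1
  while (i <= n) {
    if (pos[i]) {
      j <- i
      while (j < n && pos[j + 1]) j <- j + 1
      for (b in i:j) score[b] <- score[b] / (j - i + 1)
      i <- j + 1
    } else i <- i + 1
  }
  for (i in 1:n) {
    left_peak <- i > 1 && pos[i - 1]
    right_peak <- i < n && pos[i + 1]
    if (counts[i] == 0 && (left_peak || right_peak)) score[i] <- -1
  }
  mx <- 0
  for (i in 1:n) if (pos[i] && score[i] > mx) mx <- score[i]
  if (mx > 0) for (i in 1:n) if (pos[i]) score[i] <- score[i] / mx
  score
}

# Spearman rho as Pearson correlation of mid-ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# default scenario used across tests; overrides via ...
test_scenario <- function(...) {
  args <- utils::modifyList(
    list(linf_mean = 40, linf_cv = 0.05, k = 0.6, m_over_k = 1.5,
         f_over_k = 0.5, lc = 20, alpha = 2, n_fish = 5000, seed = 1L),
    list(...))
  do.call(population_scenario, args)
}
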