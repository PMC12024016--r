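#' von Bertalanffy growth parameters
#'
#' @param linf asymptotic fork length (cm).
#' @param k growth coefficient (1/year).
#' @param t0 theoretical age at length zero (year).
#' @return an object of class `vbgf_params`.
#' @export
vbgf_params <- function(linf, k, t0 = 0) {
  check_positive(linf, "linf")
  check_positive(k, "k")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop_param("t0 must be a single finite number")
  structure(list(linf = linf, k = k, t0 = t0), class = "vbgf_params")
}

#' @export
print.vbgf_params <- function(x, ...) {
  cat(sprintf("VBGF: Lt = %.2f * (1 - exp(-%.2f * (t %+.2f)))\n",
              x$linf, x$k, -x$t0))
  invisible(x)
}

#' Predict length at age from the von Bertalanffy growth function
#'
#' `L(t) = Linf * (1 - exp(-K (t - t0)))`; strictly increasing in `t` and
#' bounded above by `Linf`.
#'
#' @param params a [vbgf_params()] object.
#' @param t age (year), must be `>= t0`.
#' @return predicted fork length (cm).
#' @export
predict_length <- function(params, t) {
  if (!inherits(params, "vbgf_params")) stop_param("params must be vbgf_params")
  if (any(t < params$t0)) stop_param("t must be >= t0")
  params$linf * (1 - exp(-params$k * (t - params$t0)))
}

#' Pauly's empirical estimate of t0
#'
#' `log10(-t0) = -0.3922 - 0.2752 log10(Linf) - 1.038 log10(K)`; always
#' negative.
#'
#' @param linf asymptotic length (cm).
#' @param k growth coefficient (1/year).
#' @return t0 (year).
#' @examples
#' estimate_t0(39.05, 0.65)  # -0.23
#' @export
estimate_t0 <- function(linf, k) {
  check_pos_vec(linf, "linf")
  check_pos_vec(k, "k")
  -10^(-0.3922 - 0.2752 * log10(linf) - 1.038 * log10(k))
}

#' Growth performance index phi-prime
#'
#' `phi' = log10(K) + 2 log10(Linf)`, the standard index for comparing
#' growth across stocks with different Linf-K trade-offs.
#'
#' @inheritParams estimate_t0
#' @return phi-prime (dimensionless).
#' @export
growth_performance <- function(linf, k) {
  check_pos_vec(linf, "linf")
  check_pos_vec(k, "k")
  log10(k) + 2 * log10(linf)
}

#' Restructure a length-frequency sample for ELEFAN scoring
#'
#' Classical moving-average restructuring: each bin's count is divided by
#' the moving average over `ma_window` bins (window clipped at the table
#' edges) and 1 is subtracted, so bins above the local trend score
#' positive ("peaks") and bins below score negative. Runs of `m` adjacent
#' positive bins are down-weighted by `1/m`; zero-count bins adjacent to a
#' peak are penalized with score -1; finally all scores are divided by the
#' maximum positive score so the best peak scores exactly 1.
#'
#' @param table a single-year [length_frequency] table.
#' @param ma_window odd moving-average window (default 5 bins).
#' @return an `lf_restructured` object: data frame with `bin_lower`,
#'   `count`, `score`, plus peak bookkeeping used by
#'   [score_growth_curve()].
#' @export
restructure_lf <- function(table, ma_window = 5) {
  if (!inherits(table, "length_frequency")) stop_data("table must be a length_frequency")
  if (length(unique(table$year)) != 1L)
    stop_data("restructure one year at a time")
  if (ma_window %% 2 != 1 || ma_window < 3) stop_param("ma_window must be odd and >= 3")
  n <- nrow(table)
  if (n < ma_window) stop_data("fewer bins than ma_window")
  counts <- table$count
  h <- (ma_window - 1) / 2
  ma <- vapply(seq_len(n), function(i)
    mean(counts[max(1, i - h):min(n, i + h)]), numeric(1))
  score <- ifelse(ma > 0, counts / ma - 1, 0)
  # down-weight runs of adjacent positive bins
  pos <- score > 0
  run_id <- integer(n)
  rid <- 0L
  i <- 1L
  while (i <= n) {
    if (pos[i]) {
      j <- i
      while (j < n && pos[j + 1L]) j <- j + 1L
      rid <- rid + 1L
      run_id[i:j] <- rid
      score[i:j] <- score[i:j] / (j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  # penalize zero-count bins flanking a peak
  for (i in seq_len(n)) {
    if (counts[i] == 0 &&
        ((i > 1 && pos[i - 1L]) || (i < n && pos[i + 1L])))
      score[i] <- -1
  }
  mx <- max(score[pos], 0)
  if (mx > 0) score[pos] <- score[pos] / mx
  run_value <- if (rid > 0)
    vapply(seq_len(rid), function(r) max(score[run_id == r]), numeric(1))
  else numeric(0)
  structure(list(bin_lower = table$bin_lower, count = counts,
                 score = score, run_id = run_id, run_value = run_value,
                 bin_width = lf_bin_width(table)),
            class = "lf_restructured")
}

#' @export
print.lf_restructured <- function(x, ...) {
  cat(sprintf("Restructured LF: %d bins, %d peak run(s), ASP = %.3f\n",
              length(x$score), length(x$run_value), sum(x$run_value)))
  invisible(x)
}

#' Score a candidate growth curve against restructured peaks
#'
#' The VBGF trajectory with asymptote `linf`, coefficient `k` and annual
#' cohort phase `t_anchor` is traced through the length bins; the
#' explained sum of peaks (ESP) adds each hit peak's score at most once
#' (plus any negative scores of hit troughs), the available sum of peaks
#' (ASP) is the total score obtainable, and the goodness score is
#' `Rn = 10^(ESP/ASP) / 10`, equal to 0.1 when no peak is explained and 1
#' when all are.
#'
#' @param restructured an [restructure_lf()] result.
#' @param linf candidate asymptotic length (cm); must exceed the largest
#'   non-empty bin midpoint.
#' @param k candidate growth coefficient (1/year).
#' @param t_anchor cohort birth phase, fraction of a year in `[0, 1)`.
#' @return list with `esp`, `asp`, `rn_score`, and the hit bin indices.
#' @export
score_growth_curve <- function(restructured, linf, k, t_anchor = 0) {
  if (!inherits(restructured, "lf_restructured"))
    stop_param("restructured must come from restructure_lf()")
  check_positive(linf, "linf")
  check_positive(k, "k")
  mids_cm <- (restructured$bin_lower + restructured$bin_width / 2) / 10
  max_mid <- max(mids_cm[restructured$count > 0])
  if (linf <= max_mid)
    stop_param("linf must exceed the largest non-empty bin midpoint")
  edges_cm <- c(restructured$bin_lower, max(restructured$bin_lower) +
                  restructured$bin_width) / 10
  asp <- sum(restructured$run_value)
  hits <- curve_hits(edges_cm, linf, k, t_anchor)
  esp <- esp_from_hits(hits, restructured)
  # net-negative ESP (only troughs hit) floors at the no-peak score 0.1
  rn <- if (asp > 0) 10^(max(esp, 0) / asp) / 10 else 0.1
  list(esp = esp, asp = asp, rn_score = rn, hit_bins = hits)
}

# bins (indices) crossed by the curve at annual cohort ages t_anchor + j.
# Tracing stops once the annual length increment falls below one bin
# width: beyond that point successive cohorts are unresolvable and the
# sample's asymptotic pile-up carries no cohort signal.
curve_hits <- function(edges_cm, linf, k, t_anchor) {
  top <- edges_cm[length(edges_cm)]
  w <- edges_cm[2] - edges_cm[1]
  l_stop <- min(top, linf - w / (1 - exp(-k)))
  if (l_stop <= edges_cm[1]) return(integer(0))
  amax <- if (l_stop < linf) -log(1 - l_stop / linf) / k else 30
  ages <- t_anchor + 0:ceiling(min(amax, 30))
  l <- linf * (1 - exp(-k * ages))
  l <- l[l <= l_stop]
  idx <- findInterval(l, edges_cm)
  unique(idx[idx >= 1L & idx < length(edges_cm)])
}

# each peak run contributes at most once: the best-scoring bin actually
# hit in it (off-centre hits earn partial credit, which is what lets the
# search discriminate aliased (Linf, K) combinations); trough bins hit
# contribute their negative scores, penalizing curves slow enough to
# crawl through the valleys between cohort peaks
esp_from_hits <- function(hits, rs) {
  if (length(hits) == 0L) return(0)
  ru <- rs$run_id[hits]
  neg <- sum(rs$score[hits[ru == 0L]])
  pos <- if (any(ru > 0L))
    sum(tapply(rs$score[hits[ru > 0L]], ru[ru > 0L], max))
  else 0
  pos + neg
}

#' Fit von Bertalanffy growth by ELEFAN grid search
#'
#' Maximizes the restructured-peak score `Rn` over a (Linf, K) grid, with
#' the cohort phase `t_anchor` profiled out at each grid point (searched
#' at 1/24-year resolution). Ties are broken in favour of the first grid
#' point encountered (Linf varying fastest), so results are deterministic.
#'
#' @param table a single-year [length_frequency] table.
#' @param linf_range `c(min, max)` of candidate Linf (cm).
#' @param k_range `c(min, max)` of candidate K (1/year).
#' @param resolution grid points per axis (default 60).
#' @param ma_window moving-average window for [restructure_lf()].
#' @param t_anchor_res resolution of the cohort-phase search (year).
#' @return an `elefan_fit`: `params` ([vbgf_params()] with `t0 = 0` at
#'   this stage), `t_anchor`, `rn_score`, `esp`, `asp`, and the full
#'   `search_grid` of evaluated scores.
#' @export
fit_elefan <- function(table, linf_range, k_range, resolution = 60,
                       ma_window = 5, t_anchor_res = 1 / 24) {
  if (!inherits(table, "length_frequency") || nrow(table) == 0L)
    stop_data("table must be a non-empty length_frequency")
  if (length(linf_range) != 2L || diff(linf_range) <= 0 ||
      length(k_range) != 2L || diff(k_range) <= 0 || min(k_range) <= 0)
    stop_param("linf_range and k_range must be increasing intervals")
  rs <- restructure_lf(table, ma_window = ma_window)
  mids_cm <- (rs$bin_lower + rs$bin_width / 2) / 10
  max_mid <- max(mids_cm[rs$count > 0])
  edges_cm <- c(rs$bin_lower, max(rs$bin_lower) + rs$bin_width) / 10
  asp <- sum(rs$run_value)
  linfs <- seq(linf_range[1], linf_range[2], length.out = resolution)
  ks <- seq(k_range[1], k_range[2], length.out = resolution)
  anchors <- seq(0, 1 - t_anchor_res, by = t_anchor_res)
  grid <- expand.grid(linf = linfs, k = ks)
  grid$esp <- NA_real_
  grid$t_anchor <- NA_real_
  best <- list(esp = -Inf)
  for (g in seq_len(nrow(grid))) {
    linf <- grid$linf[g]
    if (linf <= max_mid) next
    k <- grid$k[g]
    esp_a <- vapply(anchors, function(a)
      esp_from_hits(curve_hits(edges_cm, linf, k, a), rs), numeric(1))
    ia <- which.max(esp_a)
    grid$esp[g] <- esp_a[ia]
    grid$t_anchor[g] <- anchors[ia]
    if (esp_a[ia] > best$esp)
      best <- list(esp = esp_a[ia], linf = linf, k = k,
                   t_anchor = anchors[ia])
  }
  if (!is.finite(best$esp))
    stop_param("no grid point has linf above the largest observed length")
  grid$rn <- ifelse(is.na(grid$esp), NA, 10^(pmax(grid$esp, 0) / asp) / 10)
  structure(list(params = vbgf_params(best$linf, best$k, 0),
                 t_anchor = best$t_anchor,
                 rn_score = 10^(max(best$esp, 0) / asp) / 10,
                 esp = best$esp, asp = asp, search_grid = grid),
            class = "elefan_fit")
}

#' @export
print.elefan_fit <- function(x, ...) {
  cat(sprintf("ELEFAN fit: Linf = %.2f cm, K = %.2f /yr (t_anchor = %.3f)\n",
              x$params$linf, x$params$k, x$t_anchor))
  cat(sprintf("  Rn = %.3f (ESP %.3f / ASP %.3f)\n", x$rn_score, x$esp, x$asp))
  invisible(x)
}
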