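---
title: "Length-based stock assessment with lenstock: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Length-based stock assessment with lenstock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lenstock)
```

`lenstock` assembles the standard length-based toolkit for data-limited
stocks — the kind of fishery where logbooks and port measurements exist
but ages, surveys and reliable total-catch series do not. Its reference
case is a chub-mackerel-like small pelagic: fork lengths to ~40 cm,
growth coefficient around 0.6/yr, annual recruitment pulses, a purse
seine with a logistic selection ogive. This vignette explains each model,
the tunable parameters and their defaults, the numerical choices, and
what the synthetic-data tests do and do not demonstrate about real data.

## The equilibrium length-structure model

The core biomass machinery assumes a population at equilibrium under
von Bertalanffy growth, `L(t) = Linf (1 - exp(-K (t - t0)))`, and
length-dependent total mortality `Z(L) = M + F * S(L)`, with the gear
ogive `S(L) = 1 / (1 + exp(-alpha (L - Lc)))`. Written per length bin,
survivors decline as

    N(L[i+1]) = N(L[i]) * ((Linf - L[i+1]) / (Linf - L[i]))^(M/K + F/K * S(L[i]))

and the expected catch composition is `C_i ∝ N_i * S(L_i)`, normalized
to proportions (`expected_catch_proportions()`). Only the ratios M/K and
F/K enter: the equilibrium length structure carries no information about
K itself. Selectivity and survivorship are evaluated at lower bin edges;
with 10 mm bins against a 40 cm asymptote the difference from
midpoint evaluation is far below sampling noise.

### Bayesian fitting and what the data can identify

`fit_lbb()` samples (Linf, Lc, alpha, M/K, F/K) on the log scale with an
adaptive Metropolis sampler (random-walk proposals whose covariance is
adapted to the posterior ridge during burn-in only; defaults 3 chains of
20,000 iterations, 5,000 burn-in, thinning 10) under log-normal priors
and a multinomial likelihood.

Two properties of this likelihood drove design choices:

* **The M/K–F/K split is not identified by length data.** Only the
  length-dependent sum `M/K + F/K * S(L)` shapes the sample, and above
  `Lc` that is simply Z/K. Profiling the exact likelihood on data drawn
  from the model itself shows a flat ridge along which M/K can wander
  from 0 to ~2 at fixed Z/K. Length-based practice therefore treats M/K
  as external knowledge; the default prior is the classical 1.5 for
  short-lived pelagics with a tight CV of 0.1, while F/K — the quantity
  the assessment is about — keeps a diffuse 30% CV (100% would change
  results little; the likelihood pins Z/K well).
* **A handful of fish above any candidate Linf would otherwise veto
  it.** Real fish vary in individual asymptote, so samples contain
  lengths above the population-mean Linf; under a pure multinomial these
  observations have probability zero and force Linf up to the sample
  maximum, dragging Z/K with it. The expected proportions are therefore
  mixed with a uniform outlier component of weight `outlier_frac`
  (default 0.005), which caps the penalty a stray large fish can impose.

When no priors are supplied, data-driven centres are derived and logged:
Linf from `Lmax / 0.95`; Lc and alpha from a logistic fit to the
ascending limb (counts relative to the modal bin, logit-linear
regression); Z/K from the Beverton–Holt mean-length estimator
`(Linf - Lmean)/(Lmean - Lc)` **minus one** — the age-domain derivation
of that estimator counts the time fish spend in a bin, which adds
exactly one unit of Z/K relative to the standing-stock convention the
catch equation uses (see "Two sampling conventions" below). Posterior
point estimates are medians; intervals are central 95%. Effective sample
sizes come from initial-ACF truncation, and fits below `ess_floor`
(default 100) are flagged, never silently returned. An externally
estimated asymptote can be imposed with `linf_fixed`, which is
recommended whenever an independent, reliable Linf exists.

### Per-recruit reference points

From posterior medians the Beverton–Holt relative-biomass chain gives,
with `x = 1 - Lc/Linf`:

* `Y'/R  = F/M/(1+F/M) * x^(M/K) * [1 - 3x/(1+1/(Z/K)) + 3x^2/(1+2/(Z/K)) - x^3/(1+3/(Z/K))]`
* `CPUE'/R = Y'/R / (F/M)`, `B0'/R` the same bracket with F = 0,
  `B/B0 = CPUE'/R ÷ B0'/R`
* `Lopt = 3 Linf / (3 + M/K)`,
  `Lc-opt = Linf (2 + 3 F/M) / ((1+F/M)(3+M/K))`
* `Bmsy/B0` by evaluating the chain at F = M and Lc = Lc-opt, and
  `B/Bmsy = (B/B0) / (Bmsy/B0)`.

These are exact algebraic identities, tested against brute-force
recursion oracles and against published reference values for the
2016–2021 Northwest Pacific chub mackerel assessments. Status labels
follow the usual cut points (healthy at `B/Bmsy >= 1` with `F/M <= 1`,
boundaries inclusive; fully exploited above 0.5; overfished above 0.2;
collapsed below), all configurable.

Report rounding follows field convention: optimal lengths to integer cm,
ratios to two decimals, `B/Bmsy` to one decimal; machine-readable output
keeps full precision.

## Growth: ELEFAN

`fit_elefan()` estimates (Linf, K) from the modal structure of a
length-frequency sample. The restructuring (`restructure_lf()`) is the
classical moving-average scheme: counts divided by the 5-bin clipped
moving average minus one; runs of adjacent positive bins down-weighted
by run length; zero-count bins flanking a peak scored −1; positive
scores rescaled so the best peak is exactly 1. The candidate growth
curve is traced at annual cohort ages `t_anchor + j` and scored as
`Rn = 10^(ESP/ASP)/10`.

Three scoring rules are fixed here because the classical literature
leaves them open, and each is what makes the estimator identifiable on
single annual samples:

1. **Best-hit peak credit.** A peak run counts at most once, at the
   score of the best bin the curve actually hits, so a curve passing
   through a peak's shoulder earns partial credit. Full-run credit makes
   slow/fast (Linf, K) aliases indistinguishable.
2. **Trough penalties stay.** Curves slow enough to crawl through the
   valleys between cohort peaks collect the negative scores they cross;
   without this, the grid optimum collapses to the smallest K searched.
   When the net ESP is negative, Rn floors at 0.1 (the no-peak score),
   keeping `Rn` in `(0.1, 1]`.
3. **Tracing stops when the annual increment drops below one bin
   width** (length `Linf - w/(1 - e^{-K})`): beyond that point cohorts
   are unresolvable and the asymptotic pile-up carries no cohort signal,
   so hitting it should neither reward nor punish a candidate.

The search is a plain grid (default 60 × 60 over the supplied ranges,
anchor profiled at 1/24 yr — finer than monthly sampling), deterministic
with first-encountered ties winning. `estimate_t0()` supplies the
empirical `log10(-t0) = -0.3922 - 0.2752 log10 Linf - 1.038 log10 K`,
and `growth_performance()` the index `phi' = log10 K + 2 log10 Linf`
used to check growth estimates across years for consistency.

## Mortality

`length_converted_catch_curve()` converts bins to relative ages through
the inverse growth curve and regresses `ln(N_i / Δt_i)` on age; Z is the
negative slope, invariant to rescaling counts and to t0. The descending
limb is selected by a rule the classical sources leave informal, fixed
here as: drop bins up to and including the modal `ln(N/Δt)` point plus
one more (incomplete selection), and bins with midpoint above
`0.95 * Linf` (unstable age conversion); both thresholds are arguments.
Bins at or above Linf are excluded with a warning. Natural mortality
comes from the empirical temperature regression
`ln M = -0.0152 - 0.279 ln Linf + 0.654 ln K + 0.463 ln T`; then
`F = Z - M` (negative F is reported with a warning, not clipped) and
`E = F/Z`, where `E < 0.5` is exactly the statement `F < M`.

### Two sampling conventions, and why the package has both

A length sample can represent the **standing stock** filtered by the
gear (counts ∝ `N_i S_i`) or the **removals** accumulated as fish die
(counts ∝ deaths per bin ≈ `N_i Z_i S_i Δt_i`). The two differ by the
time-in-bin factor `Δt_i` — the "pile-up" question debated for
length-based biomass models. The catch equation above uses the
standing-stock convention; the catch curve's `Δt` division assumes
removals. Feeding standing-stock counts to the catch curve estimates
Z + K rather than Z. `simulate_length_frequency()` therefore exposes
`sample = "survey"` (standing stock; what the biomass model assumes) and
`sample = "catch"` (removals; what the catch curve assumes), so each
estimator can be validated under its own convention — and so the
consequence of mixing them up is easy to demonstrate.

## The synthetic-data generator

`population_scenario()` fixes the study conditions; defaults are a
chub-mackerel-like stock (Linf = 40 cm with 5% individual CV, K =
0.6/yr, t0 = −0.25 yr, M/K = 1.5, F/K = 0.5, Lc = 20 cm, alpha = 2/cm,
allometry `W = 6.4e-6 L_mm^3.1` — about 300 g at 30 cm, 5,000 fish,
one seed driving all randomness). Individual-Linf variability (CV 0.05)
is included because real length samples are smooth near the asymptote;
publications in this fishery report inconsistent allometry coefficients,
so the default was chosen once for physical plausibility rather than to
match any printed pair.

`recruitment = "continuous"` walks each fish through the bins of the
equilibrium model — the generative inverse of the biomass model, and the
mode whose proportions converge to the survivorship recursion (tested
against an independent loop-coded oracle at 50,000 fish).
`recruitment = "pulsed"` places annual cohorts on the growth trajectory
with survivorship weights, truncated at the longevity rule-of-thumb
`tmax ≈ 3/K`, which is what gives ELEFAN resolvable modes. Logbooks
(`simulate_logbook()`) put operations bivariate-normally around an
annually drifting centroid truncated to the 35–45° N, 145–160° E study
box, with lognormal catches whose median declines by year and `1 +
Poisson` net deployments; sampling is catch-proportional, the usual
assumption when the measurement protocol is unstated.

What passing the recovery tests shows — and what it does not: the tests
demonstrate that each estimator inverts its own generating model at
realistic sample sizes (ELEFAN within 5%/10% on Linf/K at 50,000 fish
with 2% Linf CV; catch-curve Z within 10% at 100,000 fish; LBB medians
within 10% across six annual samples of 5,000 fish simulated without
individual-Linf spread). Real data add features the generator omits:
seasonal growth oscillation, year-to-year recruitment variation,
spatially structured selectivity, and individual asymptote variability —
the last of which provably biases the single-Linf biomass model's F/K
upward (the fit inflates Linf to cover the stretched upper tail and
compensates with extra mortality). With 5% Linf CV we observe F/K
overestimated by roughly half to one prior CV; conclusions about
absolute fishing pressure from LBB alone should carry that caveat, and
an external Linf (`linf_fixed`) is the best mitigation.

## Spatial analytics

Logbook records aggregate onto half-open 0.5° cells indexed by their
lower-left corner (each boundary point belongs to exactly one cell);
cell CPUE is the total-ratio `sum(catch)/sum(nets)`, not a mean of
per-operation ratios, and CPUE itself is defined as tonnes per net
deployment since the logbooks record nets and catch per operation.
Gravity centers are planar catch-weighted means — adequate over a
~10-degree span and standard in fisheries practice. Spearman
correlations use mid-ranks with a large-sample t approximation, checked
against a Pearson-on-midranks oracle and invariant under monotone
transforms.

## Numerical choices and degenerate inputs

* Lengths are stored in mm in tables (10 mm bins by default) and
  converted to cm at the growth/mortality/biomass module boundaries; the
  allometric `a` is reported in the unit of the supplied lengths, and
  refitting after a mm→cm conversion changes `a` by exactly `10^b`.
* The length-weight fit is log10-log10 OLS (the fisheries convention);
  isometry is judged by a two-sided t-test of `b = 3` at a configurable
  level (default 0.05). Non-positive lengths or weights, fewer than 3
  records, or zero length variance are hard errors.
* `L95th` is the count-weighted 95th percentile of bin midpoints with
  type-7 interpolation (identical to the percentile of the
  midpoint-expanded sample); `Lmean` averages bins above the estimated
  Lc.
* Readers reject malformed input (off-grid or duplicated bins, negative
  counts, zero nets, non-ISO dates) rather than coercing; all writers
  round-trip losslessly.
* End-to-end runs (`run_pipeline()`) derive every stage seed from the
  single config seed, so identical configs give byte-identical reports.
* Test problem sizes (50,000-fish oracle comparisons, six 5,000-fish
  annual samples for the posterior recovery, 60 × 60 ELEFAN grids) were
  chosen as the smallest sizes at which Monte-Carlo noise is comfortably
  below the tolerances being asserted.

## Known limitations

No seasonal growth oscillation; no hierarchical pooling across years
(annual fits are independent); K is in principle unidentifiable from
purely equilibrium length structure, so growth estimation requires modal
(pulsed) data; the M/K–F/K split rests on the M/K prior; and the
single-asymptote biomass model overstates F/K when individual growth
variability is large. None of these are implementation defects — they
are properties of the underlying length-based methods that the package
makes explicit and testable.
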