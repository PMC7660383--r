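---
title: "Symbolic conditional transfer entropy: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symbolic conditional transfer entropy: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symte)
```

## The question and the statistic

The package asks a Wiener–Granger question about monthly public-health count
series: does knowing the present of a candidate driver $X$ improve the
prediction of the future of an outcome $Y$ beyond what $Y$'s own present (and
a set of confounders $Z_1,\dots,Z_q$) already provides? The motivating
application is firearm acquisition: do mass-shooting occurrence, media
coverage of firearm control, media coverage of shootings, or acquisitions in
neighboring states drive a state's federal background checks?

All series are reduced to binary symbols $\{\downarrow,\uparrow\}$ and the
question is answered with the conditional (partial) transfer entropy

$$TE_{X \to Y\,|\,Z_1..Z_q} \;=\; H\!\big(Y(t{+}1)\mid Y(t), Z(t)\big)\;-\;
H\!\big(Y(t{+}1)\mid Y(t), X(t), Z(t)\big),$$

in bits, with all entropies estimated by plug-in frequencies of the
$(q{+}3)$-tuples observed at the $T-1$ adjacent month pairs. With an empty
conditioning set this is plain transfer entropy
$H(Y(t{+}1)\mid Y(t)) - H(Y(t{+}1)\mid Y(t),X(t))$. Only lag-1 histories are
used — no embedding-dimension search — matching the monthly resolution of the
data and keeping the estimation burden at $2^{q+3}$ cells.

Assumptions worth keeping in mind: stationarity of the symbolized series
(this is what the seasonal adjustment is for), monthly resolution coarse
enough that contemporaneous effects are invisible to a lag-1 measure, and
enough samples per joint cell for the plug-in estimator to be meaningful.

## Symbolization

Three rules produce the binary series, each chosen so that the conservative
symbol is $\downarrow$ (encoded 0):

* **Background checks** (`seasonal_adjust_detrend()` then
  `symbolize_sign()`): the raw counts are decomposed by a single ordinary
  least-squares fit on intercept, linear time, and month-of-year indicators;
  the residual's sign gives the symbol, with zero mapping to $\downarrow$.
  The original study used an ARIMA-model-based seasonal adjustment
  (TRAMO/SEATS) whose exact configuration is not reproducible from its
  description; only the *sign* of the anomaly survives symbolization, so a
  classical decomposition is an adequate, fully specified stand-in, and the
  routine is deliberately a small pluggable step. The joint fit (rather than
  sequential detrend-then-demean) is used because a seasonal profile is not
  exactly orthogonal to a linear trend on a finite sample: the joint
  projection reproduces any line-plus-12-month-periodic input with residual
  zero to machine precision, which the sequential recipe does not.
* **Media coverage** (`symbolize_median()` per outlet, then
  `aggregate_mode()` across outlets): months strictly above the outlet's
  sample median map to $\uparrow$; ties go down. The per-month mode across
  the five outlets gives one series per coverage type. Mode ties are possible
  only for even list sizes (the study uses five outlets and odd neighbor
  counts); they resolve to $\downarrow$ with a warning.
* **Mass shootings** (`events_to_binary()`): a month is $\uparrow$ when at
  least one retained event falls in it; multiple same-month events collapse.
  Scopes select all events (national), the focal state's events, or events
  anywhere else — the last deliberately independent of whether the focal
  state also had an event that month, since the source leaves that case
  unstated.

## The permutation null

Significance comes from a structure-preserving permutation test
(`stratified_permute()`, `surrogate_test()`): the effect and conditioning
series are held fixed and the cause symbols are shuffled only among
transition times sharing the same present tuple $(Y(t), Z_1(t),\dots,Z_q(t))$.
This preserves the joint histogram of $(X(t), Y(t), Z(t))$ exactly — the test
destroys only the association between $X(t)$ and $Y(t{+}1)$ within a stratum.
Two readings of "the same tuple for the effect and conditioning processes"
were possible; strata here exclude $Y(t{+}1)$, because including the future
value would preserve the very dependence under test and nullify power.

The p-value is $\#\{\text{surrogate} \ge \text{observed}\}/B$, reported as
"< 1/B" when no surrogate reaches the observed value, and compared strictly
against $\alpha = 0.050$. `q95` is the empirical 95% quantile (default
sample-quantile definition) of the surrogate distribution. $B = 20{,}000$ by
default; tests and examples use reduced values ($B \ge 200$), which they flag
as scaled-down. Because the plug-in estimator is biased upward on short
series, the same bias affects observed and surrogate values alike, so no
analytic bias correction is applied anywhere.

Reproducibility: each member state's permutation stream is seeded
deterministically from (master seed, state code), so a study run is
bit-reproducible and invariant to the ordering of states in a group. Each
state's cause series is permuted independently even when the cause is a
shared national series, because strata involve the state's own effect series
and a single shared permutation would not be well-defined.

## Group aggregation

Per-state values are combined into one statistic per legal-environment group
as

$$TE_{\text{group}} = \frac{\big(\sum_s \mathrm{pop}_s\,
\sqrt{TE_s}\big)^2}{\sum_s \mathrm{pop}_s^2},$$

the square of the population-weighted sum of root transfer entropies over the
sum of squared populations — to first approximation variance controls
entropy, so root-TE adds like a standard deviation. The formula is
implemented exactly as stated in the source, including the property that a
group of $N$ states with identical TE and equal populations aggregates to
$N\cdot TE$ rather than $TE$; it is scale-invariant in the populations, and
the surrogate replicates are aggregated identically, so the test is
internally consistent regardless of that normalization choice.

## Capacity guard

The source remarks that about two hundred observations suffice for binary
symbols and $q \le 2$ confounders, writing the burden as "$b(q+3)$
probability values". Read literally that is linear in $q$; the joint over
$q+3$ binary variables in the estimator has $b^{q+3}$ cells, so the printed
expression is taken as an exponent typo. The guard requires
$T - 1 \ge 5\cdot 2^{q+3}$ (a conventional five-samples-per-cell floor,
configurable via `min_samples_per_cell`), warning by default and erroring
under `strict = TRUE`. At $T = 228$ and $q = 2$ the guard passes
($227 \ge 160$); at $q = 3$ it does not — matching the source's own limit.

## Partitioning and geography

States are split into restrictive and permissive groups by $k$-means with
$k = 2$ on the scalar law-restrictiveness fraction (mean over years of the
fraction of a 133-law catalogue in effect). In one dimension the optimal
two-means partition is an interval split, so `kmeans_partition()` scans all
$n-1$ sorted split points and minimizes the within-cluster sum of squares
exactly — deterministic, seed-free, and free of Lloyd-iteration
initialization artifacts. The cluster with the larger mean is labelled
restrictive. Two units (Connecticut, Hawaii in the real study) are excluded
*before* clustering, config-driven.

Neighbor sets use great-circle (haversine) distance on a 6371-km sphere
between state centroids; ties break lexicographically by code. Neighbors are
drawn from the included states only — excluded units have no usable
background-check series to aggregate — and irrespective of their own cluster.
The neighbor-interaction cause series is the per-month mode of the $n$
nearest states' background-check symbols, $n \in \{1,3,5,7,9\}$.

## The synthetic world

`gen_study_bundle()` and its helpers state the world the tests assume rather
than tuning anything to pass:

* $T = 228$ months (the 1999-01..2017-12 window), 48 units by default;
* populations log-uniform across two orders of magnitude
  ($5\times10^5$–$5\times10^7$);
* law restrictiveness from a two-component normal mixture (modes 0.70/0.20,
  sd 0.05) with an expected 7/48 restrictive share, mirroring the published
  7/41 split of 48 units;
* events at 87/228 per month, assigned to units proportionally to
  population;
* centroids on a jittered grid over a continental-US-like bounding box;
* planted causes: the next background-check symbol copies a chosen driver
  (media, national events, or the current neighbor mode) with a per-group
  coupling probability, and is otherwise a fair coin. Effect series are
  generated symbolically, isolating estimator tests from preprocessing; the
  continuous generator (`gen_monthly_continuous()`) covers the preprocessing
  path separately.

One deliberate deviation: the mediated-chain generator
(`gen_confounded_triplet()`) drives the chain $x \to z \to y$ with a *sticky*
Markov source (persistence 0.9) instead of an iid coin. With an iid driver
and lag-1 measures, $Y(t{+}1) = X(t{-}1)$ is independent of $X(t)$ and the
"spurious" pairwise transfer entropy would be exactly zero — the indirect-
coupling story requires an autocorrelated driver. With persistence $a$, the
pairwise TE is positive while the conditional TE given $z$ is exactly zero,
and both are available in closed form through the exact-pmf oracle
`confounded_pmf()`.

What a green test establishes, and what it does not: the synthetic world has
exact lag-1 couplings, stationary symbol processes, and well-separated
restrictiveness modes. Real background-check data have autocorrelated
residuals, possible regime changes, contemporaneous (within-month) effects
invisible at lag 1, and a restrictiveness distribution whose bimodality is an
empirical finding, not a guarantee. Green tests validate the estimator,
test, and pipeline mechanics — not the substantive conclusions on the
deposited data, which are out of scope here because they require a download.

## Numerical conventions

* $0\log 0 = 0$ in every entropy; plug-in conditional mutual information is
  clamped at zero against $10^{-12}$-scale float noise.
* Degenerate series (all one symbol — e.g., a state with no local shootings)
  yield zero conditional transfer entropy exactly, are flagged in the study
  tables' `degenerate` column, and still enter the population-weighted
  aggregate.
* Surrogate comparison uses `>= observed - 1e-12`, so a fully degenerate
  cell (all surrogates equal to the observed zero) gets $p = 1$, never a
  spurious rejection.
* Median ties, sign zeros, and mode ties all resolve to $\downarrow$.
* The exact-pmf oracle (`te_from_pmf()`) validates normalization to
  $10^{-8}$ and is shared by tests as the independent route against which
  the plug-in path is checked.
* Calendars are strictly monthly (`YYYY-MM`); the last month of a series
  contributes no transition sample, and stratified permutation therefore
  leaves the final cause symbol in place.

## Known limitations

Binary symbolization discards magnitude; lag-1 histories cannot see
contemporaneous or longer-lag effects; the plug-in estimator is biased on
short series (absorbed, not removed, by the permutation null); the group
aggregation formula is implemented as printed and is not normalized by group
size; and the deposited study data are not packaged, so the published table
values are not reproduced here — the packaged 87-event table and the
synthetic generators are the desk-scale world instead. Configuration files
are JSON rather than YAML to stay within the guaranteed dependency set.
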