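---
title: "Virtual-twin causal benchmarking: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-twin causal benchmarking: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hospitals treat different patients. Comparing raw adverse-outcome rates
(operative mortality, stroke, renal failure, ...) across hospitals
therefore confounds institutional quality with case mix. `vtwins`
implements a patient-level alternative: for each patient we ask what
their risk would have been had they been treated at hospital $h$, and
what it would have been at a pooled "overall hospital" $O$ representing
the whole system, and we compare the two. The patient's hypothetical
counterpart under the other exposure is their *virtual twin*.

## The estimand and the estimators

For covariates $x$, let $\theta_h(x) = P_h(Y = 1 \mid X = x)$ be the
true risk at hospital $h$ and $\theta_O(x)$ the risk at the overall
hospital. The patient-level causal relative risk is

$$\tau_h(x) = \frac{\theta_h(x)}{\theta_O(x)},$$

with $\tau_h(x) < 1$ meaning the patient fares better at hospital $h$
than at the average system hospital. Working on the log scale,
$\log\tau_h(x) = \log\theta_h(x) - \log\theta_O(x)$.

Both risks are estimated with probability random forests: one model per
hospital, trained on that hospital's patients only, and one pooled model
trained on everyone. Because adverse surgical events are rare (a few
percent), classification thresholds follow the quantile rule for
imbalanced outcomes — a patient is labelled an event when their
estimated risk exceeds the training prevalence rather than 0.5
(`rfq_classify()`) — but the causal pipeline consumes the probability
estimates themselves, never the labels.

Two estimator variants are switched per patient, and getting this switch
right is most of what the `risk_forest` module exists for:

* a patient of hospital $h$ is part of $h$'s training data, so their own
  risk under $h$ uses the **out-of-bag (OOB)** estimate
  $\hat\theta^*_h(x)$ — only trees whose bootstrap sample excluded that
  patient vote. Each tree is grown on $n$ draws with replacement, so
  about $e^{-1} \approx 37\%$ of rows are out-of-bag per tree and every
  row has OOB trees for realistic ensemble sizes;
* a patient of another hospital is an external test point for $h$'s
  model, so the full ensemble $\hat\theta_h(x)$ is used.

The denominator always uses the pooled model's OOB estimate, since every
patient is in the pooled training data. This leave-self-out discipline
is what prevents a hospital's model from flattering its own patients.

## Identification assumptions

The causal reading of $\hat\tau_h$ rests on the usual pair of
observational assumptions. *Strong unconfoundedness* — assignment to a
hospital is independent of the potential outcomes given the measured
covariates — is untestable and is not estimated here; in the synthetic
cohorts it holds by construction because assignment depends on
covariates only. *Positivity / overlap* — each covariate profile could
plausibly appear at each hospital — is the assumption the package
actively polices, as follows.

## Overlap screening and bad virtual twins

Rather than estimating propensity scores, overlap is assessed with
per-hospital isolation forests over the outcome-predictive feature
subset (chosen by `screen_features()`, by default permutation importance
of a pilot forest; any externally supplied list is accepted verbatim).
An isolation forest isolates a point by random axis-aligned splits;
points in low-density regions are isolated in few splits. The raw score
of a row is its average path length across 300 trees grown on
subsamples of size $\psi = \min(256, n(h))$ with height limit
$\lceil \log_2 \psi \rceil$ and the standard $c(\psi)$ adjustment for
truncated paths.

Raw path lengths are calibrated to the unit interval by their mid-rank
position in the training hospital's own score distribution. This choice
is deliberate: it is the unique calibration under which "cutoff
$C = 0.05$" means *exactly* "exclude the 5% of the training distribution
that is most anomalous" (up to ties), and it makes calibrated training
scores uniform on $[0,1]$, which is what the anomaly-density diagnostics
assume. Probes below the training minimum map to 0, above the maximum
to 1. A patient with $i_h(x) < C$ has no valid virtual twin at hospital
$h$ — a *bad virtual twin* — and their estimate for that hospital is
flagged out rather than extrapolated. Filtering only removes rows; it
never changes kept estimates. Pairwise hospital comparisons
(`pairwise_effects()`) demand validity under **both** hospitals'
scorers, the conservative reading.

## Summaries, standardized betas and grades

Kept relative risks are summarised three ways:

1. **Hospital effect plots** — per-hospital boxplots of $\hat\tau_h$ by
   risk stratum, on a log axis (so reciprocal pairs are symmetric about
   1), box widths proportional to kept sample size. Strata cut the
   pooled model's OOB risks at their 50th and 75th percentiles
   (low / medium / high, roughly 50/25/25% of patients), plus the
   unstratified "overall".
2. **Standardized-beta grading** — kept log relative risks are divided
   once by their pooled standard deviation (all hospitals, before
   stratification, so panels share a scale), then regressed on
   hospital-specific intercepts (cell-means coding, no global
   intercept), optionally with one independent variable. The reported
   $\beta_h$ is the *negated* intercept, so positive means better than
   average; with no covariate it is exactly the negated per-hospital
   mean, which the tests exploit as a closed-form oracle. Within each
   (stratum x variable) panel hospitals are ranked by $\beta$ and the
   percentile rank is cut into eight equal bins, A+ down to C; ties
   share the better grade, so identical betas all read A+. Grades are
   relative standings: a slightly negative $\beta$ can still earn an
   A-range grade.
3. **Per-variable panels** — the same fit repeated per covariate, read
   as which patient characteristics a hospital handles comparatively
   well; for a two-hospital contrast the per-variable *slopes* on the
   standardized pairwise log relative risk are reported instead, sorted
   from most favourable to the first hospital to most favourable to the
   second.

## The synthetic cohort generator

Everything above is validated on simulated multi-hospital cohorts with
known truth (`sim_config()` / `simulate_cohort()`). The generator
emulates the structure of a multi-centre surgical registry: $H$
hospitals of unequal size; standard-normal (optionally equicorrelated)
covariates with per-hospital mean shifts on a stated subset (case-mix
differences, and overlap violations when large); true risk
$\theta_h(x) = \mathrm{logit}^{-1}(b_0 + x^\top w + \delta_h)$ with
hospital effects $\delta_h$ on the logit scale;
$\theta_O(x) = \sum_h \pi_h \theta_h(x)$ with $\pi_h = n(h)/n$ (the risk
at a randomly drawn system hospital, which is the population quantity
the pooled model estimates); outcomes Bernoulli at the assigned
hospital's risk, coupled across hospitals through one uniform draw per
patient so potential outcomes are well defined. The intercept $b_0$ is
tuned by bisection on the realised covariates so the mean assigned-risk
matches the target prevalence — rare-event regimes are sensitive enough
to the intercept that a closed-form guess is not adequate. The default
prevalence is 3%, a plausible operative-mortality regime; it is
configurable. One master seed fans out deterministically to per-stage
child seeds, and a fixed seed fixes the tables bit-for-bit.

What the generator does *not* emulate: the hundreds of mixed-type
clinical covariates of a real registry, realistic covariate
correlation structure, survival/competing-risk outcomes, or hospital
effects that vary over the covariate space (the simulated $\delta_h$ is
constant on the logit scale). Passing tests therefore demonstrate that
the machinery recovers known structure under a clean data-generating
process, not that any particular real-world registry satisfies the
identification assumptions.

`inject_anomalies()` displaces a chosen fraction of one hospital's rows
by a stated number of standard deviations on a covariate subset,
providing planted overlap violations for testing the bad-twin filter
(a 6-SD displacement of 10% of a group is excluded at rate well above
0.9 by a scorer trained on the clean distribution).

## Numerical choices

* **Probability floor.** Risk estimates are clamped to
  $[\varepsilon, 1 - \varepsilon]$ with
  $\varepsilon = 1/(2\,\mathrm{ntree})$, so a zero vote share cannot
  produce $\log 0$. Ratios are formed after clamping; $\log\hat\tau$ is
  always finite.
* **Terminal node size.** Default
  `min_node_size = max(5, ceiling(0.05 n))`, i.e. terminal nodes hold a
  fixed *fraction* of the training data rather than a fixed count, for
  two reasons specific to rare-event relative risks. First, with 1-5%
  prevalence, small fixed-size leaves (5-10 rows) mostly contain no
  events, so low risks are estimated as exactly zero, both sides of the
  ratio hit the clamp floor, and the relative-risk distribution
  degenerates into a point mass at 1; at 5% of $n$ a leaf carries
  roughly 1-3 expected events at 3% prevalence. Second, the hospital
  model (small $n$) and the pooled model (large $n$) enter the same
  ratio: with a fixed node *count* the smaller model smooths over much
  wider covariate neighbourhoods than the larger one, which biases
  $\hat\tau$ toward 1 asymmetrically; matching the node *fraction*
  matches the smoothing neighbourhoods and removes most of that bias.
  An explicit `min_node_size` always overrides the rule.
* **Forest defaults.** 500 trees, $\sqrt{p}$ candidate features per
  split, bootstrap of $n$ draws with replacement (which is what makes
  the 37% OOB arithmetic hold). Training rows are sorted by id before
  fitting so the fit is invariant to input row order.
* **Stratum edges.** Half-open intervals $[0, p_{50})$,
  $[p_{50}, p_{75})$, $[p_{75}, \infty)$ on the pooled OOB risks of all
  patients. If all risks tie, every patient lands in one stratum and a
  warning is raised; fewer than four rows also collapse to a single
  stratum.
* **Ties in grading.** Ranks use the minimum (best) rank for ties, so
  tied hospitals share the better grade.
* **Degenerate inputs.** A hospital with zero (or all) events cannot
  support a risk model and is refused by name; an all-constant feature
  set is refused by the anomaly scorer; zero variance among log
  relative risks stops standardization.

## Problem sizes used in the tests

The validation suite exercises the study conditions at desk scale:
cohorts of $H = 4$–$5$ hospitals with $n(h) = 2000$ and 3% prevalence,
500-tree risk forests, 10 simulation seeds for the distributional
checks (null recovery of $\tau \approx 1$; monotone recovery of medians
across hospital effects $\delta_h \in \{-1, -0.5, 0, 0.5\}$; top grades
for the strongly protective hospital). Isolation forests inside the
pipeline loops use 150 trees: calibration is rank-based and stabilises
well below that. Unit tests use much smaller fixtures whose expected
values come from brute-force oracles (explicit rows-by-trees OOB
aggregation; negated group means for the intercept-only ANOVA).

## Known limitations

* $\hat\tau_h$ is reported as a distribution over patients; no
  confidence intervals are attached (the upstream methodology reports
  distributions, not inference on them).
* Relative-risk medians remain mildly attenuated toward 1 at
  registry-realistic event counts (tens of events per hospital): with
  $\delta_h = -0.7$ and $n(h) = 2000$ the recovered median sits within
  about 20% of the truth. More trees and larger cohorts reduce the
  attenuation.
* The *location* of a hospital's relative-risk distribution is anchored
  by that hospital's own event count: with $E$ events, the log of the
  median $\hat\tau_h$ carries sampling noise of order $1/\sqrt{E}$
  (about 13% at 60 events) even when the true effect is null. This is a
  floor for any estimator trained per hospital without partial pooling;
  ranking-based summaries (the graded betas) are much more stable than
  the absolute medians, which is one reason grades rather than raw
  medians are the headline output.
* The anomaly score is axis-aligned; overlap violations hidden in
  rotated low-density directions are detected less efficiently than
  axis-aligned ones.
* Strong unconfoundedness is assumed, never tested; on real data the
  estimates are causal only under that assumption plus the overlap
  actually achieved after filtering.
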