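---
title: "Detecting multiplexed stimulus coding in spike counts"
author: "spikemux maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting multiplexed stimulus coding in spike counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikemux)
```

## The scientific question

When two stimuli fall together on or near a neuron's receptive field, its
firing rate cannot simply report both. One longstanding proposal is that
neurons *multiplex*: on some presentations (or parts of them) the cell
responds as it would to stimulus A alone, on others as it would to stimulus B
alone, so that across repeated presentations the population keeps both items
alive. spikemux implements a statistical pipeline for testing this idea with
trial-aligned spike counts from visual cortex (V1/V4 conventions are built
in), and a synthetic-data generator that makes every stage testable without
access to recorded data.

The atomic unit of analysis is a **triplet**: one unit's spike counts on
A-alone, B-alone, and combined (AB) presentations of one stimulus pairing.

## The model

Single-stimulus responses are modeled as Poisson. Under the Jeffreys prior
$\pi(\lambda) \propto \lambda^{-1/2}$, $n$ counts summing to $S$ give the
conjugate posterior $\lambda \mid y \sim \mathrm{Gamma}(S + 1/2,\, n)$
(`ratePosterior()`).

For the AB distribution four hypotheses are compared
(`classifyTriplet()`), with an equal $1/4$ prior:

* **single** — $y^{AB} \sim \mathrm{Poi}(\lambda)$ with $\lambda$ exactly
  $\lambda_A$ or $\lambda_B$ (an equal-weight average of the two
  sub-models);
* **outside** — a single rate outside the interval
  $(\min, \max)$ of the two single-stimulus rates;
* **intermediate** — a single rate strictly inside that interval;
* **mixture** — each presentation draws from the A component with
  probability $\alpha$ and from the B component otherwise,
  $\alpha\,\mathrm{Poi}(\lambda_A) + (1-\alpha)\,\mathrm{Poi}(\lambda_B)$,
  with $\alpha \sim \mathrm{U}[0,1]$.

'Mixture' wins when the counts are bimodal across presentations — the
signature of whole-presentation multiplexing. The winner's posterior
probability is reported with two conventional confidence readings: at least
$2/3$ (winner at least twice as likely as the best alternative) and above
$1/2$ (at least as likely as all alternatives combined).

### Making improper priors usable

Jeffreys priors are improper, so marginal likelihoods are defined only up to
a constant and hypotheses cannot be compared directly; the standard remedy
is an intrinsic-Bayes-factor construction. For the two-model *screen*
(does the data support $\lambda_A \neq \lambda_B$?) the construction is
unambiguous, and we implement the arithmetic intrinsic Bayes factor exactly,
enumerating every minimal training sample (one observation per condition) in
closed form; a fractional Bayes factor (training fraction $1/n$) is provided
as a cross-check and the two agree on which triplets pass in all our test
populations.

For the four-way AB comparison no canonical intrinsic construction exists,
and we adopt a concrete, documented operationalization: the single-stimulus rates
are conditioned on the single-stimulus data through their conjugate
posteriors, and the AB rate's Jeffreys prior is truncated and renormalized
on each hypothesis's region (the interval between the drawn rates for
'intermediate'; $(0,\min) \cup (\max, U\!\cdot\!\max)$ for 'outside'). The
region marginals then have closed forms via incomplete-gamma functions,
averaged over rate-pair draws; the mixture adds a Simpson quadrature over
$\alpha$ (201 nodes) nested in the rate draws (4000 by default). An exact
minimal-training-sample intrinsic Bayes factor for the four-way comparison
is *not* offered as a second route: its training-sample scheme for the
mixture weight has no canonical form either, and we prefer one documented
construction validated against brute-force integration (below) over two
unvalidatable ones. Other implementations of the same idea may legitimately
differ; what this package guarantees is internal numerical consistency.

### Numerical choices

* **Outside upper bound.** Jeffreys is not normalizable on an unbounded
  region, so 'outside' uses a finite cap $U = 10$ times the larger rate.
  `outsideSensitivity()` reclassifies with $2U$ and reports the change in
  winner probability; on our synthetic suites it stays well below 0.5 and is
  typically negligible.
* **Rate-pair integration.** Default: 4000 Monte-Carlo posterior draws,
  seeded and recorded; the Monte-Carlo SE of the mixture marginal is
  reported. For validation a deterministic mode
  (`mixtureQuad(rateMethod = "quantile")`) replaces draws with a
  probability-cell tensor grid whose tails are refined geometrically down to
  $10^{-14}$ cell mass. The tails matter: for a hypothesis that conflicts
  with the data the integrand concentrates in the extreme tail of the rate
  posterior, and a plain quantile grid (or plain MC at any affordable size)
  misses it. With tail refinement all four log-marginals agree with
  brute-force dense-grid integration to better than $10^{-3}$ log units on
  small instances; that agreement is asserted in the test suite.
* **Label symmetry.** The classifier always computes in a canonical
  orientation (the condition with the larger posterior-mean rate first) and
  flips $\alpha$ and the scores back. Swapping the A/B labels therefore
  traverses bit-identical floating-point operations: categories are
  unchanged and every assignment score maps exactly to $1-s$.
* **Ties.** Rate-pair draws with $\lambda_A = \lambda_B$ (measure zero) are
  rejected and redrawn; open intervals are used throughout.
* **Empty AB sets** give a log-marginal of 0 (empty product) for every
  hypothesis.

### Assignment scores

For mixture-classified triplets, each AB presentation gets a score in
$[0,1]$: the posterior probability that its count arose from the A
component, averaged over the same $(\alpha, \lambda_A, \lambda_B)$ weights
as the mixture marginal. Analyses of this kind sometimes use a normalized
firing-rate score instead; the component posterior is our default, and
`normalizedRateScores()` (the count rescaled between the two rate
estimates, clipped) is selectable for population views.
A plug-in variant evaluated at posterior means (`pluginAssignmentScores()`)
is also provided.

## Screening

Before any model comparison a triplet must pass two criteria
(`screenTriplet()`):

1. each single-stimulus distribution is consistent with a Poisson — a
   Monte-Carlo chi-square goodness-of-fit test, retained when $p > 0.10$.
   Integer bins are pooled on the right until the tail expects at least one
   count; the null is simulated by redrawing same-size samples from the
   fitted Poisson, refitting the rate and rebinning each time, with the
   add-one correction. Because the statistic's null distribution is
   simulated under exactly the procedure applied to the data, the test is
   calibrated regardless of binning details (asserted at $\pm 0.02$ in the
   tests);
2. the two rates are substantially separated — intrinsic Bayes factor above
   3 for $\lambda_A \neq \lambda_B$.

Under truly Poisson inputs roughly $0.9^2 \approx 81\%$ of triplets survive
the two goodness-of-fit rules; this is a property of the stated 0.10
retention level, not a defect.

## Correlation analyses

`spikeCountCorrelation()` computes Pearson correlations across paired
presentations of a condition, after excluding presentations where either
unit deviates more than 3 SD from its own condition mean (mean and SD
computed once, candidate included — a single pass; on clean data the rule is
a no-op). Pairs are labelled congruent when both units prefer (respond more
strongly to) the same stimulus. Each qualifying stimulus set contributes a
separate record — AB, A-alone and B-alone are never averaged together — and
single-stimulus records are pooled across A-alone and B-alone into one
baseline (an explicit pooling choice of this package), with an
optional split by whether the presented stimulus drove both units.
Congruent-vs-incongruent median differences are tested by shuffling the
preference labels 10,000 times, two-sided on the absolute median difference
(sidedness is our choice; the add-one correction makes $p < 10^{-4}$ the
smallest reportable value). Mixture-mixture pairs additionally get
assignment-score correlations, whose sign matches the spike-count
correlation for congruent pairs and reverses it for incongruent pairs.

Per-pair significance (where needed) uses the t-approximation of
`cor.test`; a permutation alternative is trivial to obtain with
`medianShuffleTest` machinery but is not the default — a convention choice.

## The synthetic population

`populationConfig()` + `generateTriplets()` state a world in which the
pipeline's assumptions hold exactly, with one knob for each deviation of
interest:

* 21 single-stimulus and 18 dual-stimulus presentations per triplet (the
  recorded-data averages for adjacent-stimulus V1 sessions);
* single-stimulus rates log-uniform on 2--40 counts/window with preferred /
  non-preferred ratio at least 3, so screening's separation rule is
  satisfiable by construction;
* regime proportions defaulting to a 'single'-dominated population with a
  one-third 'mixture' minority (single 0.50, outside 0.10, intermediate
  0.07, mixture 0.33), echoing the reported incidence pattern for adjacent
  stimuli;
* coordination through one latent population state per AB trial
  ($P(\text{state A}) = \beta$, default 0.5): a mixture unit encodes the
  state with fidelity $\phi$ (default 0.95) and emits Poisson counts at the
  encoded stimulus's rate. This is the simplest mechanism that yields
  positive spike-count correlations among congruent-preference pairs and
  negative among incongruent ones, and it keeps the implied mixing weight
  analytic: $\alpha = \beta\phi + (1-\beta)(1-\phi)$, recorded per unit in
  the truth table. $\phi = 0.5$ recovers independent units. Richer
  (clustered) coordination is out of scope;
* 'outside' units sit at $1.5\times\max$ or $0.5\times\min$ — confidently
  outside the interval at realistic counts;
* optional negative-binomial overdispersion (same mean, variance
  $\mu(1+d)$) to exercise the goodness-of-fit exclusion;
* fixational eye traces as mean-reverting AR(1) drift (stationary SD
  0.05 deg, per-sample coefficient 0.98 at 500 Hz — smooth drift, not white
  noise, because velocity-threshold detection presupposes a smooth
  baseline), clipped to the fixation window, with optional step-like
  microsaccades of known onset.

What a green test does *not* establish: the generator draws genuinely
Poisson counts and a single global coordination state, so it cannot detect
misbehavior under rate drift, bursting, serial dependence between trials, or
cell-cluster structure; and trial counts are balanced, which real sessions
are not. The generator writes the same CSV schemas the readers consume, so
synthetic runs exercise the real input path.

## Eye-movement handling

Spikes are counted in a 200 ms window offset by response latency (30--230 ms
for V1, 50--250 ms for V4), half-open so abutting windows never
double-count. Presentations are excluded for incorrect behavior, attention
directed into the receptive fields, fixation excursions beyond
$\pm 0.5^\circ$, or any detected microsaccade. The detector thresholds
smoothed speed (central differences, 5-sample moving average) at 6 SD above
the mean steady-fixation speed. Velocity-threshold detectors differ in
their smoothing and minimum-duration conventions; ours are stated defaults,
not a claim of equivalence with any particular detector. When the baseline is self-estimated, a robust first
pass (median/MAD) flags candidate events before the mean/SD are computed on
the remaining samples — a plain mean/SD first pass fails outright, because a
large saccade inflates the SD until nothing crosses $6\sigma$. Missing
traces never drop spike data; the eye rules are skipped and flagged.

## Worked example

```{r example, eval = FALSE}
cfg <- pipelineConfig(
  synthetic = populationConfig(nUnits = 20, seed = 1),
  outdir = "spikemux-run")
res <- runPipeline(cfg)
res$report$screen_pass_rate      # fraction of triplets surviving screening
res$winnerProportions            # regime proportions at win prob >= 0.67
res$summary$medians              # congruence x class medians
```

Every stage writes a CSV under `outdir` plus a JSON manifest carrying the
configuration hash and seed; rerunning with an identical configuration is
byte-identical.

## Known limitations

* The four-way comparison is one operationalization of the intrinsic-BF
  idea; other operationalizations could rank borderline triplets
  differently.
* The mixture model treats presentations as exchangeable; within-trial
  (sub-200 ms) switching is explicitly out of scope.
* Monte-Carlo marginals carry seed-dependent error at the $10^{-3}$ log
  scale at default draw counts; borderline winners near the 0.67 / 0.5
  thresholds can flip between seeds. The reported `mcSE` makes this
  visible.
* The shuffle test treats pair records as exchangeable observations; records
  sharing a unit are not independent; the test follows the field's
  convention of treating them as separate observations rather than
  correcting for the dependence.
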