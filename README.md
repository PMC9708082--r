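# spikemux

Bayesian detection of multiplexed stimulus coding in spike counts.

## What this is for

When two stimuli are presented simultaneously, does a visual-cortex neuron
respond to a fused combination, pick one winner, or *multiplex* — alternate
across presentations between its A-alone and B-alone response patterns?
spikemux answers this per unit and stimulus pairing from trial-aligned spike
counts, and then asks the population-level question: do simultaneously
recorded units tend to signal the same stimulus at the same time?

It is written for electrophysiologists with repeated presentations of
A-alone / B-alone / AB conditions (spike times or pre-counted spikes in CSV
form), and for methodologists who want a tested reference implementation of
the spike-count model comparison with a ground-truth synthetic population.

## The statistics at the core

For each **triplet** (unit x stimulus pairing: counts on A, B and AB
presentations), single-stimulus responses are Poisson with Jeffreys-prior
conjugate posteriors λ | y ~ Gamma(S + 1/2, n). The AB count distribution
is compared across four hypotheses under an equal 1/4 prior:

| hypothesis | AB distribution |
|---|---|
| single | Poi(λ), λ equal to λ_A or λ_B exactly |
| outside | Poi(λ^AB), λ^AB outside (min, max) of λ_A, λ_B |
| intermediate | Poi(λ^AB), λ^AB strictly inside (min, max) |
| mixture | α·Poi(λ_A) + (1−α)·Poi(λ_B), α ~ U[0,1] |

'Mixture' — bimodal counts across presentations — is the signature of
multiplexing. Before comparison, triplets must pass a Monte-Carlo chi-square
Poisson goodness-of-fit screen (retain p > 0.10 per condition) and an
intrinsic-Bayes-factor separation screen (BF > 3 for λ_A ≠ λ_B).
Mixture-classified triplets get per-presentation **assignment scores** in
[0,1] (posterior probability the count came from the A component), and unit
pairs get spike-count and assignment-score correlations, congruence labels
(same vs different stimulus preference) and shuffle tests on median
differences (10,000 label shuffles). Population views include trial-wise
score matrices with attention-locked and input-averaging comparator
simulations.

A synthetic-data generator states a ground-truth world (Poisson rates, the
four regimes, a latent per-trial population state with per-unit encoding
fidelity) and writes the same CSV schemas the readers consume, so the whole
pipeline is testable offline. See the methods vignette
(`vignettes/multiplexing-analysis.Rmd`) for model details, numerical
choices and limitations.

## Worked example

```r
library(spikemux)

cfg <- pipelineConfig(
  synthetic = populationConfig(nUnits = 20, seed = 1),
  outdir = "spikemux-run")
res <- runPipeline(cfg)

res$report$screen_pass_rate
#> [1] 0.7
res$winnerProportions
#>       single      outside intermediate      mixture
#>   0.53846154   0.07692308   0.00000000   0.38461538
subset(res$summary$medians, stimulus_set == "AB" &
       class_combo == "mixture|mixture")
#>  stimulus_set     class_combo  congruence median_r_sc median_r_as n
#>            AB mixture|mixture   congruent   0.6392200   0.7456168 4
#>            AB mixture|mixture incongruent  -0.5952878   0.7449581 6
```

Reading: 14 of 20 synthetic triplets survive the Poisson/separation screen
(the 0.10 retention level alone discards ~19%); among confident winners
(winning probability ≥ 0.67) 'single' dominates with a large 'mixture'
minority, as generated; and among mixture–mixture pairs, same-preference
pairs fluctuate together (positive median spike-count correlation) while
different-preference pairs fluctuate apart (negative median) — the
population-coordination signature the pipeline is built to detect. The
assignment-score correlations are positive for *both* groups: in score
space, units tend to signal the same stimulus at the same time whatever
their preferences, which is the multiplexing interpretation. Each stage's
table is also written under `outdir` with a config-hash manifest.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the installed package end-to-end on the default synthetic population
(generation, screening, four-way classification, pair correlations,
population summary), prints the screening, winner-proportion and median
tables it computed, and writes the JSON report to `--out`, with stage CSVs
beside it.
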