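---
title: "Quantal analysis of homeostatic plasticity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantal analysis of homeostatic plasticity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantalr)
```

## The quantal framework

Synaptic strength at the larval neuromuscular junction decomposes into three
parameters: the number of functional release sites $N$, the probability $p$
that a site releases a vesicle per action potential, and the quantal size
$Q$, the postsynaptic response to one vesicle. Quantal content —
vesicles released per stimulus — is $QC = N\,p$, measured per cell as the
ratio of the mean evoked amplitude to the mean miniature amplitude recorded
in the same mode. Presynaptic homeostatic potentiation (PHP) is the
phenomenon in which a reduction of $Q$ (receptor perturbation) is
compensated by an increase in $N\,p$, leaving the evoked response unchanged.
This package estimates each of these quantities and tests, per muscle,
whether PHP is expressed.

## The generative model

Raw recordings of this kind are rarely deposited, so the package includes a
generator whose statistical structure is exactly what the estimators
assume, with known ground truth for recovery testing.

**Evoked release.** Each sweep's amplitude is
$\sum_{i=1}^{N} B_i\,Q_i$ with $B_i \sim \mathrm{Bernoulli}(p)$ and
$Q_i$ gamma-distributed with mean $Q$ and coefficient of variation
$cv$ (gamma: positive support, the standard choice for quantal sizes).
The exact moments are
$\mathbb{E} = N p Q$ and
$\mathrm{Var} = N p (1-p) Q^2 + N p Q^2 cv^2$;
the test suite checks both against $10^5$-sweep simulations.

**Calcium dependence.** The per-site release probability follows a Hill
curve $p(\mathrm{Ca}) = p_{\max}\,\mathrm{Ca}^h / (K^h + \mathrm{Ca}^h)$.
The protocol only fixes the four calcium levels (0.5, 1.5, 3, 6 mM); the
curve shape is a modeling choice. The wild-type default
($p_{\max} = 0.95$, $K = 2.86$ mM, $h = 2.26$) yields
$p \approx \{0.02, 0.18, 0.50, 0.80\}$ at those levels: negligible release
in the lowest condition, and clear saturation at 6 mM so that the variance
*falls* at the highest calcium — the behavior the multiple-probability
protocol is designed around. The steep Hill coefficient is consistent with
the cooperative calcium dependence of release at this synapse.

**Pool dynamics.** Trains are modeled as discrete-time binomial depletion
with replenishment: available quanta $a_1 = $ pool size,
$r_k \sim \mathrm{Binomial}(a_k, f)$ released per stimulus, and a Poisson
number of quanta with mean (replenishment rate)/(frequency) restocked
between stimuli, capped at the pool size. This is the simplest model that
produces the linear late phase of the cumulative response that
back-extrapolation assumes. Defaults: pool 600 quanta, $f = 0.25$,
replenishment 2400 quanta/s — at 60 Hz the response depletes to a steady
state of ~40 quanta per stimulus within ~15 stimuli.

**Traces.** Raw sweeps are synthesized as baseline + events convolved with
a unit-peak difference-of-exponentials kernel (rise 1 ms, decay 6 ms) +
Gaussian noise, with spontaneous minis added as a Poisson process.
Depolarizations are positive-going in current clamp; synaptic currents are
inward (negative) under two-electrode voltage clamp and reported as
magnitudes. Defaults put single-quantum detection at a signal-to-noise
ratio near 5, where detection is nontrivial but reliable.

**Scenarios.** A scenario assigns each muscle a (release, pool) pair and a
protocol. `scenario_wild_type()` gives both muscles identical parameters
($N = 150$, $Q = 0.6$ nA, $cv = 0.3$). `scenario_m6_knockdown()` models a
muscle-6-restricted receptor knockdown: $Q \times 0.5$ with compensating
$N \times 2$ (evoked amplitude exactly maintained, quantal content doubled)
and pool $\times 1.65$ with proportional replenishment; muscle 7 is
untouched. `scenario_phtx()` applies the quantal-size reduction to both
muscles, with or without compensation. Twelve cells per muscle is the
default group size, within the range of typical published group sizes for
NMJ electrophysiology. One master seed is split into named substreams per
(cell, muscle, component), so adding a condition never changes another's
draws, and everything is bit-reproducible.

Current-clamp quantities are produced from the same quantal machinery via a
fixed scale factor (1.5 mV per nA by default, giving ~0.9 mV minis). Two
fidelity caveats are deliberate: amplitudes superpose linearly (no
nonlinear summation of driving force, so absolute quantal content in the
0.4 mM baseline condition is lower than classic current-clamp values — the
analyses compare ratios, which are unaffected), and the binomial model is
homogeneous across sites (no site-to-site heterogeneity in $p$). Passing
recovery tests therefore validates the estimators under the model's own
assumptions; they do not certify behavior on real recordings with
heterogeneous release or nonlinear summation.

## Event detection and measurement

Miniature events are deflections exceeding a user threshold above a
running-median baseline (default window 50 ms — robust to slow drift), with
a light boxcar smoothing (1 ms) for threshold crossing only. Suprathreshold
stretches separated by less than the refractory window (default 5 ms) are
merged, and event amplitude is the unsmoothed extremum minus a local
pre-onset baseline, which keeps noiseless amplitudes exact to <1%. Event
times are smoothed-peak times; `kernel_peak_time()` converts ground-truth
onsets to peak times when scoring detection. No minimum-amplitude cutoff is
imposed by default.

Evoked amplitudes are peak deflections within a post-stimulus window
(default 12 ms) minus a baseline taken immediately before each stimulus.
For 60 Hz trains this local baseline absorbs the residual decay of the
previous response; the back-extrapolation logic tolerates the small
summation that remains, because it only uses the *slope and intercept* of
the late cumulative phase. An optional pre-train baseline mode exists;
windows are truncated at the next stimulus, with a warning outside train
timing.

## The estimators

**RRP back-extrapolation.** With stimulus $k$ at $t_k = (k-1)/f$ (first
stimulus at $t = 0$), an ordinary least-squares line is fitted to the
cumulative amplitude over stimuli 18–30 (1-based, inclusive, configurable)
and evaluated at $t = 0$; division by the same cell's mean mEPSC gives the
pool in quanta. Putting the first stimulus at the extrapolation target
makes the first response part of the extrapolated pool, which is the
method's intent. Trains of 30 or 60 stimuli are both accepted; the fit
never uses stimuli beyond 30. A negative intercept (facilitating train) is
returned with a flag, never clamped. The estimator is exact on affine
cumulative data and linear in gain, so gain cancels from the quantal ratio.

**Variance–mean parabola.** Conditions are summarized by the arithmetic
mean and the unbiased ($n-1$) variance of the 30 sweeps; a theoretical
origin point (variance and mean both zero, calcium-free) is appended and
flagged so it never enters sweep accounting. The model
$\mathrm{Var} = Q\,\bar I - \bar I^2/N$ is *linear in the parameters*
$(Q, 1/N)$, so the unweighted least-squares optimum is computed exactly by
no-intercept linear regression of variance on $(\bar I, -\bar I^2)$ — no
iteration, no initialization, and the parabola passes through the origin by
construction. Positivity is checked rather than imposed: zero curvature
(variance proportional to mean) leaves $N$ unidentifiable and is reported
as `Inf` with a flag; negative curvature or non-positive $Q$ raises an
error with diagnostics. The test suite verifies agreement with a
brute-force grid search over $(Q, N)$ to $10^{-6}$ relative residual.
The fit is unweighted by default (no weighting is implied by a "best
parabolic fit"); a variance-of-variance weighted option is a possible
extension. Fits are per cell, aggregated across cells afterwards.

With quantal variability the population law becomes
$\mathrm{Var} = Q(1+cv^2)\bar I - \bar I^2/N$: the apparent quantal size is
inflated by exactly $(1+cv^2)$ while the curvature — hence $N$ — is
unaffected. The suite asserts this property (at $cv = 0.3$, $\hat Q$
converges to $0.654$ for a true $Q = 0.6$, $\hat N$ stays at 150).

**PHP assessment.** Per muscle, three Student's t tests at level $\alpha$
(default 0.05, with Welch available behind a flag): PHP is expressed iff
the miniature amplitude is significantly *reduced*, the evoked amplitude is
*not* significantly different, and quantal content is significantly
*increased*. Normalized percentages carry delta-method standard errors for
the ratio of group means. Note the structural property of this logic: when
compensation is exact, the "evoked not different" conjunct fails with
probability $\alpha$, so even a perfect experiment flags PHP in ~95% of
replicates at $\alpha = 0.05$ — an inherent ceiling, not an implementation
artifact.

**Elevated RRP and elevated N.** Per-cell RRP estimates are compared by
Student's t test. For release sites, the per-cell $\hat N = 1/\hat B$ is
the reciprocal of a regression coefficient and is strongly right-skewed at
30 sweeps per condition (occasional near-zero curvature produces huge
$\hat N$), so the group comparison is performed on the curvature scale
$\hat B = 1/\hat N$ — the directly estimated, approximately normal
quantity — with "N elevated" corresponding to significantly *reduced*
curvature. This is a deliberate design choice; comparing raw $\hat N$ by t
test is badly behaved under heavy tails.

**Statistics.** Student's equal-variance t is the default two-group test;
multi-group comparisons use one-way ANOVA followed by Tukey's HSD
(family-wise adjusted). Both are null-calibrated in the suite against the
binomial confidence interval at $10^4$ replicates. No additional
multiple-testing correction is applied across the three PHP conjuncts,
matching standard practice for this decision rule.

## Numerical and interface choices

- All fits are closed-form linear algebra (`lm`/`lm.fit`); there are no
  convergence tolerances to tune. The curvature-unidentifiability threshold
  is $10^{-8}$ relative to the data scale.
- Degenerate inputs error early with typed conditions
  (`quantalr_fit_error`, `quantalr_stat_error`, `quantalr_overwrite_error`);
  the pipeline catches per-cell errors, records them, and continues.
- Datasets round-trip through plain text (TSV tables, JSON ground truth,
  two-column traces at 1e-7 precision) with an equivalent Feather container
  for traces behind the arrow package.
- Problem sizes in the test suite: moment checks at $10^5$ sweeps,
  parameter recovery over 200 simulated cells, RRP ratios over 100 seeds,
  flag rates over 200 knockdown-vs-wild-type replicates of 12 cells per
  muscle, and $10^4$-replicate null calibration.

## Known limitations

- No nonlinear-summation correction and no driving-force/input-resistance
  corrections between muscles; quantal content is a pure ratio of means.
- The binomial model assumes homogeneous $p$ across sites; site
  heterogeneity would bias $\hat N$ downward on real data in ways the
  homogeneous generator cannot reveal.
- The detector is threshold-based; a template-matching/deconvolution
  detector is out of scope.
- Acute pharmacological blockade is modeled purely as a quantal-size
  scaling; receptor kinetics are not simulated.
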