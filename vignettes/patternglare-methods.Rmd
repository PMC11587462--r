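---
title: "Methods: sustained pattern-glare EEG responses, habituation models, and cluster-permutation inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sustained pattern-glare EEG responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Square-wave gratings near 3 cycles/degree are uniquely aggravating to the
visual cortex: in susceptible people (migraineurs, photosensitive
epileptics, visual-stress sufferers) they trigger distortions and
discomfort, a phenomenon called pattern glare. When such a grating stays on
the screen for several seconds, the evoked EEG does not return to its
pre-stimulus baseline: it settles into a sustained offset — a *DC-shift*
during the quasi-stationary part of the epoch (analysed here over
0.5–3.0 s after onset). The size of that sustained response, and the way it
changes with repeated stimulation, indexes cortical hyper-excitability.

`patternglare` implements the complete statistical pipeline for this kind
of study, exercised end-to-end on a synthetic generator with known ground
truth:

* the **Pattern Glare Index (PGI)**,
  \(\mathrm{PGI} = \text{medium} - \tfrac{1}{2}(\text{thin} + \text{thick})\),
  which cancels any response component that scales linearly with spatial
  frequency. If the brain merely tracked the visual properties of the
  grating, the medium (aggravating) response would sit at the control
  midpoint and the PGI would be zero; deviations in either direction are
  the operational signature of hyper-excitation (a −X µV response is no
  "smaller" than +X µV — polarity only reflects dipole orientation);
* **exponential change regressors** that model habituation (decreasing
  response) and sensitisation (increasing response) at two time
  granularities — across the three experimental blocks ("partitions") and
  across averaged onset-pairs within a trial — crossed with
  between-participant factor scores;
* **mass-univariate regression with cluster-based Monte-Carlo permutation
  inference** over the channel × time volume, controlling the family-wise
  error rate without parametric assumptions about the spatiotemporal
  correlation of EEG noise.

## The synthetic generator

Real data of this kind are not publicly deposited, so the package's
first-class citizen is a generator (`simulate_epochs()`) that emulates the
study design: three blocks × six trials per stimulus type (thin / medium /
thick), each trial a train of 7–9 identical 3-s onsets (nine onsets rarest,
mirroring their deliberate infrequency: default mass 0.4/0.4/0.2 over
7/8/9), epochs of −200 ms to 4000 ms, and per-trial discomfort ratings on a
1–5 scale. Participants carry three latent standard-normal factor scores
(visual stress, headache, discomfort).

Medium-stimulus epochs receive, over the DC window and a per-channel
topography \(w_c\), the amplitude

\[
A(p, j, i) \;=\; a_\mathrm{dc} \;+\; g\, s_p\,
  e^{-\lambda_\mathrm{partition}(j-1)}\, e^{+\lambda_\mathrm{onset}(i-1)},
\]

for participant \(p\), partition \(j = 1..3\) and onset-pair \(i = 1..3\):
a common DC shift \(a_\mathrm{dc}\) (default 2 µV) plus a discomfort-scaled
component with gain \(g\) (µV per unit factor score) that habituates across
partitions and sensitises across onset-pairs. Onsets 2–3, 4–5, 6–7 map to
pairs 1–3; onset 1 is clamped to pair 1 and onsets 8–9 continue at pair 3
(they lie beyond the last analysed pair). Thin and thick epochs carry no
injected effect, so the injected PGI equals the injected medium signal.
The default topography is a raised-cosine bump of radius 0.3 layout units
centred on the right-posterior electrode `B16` of a BioSemi-style two-bank
layout — the scalp region where discomfort effects concentrate in this
paradigm.

Noise is stationary Gaussian with marginal SD `noise_sd` (default 10 µV per
epoch sample, a realistic single-trial EEG level), AR(1) in time
(coefficient 0.9 at 512 Hz) and spatially correlated as
\(\exp(-d/\ell)\) with correlation length 0.4 layout units — a separable
covariance that reproduces the two properties cluster inference exists to
handle: temporal smoothness and volume conduction. Ratings discretise a
latent Gaussian (clipped rounding to 1..5), the simplest monotone map to
the five-point scale; questionnaire totals arise from a fixed 3-block
loading matrix (CHi/VDS on visual stress, four headache items on headache)
with the in-experiment discomfort index as the seventh measure.

What the generator deliberately does **not** model: blink and muscle
artifacts (an optional switch injects rectangular ±150 µV spikes purely to
exercise threshold rejection — there is no ICA stage to test), non-Gaussian
heavy-tailed noise, nonstationary drift, volume-conduction geometry beyond
isotropic distance decay, and onset-transient ERP morphology (the epoch is
silent outside the DC window). Passing tests therefore certify the
statistical machinery — calibration, recovery, determinism — not robustness
to every pathology of real recordings.

## Preprocessing

The pipeline mirrors standard sustained-ERP practice: zero-phase FIR
band-pass (0.1–30 Hz), average reference, baseline correction to the
−200–0 ms pre-stimulus window (the nearest transient-free segment), ±100 µV
threshold rejection, and a ≥ 20 % usable-trials-per-condition inclusion
rule (inclusive at the boundary). Four binned dependent variables are then
formed per participant and stimulus: the average of onsets 2–8 (onset 1
excluded for surprise, onset 9 as too infrequent), per-partition averages,
onset-pair averages ({2,3}, {4,5}, {6,7}), and the 3 × 3
partition-by-onset-pair grid. Onset 8 contributes to the pooled and
partition schemes but to no pair. Participants missing any required cell
are dropped from that scheme's analysis only, which is why such studies
report different n per analysis.

**Filter design.** The band-pass kernel is a Hann-windowed sinc, built as
the difference of two low-pass kernels each normalised to unit DC gain, so
the band-pass has *exactly* zero DC gain at any kernel length. Length
follows the usual \(\approx 3.3\,f_s/\Delta f\) rule on the narrower
transition band (defaults: the low edge uses a transition equal to the edge
itself; the high edge 7.5 Hz) and is capped at the epoch length — at a
0.1 Hz edge the ideal kernel would be far longer than any epoch, so the cap
widens the low-edge transition while leaving the DC null and the 30 Hz
roll-off intact. Filtering is centred convolution with single-reflection
padding, i.e. zero phase by symmetry rather than by forward–backward
passes.

## Factor scores and orthogonalisation

Seven standardised measures (CHi, VDS, headache frequency / intensity /
duration, sensory aura, and the discomfort index = mean medium rating −
mean pooled thin+thick rating) enter a principal-component factor
extraction with varimax rotation. Three factors are fixed by configuration
— the scree decision is an analyst's judgement, not something this package
automates. Scores use the regression (Thomson) method,
\(\hat F = Z R^{+} \Lambda\), with a pseudo-inverse so that exactly
singular correlation matrices (e.g. noise-free synthetic blocks) remain
well-defined. Determinism is enforced by rotating from the identity,
sign-fixing each loading column at its largest-magnitude entry, and
ordering columns by explained variance. Factors are labelled by the measure
block with the largest mean absolute loading (greedy bijective assignment;
ties are an error rather than an arbitrary choice).

Because the permutation framework fits one covariate at a time, factor
regressors are Gram–Schmidt orthogonalised in the fixed order visual
stress → headache → discomfort (the descending-eigenvalue order), on
mean-centred vectors and without normalisation: earlier regressors are
preserved exactly and later ones become residuals. Unorthogonalised
variants remain available — orthogonalisation is a config flag, since both
variants are scientifically reportable.

## Design regressors

`exponential_weights()` fixes the change model: a decrease is
\(w_k = e^{-\lambda(k-1)}\) over bins \(k = 1..3\), an increase is the same
sequence reversed. The two-way interaction regressor is built in four
steps: shift the factor scores to non-negative by subtracting the minimum
(so the weighting cannot invert anyone's sign), tile across bins, multiply
each bin by its weight, mean-centre. The three-way regressor applies the
onset-pair weights then the partition weights, giving each participant the
outer product of the two weight vectors scaled by their shifted score. Rows
are ordered bin-major (partition-major, then onset-pair) with participants
fastest, and row alignment with the binned data is checked structurally
before any fit.

The rate defaults to \(\lambda = 1\) per bin step. The exact base and rate
of the exponential are not identifiable desiderata here: the permutation
test is invariant to positive affine rescaling of a regressor (asserted in
the tests), and any fixed-base exponential produces rank-equivalent
weights, so \(\lambda\) is exposed as a config knob rather than hard-coded.

## Cluster-permutation inference

At every channel × time sample inside the analysis window (default
0.5–3.0 s) the PGI is regressed on `[1, x]`; the slope t (or the one-sample
t of the mean, for the intercept analysis) forms the statistic map with
df = rows − parameters. Samples with \(|t|\) beyond the Student quantile of
the per-tail forming probability (default 0.025) are clustered under
channel adjacency (layout distance threshold) at the same timepoint plus
temporal succession at the same channel; cluster mass is the sum of member
t-values (the common max-sum choice). The null distribution of the per-tail
maximum \(|mass|\) comes from:

* **sign flips** of each participant's entire PGI block for the intercept
  analysis — implemented directly as a one-sample test rather than through
  the duplicated-zero-data two-sample device some toolboxes require; the
  two are algebraically identical (pooled variance with an all-zero
  duplicate halves, and the \(1/n + 1/n\) factor doubles, leaving the same
  t), and the equivalence is asserted in the tests;
* **whole-participant block permutation** of the regressor for covariates:
  factor scores are a between-participant property, so each participant's
  within-bin pattern travels as a unit.

Monte-Carlo p-values use the add-one estimator \(p = (b+1)/(m+1)\) (never
exactly zero); with an exhaustive null (all \(2^n\) sign assignments) the
identity permutation is part of the enumeration and \(p = b/m\) is the
exact permutation p-value. A permutation that recomputes the observed
statistic counts as reaching it within a 1e-8 relative tolerance, so
exhaustive p-values match independent enumeration exactly. Clusters are
tested per tail at alpha 0.05 against that tail's own max-mass null (a
config switch halves it for a strict two-tailed correction); analyses whose
p-values land near the threshold can be escalated to a larger permutation
count (`n_perm_escalated`). Degenerate zero-residual fits cap \(|t|\) at
1e6 with a flag, keeping cluster masses finite without reordering anything.

Effect sizes at the cluster peak (max \(|t|\)):
\(r = \mathrm{sign}(t)\sqrt{t^2/(t^2+\mathrm{df})}\), plus **both**
Cohen's-d conventions — one-sample \(d = t/\sqrt{n}\) and regression
\(d = 2t/\sqrt{\mathrm{df}}\) — labelled side by side, because the two are
routinely conflated in the literature and the choice changes the number
substantially. The reported peak electrode is the one with the most member
timepoints in the cluster (ties: larger \(\sum|t|\), then channel-name
order).

## Reporting

Grand averages use a participant-level percentile bootstrap: one resample
with replacement per iteration drives *all* conditions, preserving the
cross-condition correlation the PGI depends on; bands are per-timepoint
2.5 %/97.5 % percentiles over (default) 5000 surrogates. Median splits for
visualising factor effects send participants exactly at the median to the
low group — a fixed, documented rule so splits are deterministic. Delimited
TSVs (t-maps, cluster masks, grand averages, the cluster table with a 0.1
reporting cutoff that keeps borderline effects visible) are the canonical,
numerically tested surface; PNG figures are a thin rendering layer over the
same tables and are excluded from numeric tests.

## Numerical and design choices

* **Adjacency**: edge iff layout distance ≤ threshold. On a square grid a
  threshold of 1.5× the spacing reaches the \(\sqrt{2}\) diagonals, so
  interior degree is 8; a sub-diagonal threshold (e.g. 1.2×) gives the
  4-neighbour topology.
* **Inclusion boundary**: ≥ is inclusive — "a minimum of 20 %" keeps a
  participant at exactly 20 %.
* **Bin averaging** weights epochs equally within a cell (onsets averaged
  directly, not per-trial first).
* **Exchangeability**: sign flips only for the intercept; covariate nulls
  permute participants as blocks. Both schemes are validated against
  exhaustive enumeration and by family-wise error calibration on pure-noise
  simulations.
* **Determinism**: every stochastic stage takes a seed; identical seeds
  give bit-identical epochs, nulls, bands, and exported files.
* **Tie/degenerate policies**: all-equal factor scores warn (the regressor
  collapses to the pure change pattern but the permutation null stays
  valid); all-equal loadings error; collinear Gram–Schmidt inputs error
  with the offending index.

## Problem sizes used by the test suite and acceptance script

Statistical checks run at sizes chosen to make each property identifiable
on one CPU: exhaustive-enumeration equivalence at n = 6 participants,
4 channels, 20 timepoints (64 sign assignments); family-wise error
calibration on 200 pure-noise studies of n = 20 × 16 channels ×
100 timepoints at 500 permutations; effect and factor recovery on
simulated studies with the design's own 38 participants (8 channels, 25 Hz
sampling of the epoch, 2 trials per stimulus per partition, gain three
times the noise SD for the injected effect); bootstrap coverage over
hundreds of n = 30 replications. The acceptance script reports the same
quantities recomputed from scratch under a caller-supplied master seed.

At the n = 38, 7-measure scale, principal-component factoring recovers the
generating discomfort factor reliably (|r| ≈ 0.7–0.9 with the truth);
materially smaller samples can rotate the sensory-aura item into its own
component and mislabel the third factor — a real small-sample failure mode
of questionnaire factor analysis, not an artifact of the implementation.

## Known limitations

* The generator's separable AR(1) × exponential spatial covariance is a
  simplification; real EEG noise is nonstationary and its spatial structure
  follows head geometry.
* The one-covariate-at-a-time regression inherits the framework it mirrors;
  orthogonalisation makes the shared-variance attribution explicit rather
  than solving it.
* Cluster inference favours temporally extended effects; brief effects
  inside a long analysis window lose power to the family-wise correction,
  and nothing here mitigates that.
* No source localisation, time–frequency analysis, ICA, or raw-format
  (BDF/EDF/FIF) import is provided; epochs enter as arrays plus a trial
  table.
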