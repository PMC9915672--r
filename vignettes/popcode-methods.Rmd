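---
title: "Methods: population codes for sound level under interneuron activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population codes for sound level under interneuron activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popcode)
```

## The problem

Auditory-cortex populations encode sound pressure level with two ingredients:
*which* neurons respond (cell identity) and *how strongly* they respond
(rate). Monotonic neurons grow their response with level; nonmonotonic
neurons prefer a particular level. Optogenetically driving SST interneurons
(direct inhibition of principal cells) or VIP interneurons (disinhibition via
their projections onto SST cells) tilts the balance between these two
ingredients, moving the population code toward a localist (identity-based)
or a distributed (rate-based) representation respectively.

`popcode` implements the quantities with which that shift is measured —
windowed calcium responses, sparseness statistics, population-vector
geometry, response-level curve fits, level decoding — together with a
generative model of the experiment so that every stage can be validated
against known ground truth. This vignette records the models, the estimation
choices, and their rationale.

## Response windowing

The per-trial response unit is `dF/Fstd = (F − mean(F_b)) / sd(F_b)`, with
`F_b` the one second of fluorescence preceding stimulus onset, averaged over
a one-second response window. Two windows are supported:

* **Optimal window** (per neuron and stimulus condition): the start, on the
  frame grid in [0, 4] s after onset, maximizing the sensitivity index
  between the per-trial window means `w` and per-trial baseline means `b`,
  `d' = |mean(w) − mean(b)| / sqrt((var(w) + var(b)) / 2)`. We use the
  pooled-sd form of d′ (no canonical formula is attached to the name) and
  the pre-stimulus second as the comparison segment, consistent with the
  dF/F definition; the post-response tail is an alternative reference with
  the drawback of being contaminated by slow calcium decay.
* **Fixed window** (one per recording): the start maximizing the number of
  neurons with a significant paired t-test of window versus baseline means
  in at least one of the 21 sound x laser conditions, with Bonferroni
  correction over the 21 conditions per neuron and corrected p < 0.01.
  Bonferroni is the most conservative standard choice; the responsive count
  is monotone in the threshold, so the selected window is insensitive to
  mild changes of correction.

All argmax ties break to the earliest start, making window selection
deterministic. Windows are specified in seconds from onset; frames are
1-based R indices. Degenerate traces (zero baseline sd, or d′ undefined at
every start) raise errors rather than returning arbitrary windows.

Optimal windows feed the single-cell statistics (sparseness); the fixed
window feeds everything that compares conditions (geometry, curve fits,
decoding), so that a laser effect cannot masquerade as a window change.

## Sparseness

Lifetime sparseness of a neuron is the normalized Rolls–Tovée measure over
the n = 6 nonzero levels, after subtracting the neuron's same-laser response
to silence and rectifying negatives to zero:

S = (1 − (Σrᵢ/n)² / (Σrᵢ²/n)) / (1 − 1/n).

S is 0 for equal responses, 1 for a one-hot response, scale-invariant, and
undefined (NA, excluded from summaries) when no level exceeds silence.
Activity sparseness is the fraction of neurons *not* exceeding their
reference (silence at the same laser, or silence at no laser) by more than a
threshold. The threshold is the standard deviation across neurons of the
mean 0 dB / no-laser response: the population's silence variability measured
on neuron means, not trials — trial pooling would inflate the threshold by
single-trial noise and make the statistic depend on trial count. With the
no-laser reference, the 0 dB / no-laser entry is 100% by construction and is
omitted from the output.

## Population geometry

For each laser power, the mean population vector at a level is the
per-neuron trial mean (fixed window). Separation angles are computed between
silence-subtracted vectors (origin at the same-laser 0 dB response), so they
measure overlap of the *stimulus-evoked* patterns; vector lengths are
Euclidean distances between the raw mean vectors of level pairs, measuring
rate-like separation. Summaries average unordered pairs with the diagonal
excluded; zero-norm vectors give undefined angles that are dropped rather
than imputed. Angles are invariant to a global response gain; lengths scale
linearly with it — the two statistics deliberately dissociate identity-based
from magnitude-based coding.

## Response-level curve fits

Mean curves (and sem) over the 10 trials per level are classified by the
monotonicity index MI = (r(90) − r(0)) / (max − min) after normalizing the
curve so |max| ≤ 1: below 0.3 nonmonotonic (4-parameter Gaussian), above 0.7
monotonic (4-parameter sigmoid), between — genuinely ambiguous — both models
are fit and the higher R² kept.

The fitted objective is one minus the McFadden pseudo-R²,

1 − R² = Σ (y(level) − mean(level))² / sem(level)² ÷
         Σ (grand_mean − mean(level))² / sem(level)²,

i.e. the sem-weighted squared error of the model relative to the
intercept-only model. The printed form of this ratio is orientation-
ambiguous as typeset in the field; the orientation above is the only one
for which minimizing the objective improves fit quality (it is exactly 0
when the model interpolates the data and exactly 1 at the intercept model —
both endpoints are asserted in the test suite for arbitrary sem profiles).
sem values below `1e-6 * max(|mean|, 1)` are floored there to avoid infinite
weights on noise-free fixtures.

Minimization is multi-start local search: 16 random starts drawn from
`y0 ∈ [min − range, max]`, `yrange ∈ (0, 2 range]`, midpoint/mean ∈ [0, 90]
dB, width ∈ [1, 45] dB, each polished with Nelder–Mead. We chose
Nelder–Mead as the derivative-free simplex method available in base R;
like Powell's method it needs no gradients, and with 16 seeded starts the
multi-start envelope — not the local polisher — determines the solution. A
start "succeeds" when the optimizer reports convergence with finite
parameters; a curve needs at least two successful starts to be
characterized. Counting convergences (rather than coincident optima) is the
laxer reading of that rule; the accepted-fit thresholds downstream do the
real gatekeeping.

Gaussian fits whose mean falls outside [10, 80] dB are refit as sigmoids: a
peak supported only by the 0 dB or 90 dB endpoint cannot distinguish
tuned from monotonic behavior. A fit is *accepted* when McFadden R² > 0.8
and the interpolation diagnostic is at least 0.25. That diagnostic compares
the analytic model on the 13-level grid (the 7 empirical levels plus 15, 40,
55, 65, 75, 85 dB) against the piecewise-linear interpolant through the
model's values at the 7 empirical levels; models far narrower than the level
spacing collapse between the probed levels and score low. Linear
interpolation is used — a spline would smooth exactly the sharpness the
diagnostic is meant to catch.

## Level decoding

Per laser power, trials are projected onto the smallest number of principal
components capturing 70% of variance (PCA fit once on all trials of the
condition; fitting inside each fold would be cleaner but the projection is
unsupervised, so label leakage is not at stake). Each level is decoded
one-vs-rest: the 10-trial class is oversampled to 60 via a Gaussian product
KDE (Scott's-rule bandwidth per dimension; duplicate-only classes fall back
to a tiny jitter), and a linear SVM (C = 1, untuned) is scored by stratified
10-fold cross-validation.

Two design points matter:

* **Folds are grouped by parent trial.** KDE samples inherit the fold of the
  trial they were drawn around. Assigning folds to the 120 post-oversampling
  samples directly would place children of one measured trial on both sides
  of a split and inflate accuracy.
* **The chance control permutes the classifier's labels.** `shuffle = TRUE`
  permutes the class labels of the assembled two-class dataset, which is
  independent of the features by construction and sits at 0.5 in
  expectation. Permuting the trial-to-level assignment instead leaves a
  chance association between labels and the 7 response clusters that a
  linear SVM can genuinely exploit in a 70-trial dataset — a bias of the
  small-sample design, not of the decoder.

## The two-cell model

One sigmoid cell and one Gaussian cell, with the mean fitted parameters per
condition: no activation (sigmoid y0 = −0.12, yrange = 0.88, x0 = 55 dB,
Δx = 11 dB; Gaussian y0 = −0.04, yrange = 0.54, xmean = 50 dB, σ = 13 dB);
SST activation changes only x0 → 68 dB (sigmoid) and y0 → −0.07,
yrange → 0.27 (Gaussian); VIP activation changes only yrange → 1.43
(sigmoid) and yrange → 0.86, xmean → 54 dB, σ → 17 dB (Gaussian). Responses
are evaluated on a 1 dB grid from 0 to 90 dB; angles use silence-subtracted
trajectories, lengths raw responses, exactly as in the population geometry
(restricting the grid to the experimental levels reproduces the
population-geometry output on a two-neuron response table to numerical
precision — a cross-module test).

Mean condition differences average unordered level pairs with the diagonal
excluded; whether published summaries include the diagonal or ordered pairs
is not stated anywhere we know of, but the alternatives move the means by
less than the reporting precision. Gain-regime labels come from a linear fit
of on-laser versus off-laser response over the grid: slope below/above
1 ± 0.05 is divisive/multiplicative, intercept below/above ±0.02 a.u. is
subtractive/additive, and combinations are labelled jointly — published
regime labels are read off plots, so the bands are ours.

## The synthetic generator

`generate_population()` draws, per neuron, a model kind (40% sigmoid by
default — tuned populations outnumber monotonic ones in fitted cortical
samples), a tagged flag (6%, the expected interneuron fraction), and tuning
parameters from independent Gaussians centered on the two-cell means with
sd equal to 20% of the mean magnitude. Only means are published;
independent scatter adds population heterogeneity without inventing
parameter correlations. Gaussian means are clamped to [10, 80] dB and widths
to ≥ 1 dB. High-laser parameters apply the condition's published shifts;
the medium laser applies half the high-laser change (nothing constrains the
midpoint; half-effect is the simplest monotone interpolation); the
`"control"` condition applies none. Trials are tuning-function means plus
i.i.d. Gaussian noise.

`noise_sd` defaults to 0.5 dF/Fstd units. No per-neuron noise magnitudes
are published to copy; 0.5 was chosen once so that (a) the windowed-response
noise floor (≈ 0.2 from unit-sd baseline noise averaged over a 30-frame
window, plus baseline-normalization error) is a minority component, and
(b) decoding accuracy lands in the 0.65–0.9 range typical of such
recordings rather than at ceiling. Trial noise is homoscedastic by default;
real sem grows with response amplitude, and a heteroscedastic option
(`noise_sd * (0.5 + 0.5 |mean|)`) is exposed but off, because none of the
implemented statistics requires it and the homoscedastic case is easier to
reason about in tests.

`generate_traces()` embeds each tabled trial response in a raw-fluorescence
trace: 1 s of baseline noise, then a difference-of-exponentials calcium
kernel (rise 0.05 s, decay 1 s, onset delay 0.3 s — the delay makes the
optimal-window search nontrivial and matches reported fixed-window delays of
a few hundred ms), scaled so the [0, 1] s window mean of dF/Fstd equals the
tabled response. `generate_channel_signals()` emulates the tagging
measurement: red = bleedthrough x green + 5σ elevation for tagged cells +
background noise.

What the generator does **not** emulate: noise correlations between neurons,
network interactions between the stimulated interneurons and the rest of the
population (condition effects are applied directly to tuning parameters),
motion artifacts, neuropil contamination, and spiking-to-calcium
nonlinearity. Passing tests therefore validate the *estimators* — that each
statistic recovers what the generative model planted — not the biological
claims themselves.

## Problem sizes and determinism

The test suite exercises fit recovery with 200 neurons per model kind
(10 trials per level, trial noise 10% of the drawn range — the regime in
which midpoint/mean recovery within 5 dB and range recovery within 20% is
achievable and is achieved by ≥ 90% of accepted fits), directional
population effects with 200-neuron populations, and decoding with 50-neuron
populations; the end-to-end pipeline example runs 60 neurons in well under
five minutes on one core. Every random stage (population draws, optimizer
starts, KDE draws, fold assignment) consumes an explicit integer seed, and
identical configurations reproduce bit-identical outputs; per-curve and
per-neuron sub-seeds are derived from the master seed so results do not
depend on iteration order.

## Known limitations

* The sigmoid's (x0, Δx, yrange) are jointly weakly identified when the
  midpoint approaches the top of the probed range; fits are reported but
  their parameters should be interpreted jointly, not marginally.
* The fixed-window responsive count saturates for strongly responsive
  synthetic populations, in which case the earliest near-optimal start is
  selected; with weakly responsive data the criterion is informative.
* Activity sparseness thresholds on neuron means; with very few neurons the
  threshold itself is noisy.
* `run_pipeline()` caches stage outputs keyed by a hash of the full
  configuration; editing code between runs with an unchanged configuration
  requires clearing the output directory.
* Statistical inference (mixed-effects models across cells and sessions) is
  deliberately out of scope: the pipeline emits tidy long-format tables
  (`neuron`, `level`, `laser`, value) ready for `lme4`-style formulas such
  as `output ~ sound * laser + (1 | cell)`.
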