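# popcode

Population coding of sound pressure level under optogenetic interneuron
activation.

In the auditory cortex, noise bursts of different intensity are encoded by a
mix of *monotonic* neurons (response grows with level) and *nonmonotonic*
neurons (tuned to a preferred level). Activating somatostatin-expressing
(SST) or vasoactive-intestinal-peptide-expressing (VIP) inhibitory
interneurons reshapes this code in opposite directions: SST activation pushes
the population toward a *localist* code (distinct cells for distinct levels,
weaker responses), VIP activation toward a *distributed* code (overlapping
populations, graded response strength). `popcode` implements the analysis
chain with which such an experiment is quantified, plus a synthetic-data
generator that emulates the trial structure — 7 sound pressure levels (0–90
dB SPL) x 3 laser powers (none/medium/high) x 10 trials — so the whole
pipeline can be exercised end to end with known ground truth.

## What it computes

- **Windowed responses.** Per-trial responses are the mean of
  `dF/Fstd = (F − mean(F_baseline)) / sd(F_baseline)` over a one-second
  window: either each neuron-and-condition's *optimal* window (maximizing
  the sensitivity index d′ against the pre-stimulus baseline) or a
  recording-wide *fixed* window (maximizing the count of neurons with a
  Bonferroni-corrected paired-t response, p < 0.01).
- **Sparseness.** Lifetime sparseness per neuron,
  `S = (1 − (Σrᵢ/n)²/(Σrᵢ²/n)) / (1 − 1/n)` over the n = 6 nonzero levels
  (rectified, silence-subtracted), and activity sparseness — the fraction of
  neurons *not* responding above threshold at each level.
- **Population geometry.** Separation angles between silence-referenced mean
  population vectors, `θ = arccos(u·v/|u||v|)`, and Euclidean vector lengths
  between level pairs, per laser power, with laser-minus-none difference
  matrices.
- **Response-level fits.** Monotonicity index
  `MI = (r(90) − r(0)) / (max − min)` classifies each curve (< 0.3
  nonmonotonic, > 0.7 monotonic, otherwise both models are tried); curves
  are fit with a 4-parameter sigmoid or Gaussian by multi-start minimization
  of the sem-weighted McFadden objective
  `1 − R² = Σ(y − mean)²/sem² / Σ(grand − mean)²/sem²`, with an
  interpolation-based overfitting diagnostic and out-of-range-Gaussian →
  sigmoid refitting.
- **Level decoding.** One-vs-rest linear SVM per level after PCA to 70%
  variance, with Gaussian-KDE oversampling of the 10-trial class to 60 and
  stratified 10-fold cross-validation (folds grouped by parent trial).
- **Two-cell model.** An analytic two-neuron population (one sigmoid, one
  Gaussian cell, condition-specific mean parameters) that reproduces the
  direction and size of the population-geometry effects from the single-cell
  fit parameters alone.

## Worked example

```r
library(popcode)

# a 60-neuron synthetic SST-activation experiment
run <- run_pipeline(synth_config(n_neurons = 60, condition = "SST", seed = 1))

run$geometry$mean_angle_diff
#>   medium     high
#> 1.799323 8.033445

run$geometry$mean_length_diff
#>     medium       high
#> -0.1028905 -0.5258931

sp <- run$sparseness
tapply(sp$sparseness, sp$laser, median, na.rm = TRUE)
#>      high    medium      none
#> 0.5716044 0.5353290 0.5264124

head(run$decoding)
#>   laser level  accuracy
#> 1  none     0 0.7824043
#> 2  none    30 0.6240049
#> 3  none    50 0.7910155
#> 4  none    60 0.7057035
#> 5  none    70 0.6328484
#> 6  none    80 0.7133333
```

With SST activation the separation angles between level representations grow
(+8.0° at high laser), the vector lengths shrink (−0.53 a.u.), and median
lifetime sparseness rises (0.53 → 0.57): the population moves toward a
localist code while decoding accuracy stays well above the 0.5 chance level.
Running the same pipeline with `condition = "VIP"` flips the angle and
length signs and lowers sparseness.

The analytic two-cell model gives the same picture without simulation:

```r
two_cell_summary()
#>   condition metric range       value
#> 1       SST  angle  1-90  3.58860256
#> 2       SST length  1-90 -0.12370951
#> 3       SST  angle 30-90  3.70771959
#> 4       SST length 30-90 -0.07142726
#> 5       VIP  angle  1-90 -3.99079681
#> 6       VIP length  1-90  0.26572061
#> 7       VIP  angle 30-90 -4.14665296
#> 8       VIP length 30-90  0.20784719
```

## Documentation

The methods vignette (`vignettes/popcode-methods.Rmd`) describes the models,
the estimation choices (optimizer, start sampling, sem floors, tie-breaking),
what the synthetic generator does and does not emulate, and known
limitations.
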