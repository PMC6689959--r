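---
title: "Prestimulus feedback connectivity and bistable perception: methods"
author: "prepercept"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prestimulus feedback connectivity and bistable perception: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

When an ambiguous stimulus such as the Rubin face/vase figure is flashed
briefly, observers report one of two categorical percepts, and the report
fluctuates from trial to trial even though the stimulus never changes. One
candidate explanation is that spontaneous fluctuations of the brain's
network state *before* stimulus onset bias which percept wins: specifically,
that alpha-band (~10 Hz) directed influence from a category-sensitive
region (the fusiform face area, FFA) down to primary visual cortex (V1) in
the second before the stimulus predisposes the system toward a face report.
Testing this requires a chain of analyses: locating category-sensitive
sources by decoding, contrasting post-stimulus gamma power, estimating
prestimulus spectral connectivity (coherence, imaginary coherency, directed
Granger causality), guarding the directed estimates with a time-reversal
control, group-level cluster-permutation inference, and cross-subject
correlations tying prestimulus connectivity to post-stimulus markers.

`prepercept` implements this full chain and, because the original
recordings are not publicly available, pairs it with a synthetic cohort
generator with *known ground truth*, so that every stage can be validated
by parameter recovery rather than by re-deriving published numbers. All
empirical statements below are computed by the test suite or by
`scripts/acceptance.R`; the package makes no claims about real data beyond
what the method's recovery behavior licenses.

## The generative model

Each subject contributes `nTrials = 400` epochs from `-1` to `+0.5` s
around stimulus onset at 250 Hz. Two latent sources — V1-like and FFA-like
— follow a bivariate VAR(5):

$$ y_t = \sum_{k=1}^{5} A_k\, y_{t-k} + \varepsilon_t,
   \qquad \varepsilon_t \sim \mathcal{N}(0, \Sigma). $$

* Each channel's diagonal terms form an AR(2) resonator at 10 Hz with pole
  radius 0.85, giving the broad alpha peak over a 5–25 Hz band that the
  connectivity statistics assume. A larger radius (0.95) produces a
  narrower, more realistic alpha peak but biases any smoothed spectral
  estimator at the peak; 0.85 keeps the multitaper bias small relative to
  its variance, which is what the oracle-equivalence checks require.
* Directed coupling is a single added FFA→V1 coefficient, split equally
  over lags 2–3 (8–12 ms). The lag is deliberate: instantaneous coupling
  would produce a real-valued cross-spectrum and zero imaginary coherency.
  The coefficient applies **only to samples before onset** and reverts to
  baseline afterwards, so post-stimulus connectivity is uninformative by
  construction. Defaults: `couplingFace = 0.04`, `couplingVase = 0.015`.
  These were chosen once, using the closed-form Geweke oracle, to place
  per-subject feedback Granger near 0.1–0.5 with a face–vase difference
  comfortably detectable in a 20-subject random-effects test; they are
  stronger than typical empirical MEG values, a deliberate trade for
  desk-scale power.
* On face trials the FFA source additionally receives (i) an *induced*
  60-Hz burst from 0 to 0.35 s — Hann envelope, uniformly random phase per
  trial, amplitude 2 — which survives trial-averaged power but not the
  evoked average; and (ii) an *evoked* half-sine deflection (0.05–0.30 s,
  amplitude 1.5). The evoked term exists because the decoder operates on
  the 1–33 Hz band, where a 60-Hz burst is invisible; without it there
  would be nothing for the decoding stage to find.
* One log-normal factor per subject (`betweenSubjectSd = 0.3`) scales both
  couplings and both amplitudes jointly. This shared subject-level factor
  is what generates positive cross-subject correlations between maximum
  feedback Granger, maximum gamma contrast, and maximum AUC.
* Sources are mixed into 30 sensors by smooth random unit-norm topographies
  (fixed per cohort) plus i.i.d. Gaussian sensor noise (`sd = 0.5`). Labels
  are i.i.d. Bernoulli(`pFace = 0.5`) — stochastic reporting by design.

Burn-in: 1.0 s of VAR samples are discarded before each epoch. The default
pole radius has a variance-convergence time of a few hundred milliseconds;
1 s leaves the within-epoch variance stationary to well under the sampling
error that the stationarity test can detect.

Seeding: the cohort seed spawns per-subject seeds through one
`sample.int()` draw, so identical configurations are bit-identical while
subjects stay mutually independent.

What the generator does **not** emulate: 1/f background activity,
physiological artifacts, heterogeneous sensor types, volume-conduction
leakage beyond the linear mixing, preprocessing attrition, or realistic
anatomy. Passing tests therefore demonstrate that the *analysis chain*
recovers known structure under its own assumptions — not that real MEG
data would behave this way. Two known divergences from the empirical
findings follow directly from the model: coefficient coupling necessarily
raises V1 alpha power on face trials (so the null power contrast of the
real data is not reproduced), and source coherence is higher than typical
MEG values.

## Spectral estimation

Multitaper estimates use DPSS tapers computed from the classical tridiagonal
formulation, with concentrations evaluated against the sinc kernel. The
prestimulus window (−1 to 0 s, 250 samples) uses time–bandwidth `NW = 2`
(3 tapers, ±2 Hz smoothing); the frequency grid is the window's Rayleigh
resolution (1 Hz) with no zero-padding by default (an optional `padTo`
argument exists). Windows are demeaned; scaling is a two-sided density per
Hz, and Parseval consistency is asserted by test. Sliding-window power uses
`NW = max(1.5, 10·width)`: ±10 Hz smoothing for gamma-range windows
(5 tapers at 300 ms), a near-Hann single taper at 100 ms. Both the 300-ms
and 100-ms widths are first-class settings because the width itself is an
object of study: a 300-ms window centered 100 ms before onset contains
200 ms of post-stimulus signal, so a genuinely post-stimulus burst appears
at prestimulus window centers; the 100-ms control confines it.

## Connectivity

Coherence and imaginary coherency are ratios of the trial- and
taper-averaged cross-spectrum; a single-estimate CSD is refused because its
coherence is identically 1. Directed influence uses Geweke's spectral
measure computed **nonparametrically**: the trial-averaged spectral matrix
is factorized as \(S(f) = H(f)\,\Sigma\,H(f)^*\) by Wilson's iteration
(no autoregressive fit), and

$$ F_{y \to x}(f) = \ln \frac{S_{xx}(f)}
   {S_{xx}(f) - \left(\Sigma_{yy} - \Sigma_{xy}^2/\Sigma_{xx}\right)
    |H_{xy}(f)|^2}. $$

Implementation choices: the factorization runs on the full 0–Nyquist grid
(the statistics band 5–25 Hz is applied only at the testing stage, because
the factorization needs the whole spectrum); iteration stops when the
successive-iterate relative change falls below `1e-9` (typically ~10–30
iterations; `maxIter = 100`); initialization is the Cholesky factor of the
frequency-averaged spectrum; the causal projection splits the lag-0
coefficient as \(B + B^H\) with \(B\) upper-triangular (diagonal halved)
and halves the self-conjugate half-spectrum lag — both are required for
convergence to machine precision on analytic inputs, which the test suite
asserts. A ridge of `1e-10 ×` the mean auto-spectrum is added only at
frequencies where finite sampling breaks positive semi-definiteness, and is
reported. Tiny negative Geweke values are clipped at zero and counted.
Channel order is fixed in one place — (V1, FFA), `grangerFB ≡ FFA→V1` —
because a silent direction swap is the single most likely bug in this kind
of code.

Validation is dual-route: `parametricGrangerVAR()` evaluates the same
measure from the analytic VAR transfer function and serves as an
independent oracle; `canonicalTestVAR()` (weak AR(1) target, 10-Hz
resonant source, coupling at lags 2–3) is the reference model. Its peak
value was additionally frozen once from a brute-force route (OLS VAR fit
to a 2×10⁵-sample realization). The time-reversal control reverses every
trial's samples before estimation; for lag-based coupling the dominant
direction must flip, and auto-spectra must be invariant.

## Decoding

Per time point, an L2-regularized logistic regression (`glmnet`, fixed
total penalty 1 — not tuned per fold, preserving determinism) is trained on
three folds of a stratified, seeded fourfold split and scored on the
held-out fold; features are Z-normalized with training-fold statistics
only (zero-variance channels get a floored SD). The epochs are first
band-limited to 1–33 Hz with a symmetric even-order FIR applied by FFT
convolution and exact group-delay compensation (zero phase); edge samples
within half a filter length rely on reflected padding. AUC per time point
is computed from held-out decision values pooled across folds (per-fold
averaging is available); the fold split is fixed across time points so the
AUC curve is comparable over time. Classifier weights are fold-averaged,
then transformed to activation patterns via \(A = C\,w\) with the
per-timepoint data covariance (ridge `1e-6`), unit-normalized, oriented to
have nonnegative inner product with \(w\). Patterns are projected to
source space through a spatial filter; on synthetic cohorts this filter is
the pseudo-inverse of the known mixing matrix — the package's declared
stand-in for anatomical source reconstruction, switchable for real data.
ROIs are grid points whose window-averaged absolute map value reaches 95%
of the maximum (ties kept).

The sensor array is homogeneous, so no magnetometer/gradiometer scaling is
implemented.

## Group statistics

Cluster-based permutation tests threshold cell-wise paired t statistics at
the quantile implied by `clusterAlpha = 0.05` and the declared tail, join
supra-threshold cells (neighboring bins in 1-D; 4-connectivity, no
diagonals, in 2-D), and compare observed cluster masses with the
permutation distribution of the maximum cluster mass under random
within-subject condition swaps; `p = (exceedances + 1)/(nPerm + 1)`.
Defaults: 1000 permutations for spectral and time–frequency contrasts and
10 000 for the decoding-significance test (p floor ≈ 1e-4); one-sided for
coherence and both Granger directions (directional hypotheses), two-sided
for power and time–frequency contrasts; decoding vs. chance is a one-sided
dependent-sample t test over the first 350 ms. Subject-level estimates
enter as random effects; no within-subject trial permutation is
implemented. Trial counts per condition are not equalized by default (the
number of face and vase trials is already balanced in expectation).

Error bars for within-subject designs use the Cousineau projection (remove
subject means, restore the grand mean) with the Morey correction
\(\sqrt{C/(C-1)}\).

The behavioral run-length analysis collapses consecutive identical reports
into runs; a run of length \(L\) counts \(L-1\) repetitions, capped at 10
(11 bins). Counts are averaged across subjects and fit by least squares to
\(s\cdot\mathrm{Binom}(k; 10, p)\) with \(p\) and the scale \(s\) free —
the binomial family with \(n\) fixed at the bin cap is one of several
defensible parameterizations; it tracks the geometric run-length law of an
i.i.d. Bernoulli reporter closely over these bins, which is exactly the
property the R² statistic is meant to capture. A perseverative reporter
piles mass into the top bin and is flagged non-stochastic.

Cross-subject correlations (Pearson, two-sided t-transform p, Fisher-z 95%
CI) relate per-subject maxima taken over declared search ranges: AUC over
0–0.35 s, the face–vase gamma contrast over the gamma band × post-stimulus
window, and the face–vase feedback-Granger difference over 5–25 Hz.

## Pipeline, sizes and budgets

`runPipeline()` executes simulate → decode/ROI → TFR contrasts → prestim
power/coherence/Granger (+ time-reversal) → behavior → maxima
correlations, with per-stage error reporting (a failing stage aborts with
its name after serializing the partial bundle) and byte-identical output
for identical configs and seeds. Stages are individually selectable, which
the validation suite uses to run only what a given check needs.

Problem sizes in the shipped tests are the package's chosen validation
scale: 500-trial oracle equivalence; 100 subjects for direction recovery;
500 null experiments × 500 permutations for test calibration; 20 effect
cohorts (full 20 subjects × 400 trials each) plus 5 + 5 ablation cohorts
for the double dissociation; decoding checks on constructed fixtures of a
few hundred trials. The decoding stage decimates to every 5th sample
(20 ms) by default; `decim = 1` reproduces sample-by-sample decoding when
desired.

## Known limitations

Bivariate connectivity only (no conditional/multivariate Granger, no
phase-slope index); a linear instantaneous forward model with a
pseudo-inverse, not a beamformer; no vendor MEG formats (a plain-text
CSV + JSON epochs container is provided instead); binomial run-length
parameterization is a declared choice; the generator's effect sizes are
calibrated for statistical power, not biophysical realism.
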