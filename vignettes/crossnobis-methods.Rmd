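---
title: "Methods: the crossnobis statistic and its decoding-sensitivity simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the crossnobis statistic and its decoding-sensitivity simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossnobis)
```

## The problem

Multivoxel pattern analysis asks whether the spatial pattern of fMRI
responses in a region differs reliably between two experimental
conditions. Two families of statistics dominate practice: classifier
accuracy (most often a linear SVM) and continuous cross-validated distance
statistics. This package implements both for two-condition block designs,
together with a generative simulation in which their sensitivity can be
compared under known ground truth — for example, to ask how well each
method detects a change in functional contrast-to-noise ratio (fCNR) such
as that produced by a change in physiological noise level.

## The crossnobis statistic

Let $\hat c_k \in \mathbb{R}^P$ be the per-voxel contrast estimate
(condition 1 minus condition 2 GLM coefficients) from subrun $k$, and
$R_k$ the residual matrix of that subrun's GLM. For each
leave-one-subrun-out fold $k$:

$$\mathrm{LDC}_k \;=\; \Big(\hat\Sigma_{-k}^{-1}\,\bar c_{-k}\Big)^{\!\top} \hat c_k,
\qquad \bar c_{-k} = \tfrac{1}{S-1}\sum_{j \neq k} \hat c_j,$$

where $\hat\Sigma_{-k}$ is the Ledoit–Wolf shrinkage covariance of the
pooled training residuals $\{R_j\}_{j\neq k}$. The discriminant weights
$\hat\Sigma^{-1}\bar c$ are estimated entirely from training subruns; the
held-out contrast $\hat c_k$ carries independent noise, so
$E[\mathrm{LDC}_k] = c^\top \Sigma^{-1} c \cdot (\text{scale})$ under a
true contrast $c$ and exactly $0$ when there is no pattern difference —
the statistic is unbiased and may legitimately go negative. The fold
average is reported as is (`mean`) and divided by $\sqrt{P}$
(`normalized`) so values are comparable across ROI sizes. Because both the
training and the test side scale linearly with the pattern, the statistic
grows quadratically in the true contrast magnitude.

**Shrinkage covariance.** With more voxels than timepoints the sample
covariance $S$ is singular, so whitening uses
$\hat\Sigma = (1-\lambda)S + \lambda T$ with $\lambda$ chosen by the
analytic Ledoit–Wolf risk formula. The default target $T$ is the diagonal
of $S$: variances are trusted, off-diagonal covariances are shrunk. This
is the common choice in MVPA noise normalisation because it preserves
voxel-specific noise levels; a scaled-identity target is available via
`target = "identity"`. The covariance is always estimated from training
residuals only, never from the held-out subrun, so fold independence is
preserved.

**SVM decoding.** The comparison method fits one GLM regressor per 16-s
block (16 regressors per condition over the session), yielding one
response pattern per block. A linear-kernel SVM with unit box constraint
is trained on the 24 block patterns of three subruns and tested on the 8
held-out patterns, cycling over subruns; features are standardized using
training-fold statistics only. Fold accuracies are therefore multiples of
1/8 — one source of the method's granularity. A test pattern exactly on
the decision boundary (a measure-zero event) is assigned to the first
class and counted.

## GLM and drift handling

Each subrun is fitted separately by OLS. Drift terms — a linear ramp and
one sine/cosine pair with period equal to the subrun length, the standard
first-order detrending set — enter the GLM as nuisance regressors rather
than being projected out beforehand. By the Frisch–Waugh–Lovell theorem
this is equivalent to detrending both data and design as far as the
contrast is concerned, but it has one important advantage: when the
condition blocks tile the subrun with no fixation gaps, the two condition
boxcars sum to the constant vector, and pre-projecting out an intercept
would leave the two detrended regressors exactly collinear (only their
difference identifiable). Keeping the drift terms inside the model — and
including the constant column only when the event regressors do not
already span it — keeps both condition amplitudes identifiable in all
geometries, and recovers them exactly on noiseless data. A standalone
`detrend()` is still exported for timeseries uses such as tSNR
preprocessing. Per-subrun fitting (rather than one concatenated GLM) is
deliberate: it prevents any trend or noise information from leaking across
cross-validation folds. Residual variances use $n - \mathrm{rank}(X)$
denominators.

## The simulation

`makeBlockDesign()` produces the reference geometry: two conditions
alternating in 16-s blocks, 8 blocks per subrun, 4 subruns, with the
leading condition alternating across subruns. The default sampling
interval is 2 s (8 samples per block); it is a free parameter because the
statistic operates on whatever sampling the data provide. Regressors are
plain boxcars — no haemodynamic convolution — because the simulated signal
is defined directly at the level of block amplitudes, and convolving both
the generator and the analysis model with the same kernel would change
nothing about the comparison being studied. The default has no inter-block
gaps (the contiguous alternating reading of the design); a gap option
exists and gaps are placed between blocks only.

`drawGroundTruth()` samples each voxel's two condition amplitudes i.i.d.
from $\mathcal N(0,1)$, so the unnormalized per-voxel difference has mean
absolute value $2/\sqrt{\pi}$, and then rescales the whole pattern so the
mean absolute contrast over voxels is exactly 1 — the simulation's unit of
effect size.

`simulateParticipant()` adds three noise sources to the noiseless
design-times-amplitudes signal:

* **attention noise** — an independent $\mathcal N(0, 1)$ amplitude offset
  per block per voxel, modulated by the block boxcar (trial-to-trial
  response variability);
* **thermal noise** — i.i.d. $\mathcal N(0, 1.8)$ per timepoint and voxel
  (scanner noise, spatially and temporally white);
* **physiological noise** — 10 shared unit-SD Gaussian component
  timecourses per subrun, projected onto voxels through
  standard-normal weights drawn once per participant and held fixed
  across subruns, the projection multiplied by `physScale`. Redrawing the
  component timecourses each subrun while fixing the projection weights
  gives the noise a participant-stable spatial covariance — structure the
  shrinkage-whitened discriminant can exploit — without introducing any
  dependence between subruns.

All randomness hangs off one root seed through deterministic child streams
per participant, subrun and noise source, so datasets regenerate
bit-identically and individual noise components are reproducible in
isolation. A zero-contrast ground-truth draw (probability zero) is redrawn
with a warning.

**What the generator does not emulate.** No haemodynamic lag or
dispersion, no temporal autocorrelation in the thermal noise, no scanner
drift (the analysis removes drift anyway; simulating it would only test
the detrender), no head-motion trajectories or spin-history effects, and
no spatial smoothness beyond the low-rank physiological structure. Passing
tests on these data show that the statistics behave as designed under the
stated noise model; they do not certify behaviour under autocorrelated or
artefact-laden real data.

## fCNR definitions and noise calibration

Two contrast-to-noise quantities are implemented. The stimulus-versus-
baseline form (`computeFcnrStimulus()`) divides the fitted response
amplitude — the peak of $|\beta| \times$ regressor, measured from the
implicit zero baseline — by the residual SD of a GLM that models only
stimulus presence.

The simulation works with the between-condition form
(`computeSimFcnr()`): per voxel, the absolute subrun-averaged contrast
estimate divided by a noise term. The default noise term is the
**standard error of that contrast estimate**, computed from the GLM
residual variance and the design — i.e. the noise SD *of the contrast*,
after the averaging over stimulus blocks and subruns that the estimator
performs. This is the quantity the calibration targets, and the choice is
deliberate: with mean absolute contrast fixed at 1 and thermal noise alone
at SD 1.8, the per-timepoint residual SD can never drop below 1.8, so a
raw-residual denominator is bounded above by about $1/1.8 \approx 0.56$
and could never reach target regimes like 1.6–1.8; the contrast-level
definition spans those values naturally (about 4.2 at zero physiological
noise, decreasing monotonically as `physScale` grows). The raw
per-timepoint denominator remains available as `noise = "residual"` for
users who want the timecourse-level quantity. Voxels with a numerically
zero denominator are flagged undefined and excluded from the ROI mean with
a count, never dropped silently.

`calibrateNoiseToFcnr()` holds attention and thermal noise fixed and
bisects on `physScale` until the measured mean fCNR (averaged over a small
pool of measurement participants simulated under a fixed calibration seed)
is within a stated relative tolerance, 2% by default, of the target.
Scaling only the physiological component mirrors the scientific question —
a motion-correction-like intervention is modelled as a pure change in
physiological noise level — and keeps the other noise sources constant
across conditions; a joint rescaling of all noise sources would change the
noise *composition* along the sweep and confound the comparison.
Unreachable targets (above the zero-physiological-noise ceiling) fail
loudly with the achievable bound.

## Group inference

`ffxPermutationTest()` implements the fixed-effects permutation test for
paired condition measures: each participant's pair of labels is swapped
independently with probability one half, the group mean difference is
recorded per iteration (10,000 by default), and the two-sided p-value uses
the add-one estimator $(\#\{|t^\ast| \ge |t|\} + 1)/(B + 1)$, which is
never exactly zero. For a two-condition pairing, independent per-pair
swaps and full relabelings coincide. `pairedTTest()` and
`oneSampleTTest()` wrap `stats::t.test()` with an explicit degenerate-case
convention (constant differences: $p = 1$ when identically zero, $p = 0$
otherwise). Two-sided testing is used throughout.

## The sensitivity experiment

`rejectionProbability()` estimates, for a pairing of two calibrated noise
levels, the probability that a 15-participant experiment detects the fCNR
difference: for each of 100 simulated datasets it generates *matched*
cohorts — the same participants (identical ground-truth patterns) observed
under the two noise levels with fresh noise — applies a two-sided paired
t-test to the per-participant statistic (normalized LDC, or SVM accuracy),
and counts rejections at $\alpha = .05$. Sharing the ground truths across
the pair isolates the noise manipulation, exactly as a within-participant
intervention would. Pairing a level with itself yields a diagonal cell
whose rejection probability estimates the false-positive rate and should
sit near $\alpha$. With `physScaleB = NULL` the test is instead one-sample
against the method's chance level (0 for LDC, 0.5 for accuracy) —
detection of any pattern information at all. `buildGrid()` sweeps all
pairings and methods into a `RejectionGrid`, with per-cell seeds derived
from the root seed (any cell can be recomputed in isolation) and optional
per-cell JSON checkpoints so interrupted grids resume.

The default fCNR level list spans 1.0–2.4 in steps of 0.2, bracketing the
calibration regime of interest; it is a configuration choice
(`experimentConfig(fcnrLevels = ...)`), not a property of the method.

## Numerical choices

* OLS via QR; rank-deficient designs are rejected naming the dependent
  columns rather than silently pivoting.
* The whitening solve uses the Cholesky factor of the shrunk covariance;
  shrinkage guarantees positive definiteness whenever $\lambda > 0$.
* fCNR denominators at numerical-noise level relative to the signal are
  treated as zero (undefined), with a reported count.
* Child seeds derive from the root seed by an integer LCG scramble and
  stay below $2^{31}$.
* Test problem sizes: scale-free algebraic identities are checked on tiny
  instances (2–4 subruns, 3–20 voxels) against explicit dense oracles;
  distributional properties use the reference 500-voxel geometry with
  cohort counts (up to 100 datasets, 1000 null participants) chosen to
  keep Monte-Carlo error well inside the asserted bands; grid-level
  directional properties use reduced cells (25–30 datasets, 150 voxels,
  12 participants) with correspondingly widened binomial bands.

## Known limitations

* Only two conditions and a single pairwise contrast; no multi-class
  decoding, searchlights, or representational dissimilarity matrices.
* No temporal prewhitening: the GLM assumes white noise within subrun,
  which the generator satisfies but real data may not.
* The SVM wrapper targets the balanced, equal-blocks-per-subrun layout;
  unbalanced designs are rejected rather than reweighted.
* Real-data inputs are expected as matrices (or NIfTI via the optional
  RNifti route) that have already been realigned and slice-time
  corrected; no preprocessing is performed here.
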