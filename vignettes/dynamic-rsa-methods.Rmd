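---
title: "Dynamic RSA: model, estimator, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic RSA: model, estimator, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Classical representational similarity analysis (RSA) compares a *static*
neural representational dissimilarity matrix (RDM) against static model
RDMs. For time-varying stimuli — observed actions, film, music — both the
stimulus features and the neural representation evolve continuously, and the
scientifically interesting question becomes *when* the brain represents a
given stimulus state: after it happened (a lagged representation) or before
it happens (a predictive representation).

Dynamic RSA (dRSA) answers this by building a *time series* of RDMs on both
sides — one neural RDM per time point, one model RDM per time point and per
stimulus-feature model — and estimating the similarity between the neural
RDM at time $t_y$ and a model RDM at time $t_x$ for every pair
$(t_x, t_y)$ within a lag window. Averaging the resulting 2-D matrix along
its diagonals yields a *lag profile* as a function of
$\ell = t_y - t_x$ (neural time minus model time, fixed sign convention
throughout this package): a peak at positive $\ell$ means the neural
representation follows the stimulus; a peak at negative $\ell$ means the
neural signal predicts a future stimulus state.

## The estimator

A plain Pearson correlation between RDM slices (`estimator = "correlation"`)
is provided for reference, but it cannot attribute similarity uniquely:
stimulus-feature models of a naturalistic stimulus share variance with each
other, with themselves at nearby time points (temporal autocorrelation), and
with other models at shifted time points (motion correlates with posture
earlier and later in time). The primary estimator is therefore a
principal-component regression (PCR):

1. For the tested model at $t_x$, the *nuisance set* contains every other
   model's RDM series at all time points, plus the tested model itself at
   all time points farther than its *autocorrelation exclusion window* from
   $t_x$ — the smallest lag at which the model shares less than 10% variance
   with itself (time-averaged squared slice correlation;
   `autocorr_exclusion_window()`).
2. A first-stage PCA per nuisance block keeps the components explaining at
   least 0.1% of that block's variance (`var_threshold`).
3. The kept components are stacked with the tested slice; a second PCA keeps
   the first `min(max_components, rank)` components, ordered by explained
   variance (default cap 75, automatically bounded by the rank of the pair
   space, i.e. by the number of stimulus pairs minus one).
4. The neural slice is regressed on these decorrelated components
   (least squares through the SVD, never normal equations) and the component
   weights are back-projected through the second PCA's loadings; the
   coefficient attached to the tested slice is the dRSA value of that cell.

When nothing is dropped in either PCA, this back-projection is *exactly*
ordinary multiple regression — a property the test suite asserts at 1e-8
against `lm()`. Before any PCA or regression, each RDM series is boxcar
smoothed (30 ms), min–max rescaled to the common 0–2 range over all pairs
and time points at once (so correlation-metric and Euclidean-metric RDMs are
commensurate), and centered per time point. The step order is fixed and
recorded on every `rdm_series`.

### Temporal subsampling and realignment

A finite stimulus set imposes one arbitrary pairwise temporal alignment,
which imprints idiosyncratic structure on the dRSA matrix. The pipeline
therefore repeats, per iteration: extract one random sub-segment
independently per stimulus (identical window for the neural stream and all
models of that stimulus, so their alignment stays intact), realign, rebuild
all RDM series on the realigned segment, run the estimator, and average lag
profiles over iterations (`drsa_subsample()`; defaults 1000 iterations of
3-s segments, scaled down in the test suite). When the segment equals the
stimulus duration the loop degenerates to a single pass, which the package
allows and logs.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lag_range_s` | 1.0 s | half-width of the lag window; only cells with |t_y − t_x| inside it are computed |
| `segment_s` | 3.0 s | subsampled segment length |
| `n_iterations` | 1000 | subsampling iterations (20 in the scaled validation world) |
| `var_threshold` | 0.001 | first-stage PCA variance fraction kept per nuisance block |
| `max_components` | 75 | second-stage PCA cap, bounded by the pair-space rank |
| `autocorr_r2_threshold` | 0.10 | shared-variance level defining the exclusion window |
| `kernel_ms` | 30 ms | boxcar smoothing of RDM series |

## The synthetic world

No neural recordings are shipped or required: the package validates itself
the way the method was originally validated, by *parameter recovery on
simulated neural RDM series*.

**Stimuli.** `generate_kinematics()` emulates a motion-capture stimulus set:
each of `n_stimuli` stimuli is a set of `n_markers` 3-D trajectories built
from a fixed skeleton offset, a whole-body component shared by all markers
of a stimulus, and marker-specific components. All signals are sums of
random-phase sinusoids on the Fourier grid of the window at or below
`cutoff_hz`, i.e. low-pass-filtered noise with an exactly band-limited, dense
spectrum. Two consequences are deliberate: the band-limit invariant is
testable at machine precision (no spectral leakage), and the model RDM
series are temporally dynamic — the stimulus-design requirement of the
method. The default cutoff is 2 Hz at the 100 Hz reference scale; the 50 Hz
validation world uses 6 Hz so that autocorrelation exclusion windows fall in
the sub-second range rather than exceeding a second. Units are arbitrary
throughout: every downstream dissimilarity is correlation-based or min–max
rescaled. Each stimulus draws from its own child RNG stream, so enlarging
the set never perturbs existing stimuli.

**Frames and gaze.** `render_frames()` projects markers orthographically
(depth axis dropped, vertical axis up), scales them into the central 90% of
the frame with one common affine map, and renders each frame as a sum of
unit-peak Gaussian blobs clipped to [0, 1]. `generate_gaze()` produces four
band-limited channels (x, y for two eyes, the second eye tracking the
first). These stand in for video recordings and eye-tracker output; they are
*not* attempts to imitate real videography (no appearance, occlusion, or
camera optics), which matters for interpreting the validation results (see
Limitations).

**Models.** The battery mirrors the standard hierarchy: pixelwise smoothed
luminance; optical-flow magnitude and raw 2-D direction (windowed
Lucas–Kanade local least squares — any dense gradient-based estimator
passing the known-translation oracle within 20% is acceptable here, since
flow only feeds correlation-based RDMs); view-dependent posture (raw 3-D
marker coordinates) and motion (first difference, midpoint convention);
view-invariant posture and motion (alignment by translation plus rotation
about the vertical axis only — closed-form constrained Procrustes — applied
in both directions and averaged); acceleration (second difference); and eye
position (Euclidean metric on the four gaze channels, too few for a stable
correlation). Derivative models are interpolated back onto the original time
grid: interior samples average the two neighbouring midpoints, the first
sample is duplicated from the second, so all model series share one grid.
Flow direction is kept as the raw per-pixel 2-D vector (not normalized),
matching the doubled feature count and avoiding undefined directions at zero
flow.

**Simulated neural series.** `simulate_neural_rdm()` implants model RDM
series at chosen weights and lags plus temporally white uniform noise,
drawn from U(0, 2) to match the rescaled RDM range (the distribution family
is stated by the method's validation design; the support is our choice).
Lag shifts are rounded to whole samples — RDM slices are not band-limited
objects, so interpolation would be cosmetic. Samples shifted in from beyond
the series edge are filled with fresh uniform noise at the same component
weight: this keeps all series the same length (a requirement of the
estimator) while adding nothing temporally structured.

## Numerical choices

* **Boxcar edges**: the smoothing window is truncated (shrinks) at the
  series edges, mirroring common M/EEG practice; undefined entries are
  excluded and the window renormalized.
* **Undefined dissimilarities** (zero-variance feature vectors under the
  correlation metric) propagate as NA with a reported count; above 10% the
  RDM computation aborts. The estimator drops affected pair rows and
  re-centers, so a silent 0 or 1 never biases an RDM.
* **Degenerate PCR inputs**: a rank-deficient second PCA keeps the rank; a
  zero-variance tested slice yields NA.
* **Peak ties** break to the earliest lag, everywhere.
* **Permutation stream**: sign flips are tied to a canonical lexicographic
  ordering of the subject curves, so cluster p-values are invariant to the
  order in which subjects are supplied.
* **Jackknife retrieval** uses `n * mean(jack) − (n−1) * jack_i`; the mean
  of the retrieved values equals the grand jackknife estimate by algebraic
  identity (asserted to 1e-12).
* **FDR** is Benjamini–Hochberg step-up (field convention), not
  Benjamini–Yekutieli.
* **Exclusion window** is computed once per model per segment from the
  time-averaged autocorrelation, not per time point — stability and speed;
  it is applied symmetrically around $t_x$.

## What a green test establishes — and what it does not

The validation suite implants known structure and asks the pipeline to
recover it: single-model implants peak at the implanted lag (±1 sample)
across implant lags from −300 to +300 ms; three correlated video-level
models implanted at weights 1:1:1 against noise weight 3 are each recovered
at zero lag; peak values fall strictly as the implant-to-noise ratio drops
through 1:0, 1:1, 1:5, 1:10; the cluster permutation test is calibrated on
null data (family-wise error within the binomial 95% CI of its nominal
level on 500 replicates).

Two caveats. First, the synthetic world is simpler than real recordings: no
sensor noise model, no appearance variation in the rendered frames, no
subject variability beyond independent noise seeds. Recovery here shows the
estimator chain is implemented correctly, not that real MEG effects of a
given size are detectable. Second, at desk scale (5 stimuli = 10 pairs, a
9-dimensional centered pair space) the *suppression* half of the
single-implant property is only partly attainable: implanting a model and
testing its own temporal derivative (or the near-equivalent rendered level)
leaves the non-implanted sibling at roughly 0.5–0.65 of the implanted peak,
although peak *locations* are always recovered exactly. We verified this is
not an implementation defect — the back-projected PCR equals OLS exactly in
the no-drop regime, and a nuisance block that spans the neural slice
collapses the tested beta to ~0.004 at 91 pairs — but a geometric property
of minimum-norm attribution among temporally coherent base/derivative model
pairs in a small pair space, the same class of residual leak known for
derivative-pair models (e.g. a motion model tested against an implanted
acceleration model) even at full scale. The corresponding acceptance test
is left failing rather than weakened, and the effect shrinks but does not
vanish at the full 14-stimulus scale.

## Known limitations

* The PCR estimator is O(model time points) SVDs per iteration and tested
  model; pure R is comfortable at the validation scale (seconds per
  iteration) but a 400-parcel searchlight at full scale would want the
  per-time-point loop parallelized.
* External neural data enter only as an `rdm_series` in the package's
  canonical pair order (`as_rdm_series()`); no MEG file readers are
  provided, and an external RDM series cannot be re-subsampled per stimulus
  (feature-level input is required for that).
* Archives are plain text (JSON + CSV); large binary stores are out of
  scope.
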