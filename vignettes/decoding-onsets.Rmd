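---
title: "Time-resolved decoding of spatial frequency and Bayes-factor onset inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved decoding of spatial frequency and Bayes-factor onset inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saccdecode)
library(dplyr)
```

## The scientific question and the pipeline

When a brief grating is flashed somewhere in the visual field, the EEG
carries a signature of its spatial frequency (SF) that a linear classifier
can read out, timepoint by timepoint. Two latency phenomena organize the
analysis this package implements:

* **Under stable fixation**, a classifier trained to separate high from low
  SF at one parafoveal location decodes test stimuli at other locations only
  later, with the latency growing with the test location's eccentricity from
  current fixation - an emerging position-invariant SF representation.
* **Under saccade preparation**, peripheral SF becomes decodable at
  parafoveal training locations at a much shorter latency, and roughly
  uniformly across positions - a spatially coarse predictive representation.

Because the underlying human recordings are not publicly deposited, the
package is organized around a *synthetic session generator with embedded
ground truth*: every discriminative component is injected at a known
latency, so each stage of the pipeline - saccade detection, trial exclusion,
preprocessing, decoding, Bayes-factor onset inference - has an objective
recovery target. The pipeline itself is exactly the one a real dataset
would go through.

## The generator

A session is described by `session_config()`: five blocks of 480 trials
(224 fixation + 224 saccade + 32 control per block; 2,400 in total), two
fixation points 20.08 degrees of visual angle (dva) apart, eight stimulus
locations 5.05 dva from their fixation point, gratings of 0.33 or 1
cycles/dva flashed for 100 ms, catch (oddball) trials overlaid every 11-20
trials, EEG at 512 Hz and gaze at 1000 Hz.

```{r schedule}
cfg <- session_config(n_blocks = 1, trials_per_block = 48,
                      n_fixation_per_block = 24, n_saccade_per_block = 16,
                      n_control_per_block = 8, seed = 1)
sched <- build_session_schedule(cfg)
count(sched, base_type)
```

### Geometry and the eccentricity groups

Each fixation point is flanked by four stimulus centres (above, below,
outward, inward along the horizontal meridian). Locations 1-4 belong to the
left fixation point and 5-8 to the right, with location *k* and *k* + 4 at
the same screen offset, so a 20.08 dva saccade maps each parafoveal
location onto its *congruent* peripheral partner (pairs 1-5, 2-6, 3-7,
4-8); the *incongruent* partner is the congruent location of the mirror
position. Test locations are grouped by their distance from current
fixation: near (5.05 dva, the other parafoveal positions), mid (the inner
opposite-side location, 15.03 dva) and far (20.7-25.1 dva). The exact
angular arrangement of the eight positions is configuration, not a claim:
only the distances matter downstream, the grouping is computed from them,
and the cut-points (7.5 and 17.5 dva) are config defaults chosen so the
three groups are non-empty under the default layout. In this layout the
mid group has a single member per side; its curves are therefore noisier
than near/far at equal trial counts.

### Ground truth: per-(train-view, test-view) components

`make_ground_truth()` defines, for every (trial type, train location K,
test location L), the latency at which an SF-discriminative component along
K's topography appears in trials at L. Defaults: same location 80 ms, near
145 ms, mid 205 ms, far 295 ms, and a uniform 140 ms on peripheral-saccade
trials; control trials follow the fixation mapping. Each trial carries the
class-signed sum of these components (plus an early response along its own
location's topography), so a classifier trained at K becomes able to decode
trials at L from exactly `onset(type, K, L)`. We deliberately index the
truth by the (train, test) pair rather than by a single shared "invariant"
topography: a shared component would make the cross-decoding onset the
*maximum* of the training and test latencies, which could not realize a
saccade onset (140 ms) earlier than the fixation near onset (145 ms) under
fixation-trained classifiers. The 8 topographies are orthonormal across the
62 non-mastoid channels, so components never leak across train views.

Synthetic "subjects" are independent seeds: `subject_truth()` jitters each
topography (SD 0.2, renormalized) and every onset by at most one 256 Hz
sample, which provides the across-subject variance that group-level
Bayes-factor inference operates on.

### Signal and noise levels

Components rise with a 4 ms raised-cosine ramp and are sustained to the end
of the epoch (in the continuous recording: to 500 ms, then a 50 ms
offset ramp). The default amplitude (1.5 microvolt along a unit-norm
topography, against noise of SD 1 per channel) puts single-subject
post-onset decoding near 0.9-0.95. That is deliberately higher than real
EEG SF decoding (which peaks nearer 0.6): the generator is a verification
instrument, and sharp onsets are what make latency recovery to within two
samples (about 7.8 ms) a meaningful target at desk-scale trial counts.
Consequences for interpretation: passing recovery tests shows the pipeline
is unbiased and correctly ordered, not that real recordings would yield
latencies this crisp.

The background noise is first-order autoregressive in time (lag-one
coefficient 0.4 in epochs, 0.97 in the continuous recording, giving a
roughly 1/f-like spectrum) with random orthogonal spatial mixing across
channels. It reproduces the two features the pipeline is sensitive to -
temporal smoothness and spatial correlation - without claiming biophysical
realism: no alpha rhythm, no heteroscedasticity across channels, no
non-stationarity. Gaze jitter is 25 ms boxcar-filtered white noise with
0.02 dva RMS: low-pass enough that a 1 dva, 25 ms microsaccade clears the
5-sigma velocity threshold, which the detector-recovery properties require
of any generator that feeds this detector.

## Eye events and exclusions

`detect_saccades()` implements the median-based velocity detector: per-axis
thresholds at `lambda = 5` robust SDs of all recorded velocities (blinks
excluded), an elliptical combined-axis criterion sustained for at least
15 ms, a keep-the-first merge of events closer than 50 ms, and a 15 dva
amplitude validity flag for the cued saccades (the threshold is an argument
because microsaccades must remain detectable for the ocular-component
criterion). Velocity uses the five-sample moving-window estimator, exact
for linear motion.

`exclude_trials()` applies, in fixed order: gaze deviation > 2.5 dva from
the current fixation point during the stimulus (on saccade trials this
check ends at saccade onset - it targets fixation instability, not the
commanded movement), saccade landing > 2.5 dva off target, the eyes
arriving before the 100 ms stimulus has been removed, and the 100-400 ms
stimulus-to-saccade inclusion window. One reason per excluded trial; a
saccade trial with no detected valid saccade falls under the latency
reason.

## Preprocessing

`standardize_record()` anti-alias filters and decimates to 256 Hz and
re-references to the mastoid average; `filter_eeg()` applies a zero-phase
0.1-80 Hz band-pass (order-2 high-pass cascaded with an order-4 low-pass)
plus a 48-52 Hz notch. Zero-phase (forward-backward) filtering matters
here: latency is the readout, and causal filters would bias every onset
late. `epoch_and_baseline()` cuts -200..+500 ms epochs and subtracts the
-100..0 ms mean per trial and channel; 0 ms always lies on the 256 Hz grid.

`select_ocular_components()` implements the ocular-component criterion on
any standard decomposition's activations: a component is rejected when its
mean variance in -20..+10 ms windows around saccade onsets exceeds its
fixation-period variance by more than 10% (strictly; a ratio of exactly 1.1
is kept). Fixation periods exclude all detected eye-movement spans,
microsaccades included. The decomposition itself (e.g., ICA run on a 2 Hz
high-passed copy) is out of scope by design - only the selection rule is
bespoke. Gross-artifact repair (subspace reconstruction, bad-channel
interpolation) is omitted because the generator produces none; the
epoching interface accepts any keep/drop vector, which is the hook a real
dataset would use.

## Decoding

`train_stack()` fits, at each of the 180 timepoints, a two-class linear
discriminant on the 64-channel amplitude vector. The pooled covariance is
regularized by Ledoit-Wolf analytic shrinkage toward a scaled identity -
with 64 dimensions and tens of trials per class the unshrunk estimate is
unusable, and the shrinkage intensity is computed from the data rather than
tuned. Class balance is enforced everywhere by seeded subsampling of the
majority class; decision-boundary ties go to the "low" class
deterministically. Evaluation is strictly on the time diagonal (train
timepoint t, test timepoint t); temporal generalization matrices are out of
scope. `crossval_same()` runs stratified five-fold cross-validation at the
training cell; `cross_test()` evaluates a stack on any disjoint selection;
`decode_subject()` orchestrates the schemes (fixation cross-location,
saccade congruency, saccade eccentricity, latency bins) and
`aggregate_series()` averages in the stated order - over (train, test)
pairs within a condition, then over the two fixation sides - leaving one
series per subject and condition for inference.

## Inference

`bf_ttest()` computes the JZS Bayes factor for a one-sample t-test: point
null against a symmetric Cauchy prior with scale r = sqrt(2)/2 on the
standardized effect, evaluated by adaptive quadrature over the
inverse-gamma mixture representation. The test suite certifies it against
a brute-force oracle that builds the noncentral-t likelihood from first
principles and integrates the prior on a grid (agreement to better than
1e-4 relative). The prior is two-sided: below-chance decoding counts as
evidence against the null, which is what lets the same machinery assess
condition differences around zero (`difference_bf()`).

`detect_onset()` applies the onset rule: the first sample of the earliest
run of three consecutive timepoints with BF10 > 3. Because the two-sided
prior will also flag a sustained below-chance excursion, the pipeline's
recovery runs use `direction = "above"`, which additionally requires the
across-subject mean to lie above the null; the bare rule remains the
default so the operator matches its definition exactly.
`jackknife_onset_ci()` recomputes the onset over every leave-two-out
subject subset (45 subsets for 10 subjects) and reports the 2.5th and 97.5th
percentiles of the onset distribution; subsets with no detected onset are
excluded from the percentiles and counted explicitly, an honest-missingness
choice in preference to imputing an onset that was never observed.

## The recovery experiment

`run_cohort()` is the one-call experiment: 10 subjects, each simulated with
`cohort_design()` (a balanced reduced-scale design of about 450 trials -
one training cell per side, cross-test fixation and control cells, and
congruent/incongruent peripheral-saccade trials with truncated-normal
latencies, mean 200 ms, SD 60 ms on 100-400 ms), decoded with shared
classifier stacks, and summarized into per-condition Bayes-factor time
courses, onsets, and a recovery table against the embedded truth. Cohort
subjects use the direct epoch generator (`simulate_epochs()`), which shares
its component-injection code with the continuous generator; the full
continuous path (gaze, EEG, detection, exclusion, resampling, filtering,
epoching) is exercised end to end by `run_session()` and its tests. The
trial counts are a deliberate desk-scale choice - large enough that every
condition's onset is estimable, small enough that a 20-cohort recovery
study runs in minutes on one CPU; the full printed design (2,400 trials per
session) remains available through `session_config()` defaults.

```{r cohort, eval = FALSE}
res <- run_cohort(n_subjects = 10, seed = 42)
tidy(res)     # per-condition recovered vs embedded onsets
autoplot(res) # accuracy curves with recovered (solid) and embedded (dashed) onsets
```

## Numerical conventions and degenerate inputs

* Epoch grid: 256 Hz, samples -51..128 around stimulus onset; one grid step
  is 3.90625 ms and "two samples" is 7.8 ms.
* A timepoint where all subjects score identically has no sample variance:
  the Bayes factor is reported as the t = 0 limit when the mean sits on the
  null and as unbounded evidence otherwise; `bf_ttest()` itself refuses
  zero-variance input so the degenerate case is always explicit.
* A constant gaze axis has zero velocity spread and drops out of the
  elliptical criterion; a fully constant trace yields a warning and no
  events.
* Ties at the LDA decision boundary go to "low"; the strict `>` in the
  variance-ratio criterion keeps a component at exactly 1.1.
* Every random draw flows from explicit seeds (`withr::with_seed`); equal
  seeds give byte-identical schedules, gaze, recordings and epochs.

## Known limitations

The generator's noise model is stationary and Gaussian; its SNR is
deliberately high; eccentricity latencies are injected, not emergent, so
recovery demonstrates pipeline correctness rather than neural fact. The
exclusion stage sees planted violations of two kinds only (fixation
excursions and off-target landings). The ocular-component stage evaluates
the selection rule on supplied activations; no ICA is computed internally.
Binocular processing, drift/tremor classification and off-diagonal temporal
generalization are out of scope.
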