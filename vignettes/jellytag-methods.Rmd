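---
title: "Methods: orientation, segmentation, featurization and supervised behavior classification for jellyfish biologging tags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orientation, segmentation, featurization and supervised behavior classification for jellyfish biologging tags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## Scientific problem

Animal-borne motion tags ("biologgers") attached to jellyfish record
tri-axial acceleration, angular rate and magnetic field at high rate
(default 100 Hz) alongside 1 Hz pressure, temperature and light. Two
questions dominate the analysis of such deployments:

1. **Tether influence.** Tags on soft-bodied animals are often secured with
   a tether; when the tether goes taut it yanks the tag and contaminates the
   motion signal. Influenced periods must be detected and removed before any
   behavioral inference.
2. **Activity state.** Among the uninfluenced data, is the animal actively
   swimming (rhythmic bell pulsation) or passively drifting?

`jellytag` implements the full chain from raw channels to an activity
budget: orientation estimation, static/dynamic acceleration separation,
per-deployment pulse-cycle segmentation, a fixed 45-feature featurization of
each pulse period, quadratic discriminant analysis (QDA) classifiers with
sequential forward feature selection (SFS) under a nested cross-validated
area-under-the-precision-recall-curve (AUPRC) criterion, and downstream
orientation summaries and rank-based group comparisons. A synthetic
deployment generator with known ground truth supports development and
validation where annotated field recordings are unavailable.

## Coordinate conventions and orientation estimation

The body frame is x forward (along the bell axis), y left, z up; the earth
frame is North-East-Up. The earth-to-body rotation is the Euler sequence
yaw-pitch-roll applied as frame rotations:

$$ R = R_x(r)\, R_y(p)\, R_z(h), $$

with heading $h$ measured clockwise from magnetic north in $[0, 360)$,
pitch $p \in [-90, 90]$ and roll $r \in (-180, 180]$. At rest the
accelerometer measures the gravity direction in the body frame,
$\mathbf{g}_b = R\,(0,0,1)^\top$, and the magnetometer measures the local
field $\mathbf{m}_b = R\,\mathbf{f}$.

`euler_angles()` inverts this forward model from the *static* (low-passed)
accelerometer and the magnetometer:

* pitch $= \operatorname{atan2}(a_x, \sqrt{a_y^2 + a_z^2})$,
* roll $= \operatorname{atan2}(a_y, a_z)$,
* heading: the magnetometer vector is de-rotated by roll then pitch into a
  locally level frame, and heading $= \operatorname{atan2}(-m'_y, m'_x)$,
  mapped into $[0, 360)$; an optional declination converts magnetic to true
  north.

Two failure modes are flagged rather than silently propagated:

* **gimbal proximity**: $|p| > 70^\circ$ makes roll and heading
  ill-conditioned (`gimbal = TRUE`);
* **degeneracy**: $\lVert \mathbf{a}_{\text{static}} \rVert < 0.5\,g$ means
  gravity cannot be trusted (free fall, impact, tether snap); all three
  angles are `NA` and `degenerate = TRUE`.

### Orientation change between two postures

`orientation_change(start, end)` reports the single rotation angle
$\theta \in [0, 180]$ separating two postures. It composes the rotation
matrix built from the *Euler-angle differences* (heading and roll
differences wrapped to $(-180, 180]$) and takes
$\theta = \arccos\!\big((\operatorname{tr} R - 1)/2\big)$. Note this is the
angle of the rotation parameterized by the angle differences, not the
relative rotation $R_{\text{end}} R_{\text{start}}^\top$; the two coincide
when either posture is near level but differ in general. The
difference-based definition is used because it matches how per-period
orientation change is tabulated from start/end Euler summaries, and it is
symmetric under swapping start and end. The test suite pins this definition
against an independent quaternion composition oracle.

## Static/dynamic separation and the FIR filter

`split_static_dynamic()` separates gravity (posture) from propulsion:

$$ \mathbf{a} = \mathbf{a}_{\text{static}} + \mathbf{a}_{\text{dynamic}}, $$

where the static part is the output of `lowpass_fir()` and the dynamic part
is the exact remainder, so the decomposition is additive to machine
precision by construction.

The filter is a linear-phase Hamming-windowed-sinc FIR low-pass:

* cutoff 0.2 Hz — well below the slowest plausible bell-pulsation rate
  (search band starts at 0.05 Hz only for spectral estimation; propulsion
  energy in scyphozoan swimming sits at several tenths of a hertz and
  above), and well above postural dynamics;
* order $6 f_s / f_c$ rounded to even, giving roughly six cutoff periods of
  support — long enough for strong stop-band rejection at the pulse
  frequency, short enough that 30 s edge regions bracket the transient;
* taps renormalized to exact unit DC gain, so a constant input is returned
  bit-for-bit and posture is never attenuated;
* applied by FFT convolution over a reflection-padded signal with the group
  delay removed, so the output is zero-phase and the same length as the
  input. Signals shorter than the filter raise a typed error rather than
  returning an untrustworthy estimate.

## Body signals

`body_signals()` derives the per-sample quantities the featurization
consumes from the dynamic acceleration and the gyroscope:

* `da_x`, `da_y`, `da_z`: signed dynamic acceleration;
* `dax_abs` $= |da_x|$ and `pdba` $= |da_y| + |da_z|$, with
  `odba = dax_abs + pdba` (overall dynamic body acceleration splits exactly
  into its thrust-axis and partial components);
* `pav` $= \sqrt{g_y^2 + g_z^2}$, the pitch-and-roll angular velocity
  magnitude;
* jerk as the forward first difference scaled by $f_s$;
* `_norm` variants divided by the deployment mean, so each normalized
  series has mean exactly 1. A zero-mean channel cannot be normalized and
  raises a typed error.

Normalization by the deployment mean is what lets a classifier trained on
one animal transfer to another with a different absolute activity level;
the un-normalized variants are kept because tether yanks are diagnostic
precisely in absolute units.

## Representative pulse frequency and segmentation

Each deployment is summarized by a single **representative pulse frequency**
(RPF): `representative_pulse_frequency()` takes the DCT-II of the signed
thrust-axis dynamic acceleration `da_x`, maps coefficient $k$ to frequency
$k f_s / (2N)$, and returns the argmax of the magnitude within the search
band 0.05–5 Hz. The DCT is computed exactly via a length-$2N$ FFT of the
mirrored signal rather than by an $O(N^2)$ matrix product.

Two numerical choices deserve note:

* **Signed, not rectified, input.** Rectifying ($|da_x|$) doubles the
  fundamental and pushes power onto harmonics of twice the pulse rate; the
  signed signal keeps the dominant line at the true pulsation frequency.
* **Confidence flag.** The estimate carries `peak_ratio`, the band maximum
  over the band median, and `low_confidence = TRUE` when that ratio falls
  below 3. A spectrally flat signal has ratio near 1; a clean pulsation
  signal has a ratio of tens to thousands. The flag warns that the argmax
  of a flat spectrum is not a meaningful pulse rate.

`segment_periods()` then cuts each annotated run (maximal stretch of
constant activity/tether label, rasterized to seconds, with uncovered
seconds treated as unknown and merged with adjacent unknown runs) into
consecutive non-overlapping windows of exactly one pulse cycle,
$\operatorname{round}(f_s / \text{RPF})$ samples. Partial cycles at run
ends are discarded, so every period is a whole cycle with a single
unambiguous label. Unknown-labeled periods are emitted (so the whole record
can be predicted) but marked ineligible for training.

One pulse cycle is the natural analysis unit: it is the shortest window
over which the propulsion waveform is stationary, and per-cycle features
are comparable across animals with different pulse rates because the
window length adapts to the RPF.

## Featurization

`featurize_periods()` computes a fixed catalog of 45 features per period —
23 accelerometer-derived and 22 gyroscope-derived (`feature_catalog()`
enumerates them). The families are:

* **Moments and extremes** of the body signals and their normalized
  variants over the period (mean, sd, max, …).
* **Gini index** of non-negative signals, a scale-free measure of how
  concentrated a signal's energy is within the cycle: a single sharp thrust
  spike has a high Gini, continuous agitation a low one. The package uses
  the sorted-value formula
  $1 - \tfrac{2}{S}\sum_k v_{(k)} \tfrac{N - k + 0.5}{N}$, algebraically
  identical to the mean-absolute-difference definition
  $\sum_{ij} |v_i - v_j| / (2 N^2 \bar v)$, against which it is tested.
* **Spectral features**: band energies from the magnitude spectrum (which
  sum exactly to the total in-band energy), spectral Gini, and the location
  of the dominant coefficient.
* **Peak counts**: strict local maxima above a height floor, pruned
  greedily by height so that no two retained peaks are closer than a
  minimum separation (a fraction of the pulse cycle). A plateau counts
  once; peaks merging under the separation constraint keep only the
  tallest.
* **Cross-axis structure**: correlation between the y and z dynamic
  channels, with a zero-variance guard.
* **Orientation context** (when Euler angles are supplied): start/end
  angles, circular summaries and the per-period orientation change, plus
  the gimbal/degenerate fraction.

All features are finite by construction on valid input; degenerate cases
(all-zero signal, empty band) return a defined value with an explanatory
attribute rather than `NaN`.

## Classification: QDA

`fit_qda()` estimates per-class Gaussians $(\hat\mu_c, \hat\Sigma_c)$ by
maximum likelihood (biased covariance by default; the unbiased option
exists for like-for-like comparison with reference implementations) plus
the class prior $\hat\alpha$, with a small ridge ($10^{-6}$ by default) on
the covariance diagonal for numerical safety in near-collinear feature
sets. The posterior for class 1 is computed in log space via Cholesky
factors,

$$ \Pr(1 \mid x) = \operatorname{logistic}\!\big(\log\hat\alpha +
   \log\phi_1(x) - \log(1-\hat\alpha) - \log\phi_0(x)\big), $$

so extreme instances saturate cleanly at 0 or 1 instead of overflowing.
Classification thresholds the posterior with ties going to class 1.

**Class-1 convention.** Throughout the package, class 1 is the minority
class of interest — the class whose retrieval the AUPRC scores. For the
tether task the package requires an explicit choice
(`training_policy(tether_class1 = "influenced")`), because which label is
the minority depends on the deployment setting; for activity, drifting is
the class of interest.

**A structural limitation worth knowing.** QDA with unequal covariances has
two decision tails: when class 1 has the larger variance along a feature,
*both* extremes of that feature are assigned to class 1. If the
tether-uninfluenced class mixes swimming and drifting periods (a bimodal
class that a single Gaussian cannot represent), very quiet drifting periods
can fall in the lower tail of the influenced class and be misflagged as
influenced. The AUPRC criterion cannot penalize this during feature
selection, because it scores only the ranking of true class-1 instances.
The package keeps faithful QDA semantics rather than patching the decision
rule; the practical mitigations are (a) training the tether model on
deployments that include drifting examples in the uninfluenced class, and
(b) inspecting the per-class `tidy()` summaries for features where the
influenced class has much larger variance.

## Feature selection and honest evaluation

`sfs()` performs sequential forward selection: starting from the empty set,
it repeatedly adds the candidate feature that maximizes inner
cross-validated AUPRC, stopping when the best improvement falls below
`min_delta`. If no single feature clears the threshold, the best single
feature is still returned (a classifier with no features is useless).

`nested_cv()` wraps SFS in an outer stratified k-fold loop: for each outer
fold, SFS and QDA fitting see only the training side, and the held-out fold
is scored once. The reported AUPRC is therefore an estimate of
generalization performance uncontaminated by the selection — the package's
tests verify both that pure-noise features score near the class prevalence
(no optimism) and that the nested estimate is on average below the
naive estimate from selecting on all data first.

The **operating threshold** is chosen as the equal-error-rate (EER) point:
`eer_threshold()` finds where precision and recall cross on the
fold-averaged *test-side* precision-recall-at-threshold curves, snapped to
a coarse candidate grid (0.1–0.9 by 0.1, ties to the higher threshold).
Using test-side curves keeps the threshold choice as honest as the score
estimate; using a coarse grid avoids pretending to more precision than
five-fold curves support.

**AUPRC, not accuracy or AUROC.** With minority prevalences of a few
percent, accuracy is dominated by the majority class — `majority_rule_metrics()`
quantifies exactly how well "predict the majority always" does, as the
baseline any classifier must beat — and AUROC is insensitive to precision.
AUPRC directly measures retrieval of the rare class; its chance level is
the class prevalence. The package implements the full
precision-recall sweep over unique score thresholds and the
average-precision estimator of the area. Users should know this estimator
is biased upward in small samples by roughly $(1 - \pi) / (2 P)$ for
prevalence $\pi$ and $P$ positives; fold sizes should be kept large enough
that this bias is small relative to the effects of interest.

## Pipeline and downstream analysis

`process_deployment()` chains kinematics → RPF → segmentation →
featurization for one record. `train_task()` assembles eligible training
rows under a `training_policy()` (which sources count for which task, which
label is class 1), runs `nested_cv()` and refits on all eligible data.
`predict_deployment()` applies both fitted tasks to a new record at their
EER thresholds and reports the period table plus an activity budget:
fraction of periods tether-influenced, and fraction drifting *among the
uninfluenced periods only* — influenced periods are contaminated and
excluded from behavioral rates rather than guessed at.

Two reference comparators are built in: `odba_threshold_baseline()` (a
single-feature ODBA threshold, the traditional energetics proxy) and
`accel_only_variant()` (SFS restricted to accelerometer features, measuring
what the gyroscope adds).

`behavior_comparisons()` contrasts feature distributions between groups
with an exact Mann-Whitney U test (exact enumeration for $n \le 12$, tie-
and continuity-corrected normal approximation otherwise); rank tests are
used because per-period features are heavy-tailed and the sample sizes per
deployment are small.

## The synthetic generator

`simulate_deployment()` is a first-class component, not a test shim: its
defaults define the study conditions under which the package is validated,
and every simulated record comes with complete ground truth (per-second
labels, the true Euler trajectory, the true pulse frequency).

Construction, per deployment (all parameters in `sim_config()`):

* **Behavioral states** follow alternating renewal processes: drifting
  bouts (mean 20 s, default 3% of time) and taut-tether bouts (mean 8 s,
  default 8%) are laid down independently on the 1 Hz grid; a fraction of
  seconds (default 5%) is masked as unknown in the *annotations* while the
  truth retains the real labels — mimicking the video-annotation gaps of
  real deployments.
* **Orientation truth**: heading is a wrapped random walk
  (1°·s^−1/2), pitch an Ornstein-Uhlenbeck process (mean 20°, sd 15°,
  correlation time 300 s), roll a slow sinusoid (15°, 300 s period). The
  time constants are deliberately slow relative to the 0.2 Hz filter
  cutoff so that the static accelerometer tracks posture; the residual
  orientation error of the pipeline on noise-free data (< 1° RMS outside
  the 30 s filter edges) is essentially the in-band leakage of these
  processes.
* **Propulsion**: during swimming, thrust on the body x axis is a
  zero-mean half-sine burst train (duty cycle 0.4) at a per-deployment
  pulse frequency drawn from a plausible range (or fixed via
  `pulse_freq_hz`), with a 25% second harmonic added **in quadrature**
  ($\cos 4\pi u$ against the burst's phase). The quadrature choice is
  deliberate: an in-phase second harmonic adds coherently to the harmonic
  content the rectified burst already has, and can make the spectral line
  at twice the pulse rate marginally exceed the fundamental, which no
  estimator should be expected to disambiguate. Quadrature keeps the
  harmonic's energy (realistic bell-recontraction asymmetry) while keeping
  the fundamental dominant, as it is in real pulsation signals. Thrust is
  zero-mean within each cycle so that it does not alias into the static
  (gravity) estimate.
* **Gyroscope**: pitch-and-roll angular velocity consistent with the
  orientation derivative plus pulsation-locked oscillation during swimming.
* **Tether yanks**: large-amplitude (3 g) transients on top of whatever
  the animal is doing — influence is superimposed on, not substituted for,
  behavior, which is why influenced periods are removed rather than
  reclassified downstream.
* **Sensors**: gravity and the magnetic field (default 0.4 north,
  −0.35 up, in gauss) rotated into the body frame by the true orientation,
  plus white noise per channel (0.02 g, 1 dps, 0.005 gauss); 1 Hz depth is
  a slow sinusoid with matching pressure.

Known limitations, stated plainly: states are renewal processes with no
behavioral autocorrelation beyond bout duration; the propulsion waveform is
a fixed shape with no cycle-to-cycle variability in amplitude or period
within a deployment; sensor noise is white (no bias drift, no hard/soft
iron magnetometer distortion, no temperature sensitivity); and tether
dynamics are a stereotyped transient rather than a physical tether model.
The generator is therefore suitable for validating the signal-processing
and inference chain, and for ordering methods by difficulty, but absolute
performance numbers on synthetic data will be optimistic relative to field
recordings.

`simulate_gaussian_features()` is a second, minimal generator — labeled
draws from two arbitrary Gaussians — used to study the classifier in
isolation, including under controlled domain shift between training and
test distributions.

## Reproducibility

All stochastic functions take explicit seeds; a simulated deployment is
bit-identical under the same `sim_config()`. Models round-trip through JSON
(`write_qda_json()`/`read_qda_json()`) with identical posteriors, feature
tables and predictions round-trip through CSV, and cross-validation reports
are serializable with `write_cv_report()`. The script
`scripts/acceptance.R` in the source tree runs the full chain end to end
from a single seed and writes its headline quantities as JSON.

## What this vignette does not claim

This document describes methods, models, parameters and their rationale.
It intentionally reports no empirical performance numbers beyond those
computed by the package's own test suite and the acceptance script; run
those to reproduce every quantitative claim.
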