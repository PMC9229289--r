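---
title: "Identifying people from single-lead ECGs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying people from single-lead ECGs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ecgid` implements a fiducial (landmark-based) ECG biometric pipeline:
wavelet delineation of the P-QRS-T landmarks of each heartbeat, a
22-dimensional interval/amplitude feature vector per beat, mean-impact-value
(MIV) feature screening, and a probabilistic neural network (PNN) classifier
whose single hyperparameter — the kernel smoothing factor δ — is tuned by
the whale optimization algorithm (WOA). This vignette explains the model,
the tunable parameters, the synthetic-data generator used for evaluation,
and the numerical and design choices that were genuinely open.

## 1. Wavelet delineation

### The transform

All detectors operate on the undecimated (à-trous) dyadic wavelet transform
with a quadratic-spline filter pair: low-pass `(1, 3, 3, 1)/8` and high-pass
`(2, −2)`. With this pair the detail signal at scale *j* approximates the
derivative of the input smoothed over roughly `2^j` samples, so a sharp
positive wave appears on each scale as a positive lobe (rising edge), a
zero-crossing (the peak), and a negative lobe (falling edge). Scales are
defined in samples; the transform never resamples, and sampling-rate
dependence is confined to the detector windows. Four scales are computed;
`S4` emphasises the band where the R wave dominates all other waves and
noise, and `S1` retains the sharp, local Q/S structure.

Boundaries use symmetric (mirror) extension, which avoids the spurious
edge maxima a zero-padded convolution would create. The causal filter
cascade delays features; the per-scale group delay is defined as the
centroid of the absolute cascade impulse response, rounded half-up
(1, 3, 7, 15 samples for scales 1–4), and every detector subtracts it
before reading indices off a scale. The exact filter coefficients are a
design choice — the literature on wavelet QRS delineation names the
quadratic spline pair but rarely prints coefficients — so the bank is
looked up by name (`spline_wavelet_filters()`) and alternates can be added
in one place.

### R peaks

R detection follows the classical modulus-maxima scheme: on `S4`, adjacent
opposite-sign local extrema whose magnitudes exceed
`r_threshold_frac × max(|S4|)` (default 0.3) bracket a QRS; the
zero-crossing between them is delay-corrected, and the R index is the
absolute-amplitude maximum of the raw signal within ±100 ms. Candidate
pairs closer than the refractory period (default 0.2 s) are merged, keeping
the pair with the larger modulus product; a pair spanning more than 150 ms
is rejected as not a QRS. The mean R-R interval `TR` of the detected peaks
sets the search bounds for everything downstream.

### Q and S

Q and S are found on `S1`: walking away from the R peak, the third local
extremum of `|S1|` (magnitudes below 2% of the global `|S1|` maximum are
ignored as ripple) marks the Q region on the left and the S region on the
right, bounded by `±0.5·TR`. On smooth morphologies the slope lobes of Q
and R can merge, so the walk result alone is biased; by default the
detector therefore snaps to the raw-signal trough nearest to R within
100 ms (`qs_refine = TRUE`). The ECG rises monotonically from the Q/S nadir
into the R peak, so the nearest local minimum *is* the nadir. With
`qs_refine = FALSE` the raw walk result is returned, which is useful for
testing the walk itself. Cycles with fewer than three usable extrema have
that wave marked missing. Whether the walk should count extrema of `S1` or
of `|S1|` is not settled in the delineation literature; `|S1|` was chosen
because it is polarity-agnostic.

### P and T: locally windowed transforms

P and T are one to two orders of magnitude smaller than R on the wavelet
scales, so a global transform lets the R response mask them. The detector
therefore computes a *fresh* four-scale transform inside a window that
excludes the QRS: `[q − w_p, q]` for P and `[s, s + w_t]` for T (defaults
`w_p = 0.20·fs`, `w_t = 0.30·fs` samples). Inside the window, a P/T peak is
accepted when the `S4` minimum falls below `−pt_threshold_frac ×
max(|S4|)` (default fraction 0.25, both statistics taken over the window
interior); the peak position is the delay-corrected zero-crossing between
the preceding `S4` maximum and that minimum, refined to the raw-signal
extremum within ±60 ms. The onset is the preceding `S4` maximum and the
offset mirrors the onset about the peak, exactly. If no sub-threshold
minimum exists, the window is translated outward in steps of `step_a`
(default 0.02·fs) until the P window would pass `TR/2` or the T window
`2·TR/3`, after which the wave is reported missing.

Two numerical details matter here. First, the anchored edge of each window
sits on the Q/S nadir; if the detected nadir is off by even a couple of
samples, mirror extension creates a kink whose `S4` response can rival the
true wave, and the S-recovery upstroke inside the T window is genuinely
large. Both the threshold statistic and the search are therefore
restricted to the window interior, excluding a guard band of twice the
scale-4 delay at the anchored edge of the T window and one delay at the
anchored edge of the P window. Second, using the zero-crossing rather than
the `S4` minimum itself removes a peak-position bias of about one
effective wave width that the minimum alone would carry for wide T waves.

"Value less than the given threshold" is read as a signed minimum below
the negative threshold, which matches an upright wave; `polarity = -1`
flips the convention for inverted leads.

### Assembly

Per-cycle fiducials must satisfy
`p_on ≤ p_peak ≤ p_off < q < r < s < t_on ≤ t_peak ≤ t_off` over the
points that are present. Cycles violating the ordering are excluded (with
a logged count) rather than repaired: windowed P/T detection admits error
and false detection, and imputation would manufacture data. Missing waves
simply exclude the cycle from feature extraction.

## 2. Features

Each complete cycle yields 22 characteristic values in a fixed order: 16
distances (R-R, R-Q, R-S, R-P, R-T, R-Pbegin, R-Pend, R-Tbegin, R-Tend,
Q-P, Q-Pbegin, S-T, S-Tend, P-T, Pbegin-Pend, Tbegin-Tend) and 6
amplitudes (R-Q, R-S, Q-P, S-T, Pbegin-P, Tbegin-T). Distances are
absolute index differences divided by the sampling rate — seconds, not
samples, so that recordings at different rates can be pooled. R-R uses the
next cycle's R peak; the last cycle reuses the previous interval.
Amplitudes are signed differences of the raw sample values (signed rather
than absolute, preserving polarity information). No standardisation is
applied by default: the PNN kernel operates on the raw features.

Identification can vote over several heartbeats: consecutive,
non-overlapping groups of `k` cycles (default 3) are classified
individually and the majority label wins, ties going to the label seen
first. Majority voting was chosen over concatenating three cycles into one
66-dimensional vector because it leaves the model input unchanged and
degrades gracefully when a subject contributes fewer cycles.

## 3. The PNN classifier

The pattern layer stores every training vector; for input `x` the class
score is the within-class mean of the kernel
`φ(x, x_ij) = exp(−‖x − x_ij‖² / δ²) / (√(2π) · δ^d)`, and the predicted
class is the argmax, ties resolved toward the earliest class label. The
kernel is implemented in exactly this form — with `δ²` (not `2δ²`) in the
exponent and a `√(2π)·δ^d` constant rather than the multivariate
`(2π)^(d/2)·δ^d` — because that is the form the method is defined with;
both peculiarities are irrelevant to the argmax, and
`standard_gaussian = TRUE` switches to the textbook Gaussian. The
normalisation constant is included whenever scores are reported and
dropped inside classification, which works in the log domain with a max
shift so that δ as small as 10⁻⁴ remains stable; in the δ→0 limit the PNN
provably reduces to 1-nearest-neighbour, which the tests exploit as an
oracle. Because the summation layer *averages* within a class, the δ→∞
limit selects the class with the smallest mean squared distance — not the
largest class, as it would with a summed kernel.

Two error metrics are available: the misclassification rate (default) and
the mean squared difference of integer-coded labels. The squared-label
form is kept because the method family defines its network error that way,
but it penalises label *distance*, which is meaningless for nominal
subject identities — hence the default.

## 4. MIV feature screening

For feature *i*, the trained model is evaluated on two copies of the data
with that feature scaled by `(1 + α)` and `(1 − α)` (`α = 0.10` by
default; the method's literature writes the perturbation as a percentage
without fixing a value, and 10% is the customary setting). The mean
elementwise difference of the two outputs is the impact value `MIV_i`; its
sign gives the direction of association and its absolute value the
importance. The model output is the numeric predicted label (subjects are
numbered from 0), matching the scalar-output form the screening equations
require; the winning-class score is available as an alternative output.
Features with `|MIV| > 0.1` are retained. The retained count is
data-dependent by design — nothing hard-codes how many features survive,
and on clean synthetic cohorts very few features may flip any prediction
at all, giving many exact zeros.

## 5. The whale optimization algorithm

WOA is a population metaheuristic over a box-bounded search space. Each
iteration, each whale draws `p ~ U(0,1)` and per-dimension coefficients
`A = 2a·r₁ − a`, `C = 2r₂`, with the control factor `a = 2 − 2t/T_max`
decaying linearly from 2 to 0. With `p ≥ 0.5` the whale spirals toward the
best position found (`X* + |X* − X| e^{bl} cos 2πl`, `l ~ U(−1,1)`,
`b = 1`); otherwise it encircles the best (`X* − A·|C·X* − X|`) where
`|A| < 1` and searches around a random whale (`X_rand − A·|C·X_rand − X|`)
where `|A| ≥ 1`. The prose description of the method ties `|A|` to
encircle-versus-random while its case equation ties `p` to
encircle-versus-spiral; the canonical reconciliation above is adopted. The
spiral uses the distance `|X* − X|` without the `C` factor — the original
algorithm's form — since the source typography reuses the encircling
distance inconsistently. Positions are clipped to the bounds; the best
position is elitist, so the fitness history is non-increasing by
construction.

Smoothing-factor tuning runs a one-dimensional WOA over
`δ ∈ [0.01, 10]` with population 10 and 100 iterations (the configuration
the method was published with), minimising the validation
misclassification rate of a PNN refit at each candidate δ. On cleanly
separable data many δ values achieve zero validation error and the tuned δ
is then simply the first zero-error candidate encountered — its exact
value is data-dependent and not meaningful on its own.

## 6. The synthetic cohort generator

Real multi-subject ECG corpora cannot ship with a package, and detector
scoring needs *exact* ground truth. The generator therefore renders each
heartbeat as the sum of five Gaussian bumps (P, Q, R, S, T), with
per-subject amplitudes, widths and center offsets drawn once per subject
from the documented physiological ranges in `subject_template_ranges()`,
and per-cycle R-R jitter up to ±2%. Ground-truth peak indices are the
extrema of the rendered noise-free signal within ±2 widths of each bump
center; P/T onsets and offsets are placed at ±2 widths. White noise at a
configurable SNR and sinusoidal baseline wander are added only *after* the
truth is recorded. The ranges were chosen so that every wave produces a
distinct extremum — in particular the R bump is kept narrow (σ 10–18 ms)
and the Q/S notches at 55–75 ms so the R tail cannot swallow them, a
constraint Gaussian morphology imposes that sharp real QRS complexes do
not.

What the generator does *not* emulate: pathological morphologies,
within-subject morphology drift, electrode artefacts, multi-lead
structure, and the heavy-tailed noise of ambulatory recordings. Passing
tests on this cohort therefore demonstrate the pipeline's correctness and
its behaviour under idealised conditions, not clinical-grade performance;
published accuracies on clinical databases are reproduced only as
arithmetic (weighted-average pooling of the printed per-database rows),
never re-measured.

## 7. Evaluation protocol and problem sizes

The bundled evaluation (tests and `scripts/acceptance.R`) uses a
20-subject, 10-cycle, 360 Hz noise-free cohort — 200 beats, the same
per-subject cycle count as the published protocol — with a deterministic
70/30 per-subject split (7 training, 3 test cycles each). Detector quality
is scored as R recall/precision within ±3 samples and P/T detection within
±5 samples; identification as single-cycle and three-cycle majority-vote
accuracy with the WOA-tuned δ, alongside the δ = 1 baseline. Per-database
percentages are pooled by subject counts (90/18/48), reported to two
decimals. The whale optimizer is benchmarked on a 5-D sphere function
(population 10, 100 iterations), where it reliably reaches fitness below
10⁻³ from any small seed.

## 8. Known limitations

* Gaussian-bump morphology makes Q/S delineation easier than on real
  QRS complexes with slurred or notched transitions.
* The third-extremum Q/S rule degrades on smooth signals and relies on the
  trough-snapping refinement; on inverted or biphasic waves the
  `polarity` switch handles only the simple case.
* The MIV screening perturbs features one at a time and cannot see
  interactions.
* WFDB support covers single-channel format-16 records — enough to
  round-trip the package's own exports and read simple PhysioNet files,
  not the full format zoo.
* With 10 cycles per subject the test split is 3 cycles; three-cycle
  voting then rests on a single group per subject, so grouped accuracy is
  quantised in steps of one subject.
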