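---
title: "Quantifying cerebral blood and CSF flow from cardiac-gated PC-MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cerebral blood and CSF flow from cardiac-gated PC-MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cranioflow)
```

## The problem

Cine phase-contrast MRI (PC-MRI) encodes fluid velocity in the image phase,
gated to the cardiac cycle: one acquisition yields, for a plane transecting
the vessels of interest, a velocity image and a magnitude image at each of
32 cardiac frames. From such acquisitions at four planes — extracranial
vessels (internal carotid and vertebral arteries, internal jugular veins),
intracranial vessels (carotids, basilar artery, superior sagittal and
straight sinuses), the cerebral aqueduct, and the C2–C3 subarachnoid space
— one can reconstruct volumetric flow waveforms for arterial blood, venous
blood and cerebrospinal fluid (CSF), and from these derive the quantities
that characterise cranio-spinal hydro-hemodynamics: composite mean flows,
the arteriovenous flow balance, blood and CSF stroke volumes, and
pulsatility indices, compared between a young and an elderly group.

`cranioflow` implements that full measurement chain, together with a
synthetic cine generator whose scenes have closed-form ground truth, so
every stage — aliasing handling, segmentation, flow reconstruction, derived
metrics, cohort statistics — is testable end to end without any scanner
data.

## From phase images to flow curves

**Velocity convention.** Velocity images store cm/s with cranio-caudal flow
positive. Each vessel carries a `direction_sign` (+1 cranio-caudal:
veins and systolic CSF flush; −1 caudo-cranial: arteries); quantification
multiplies by it so that every reported flow curve is positive in the
vessel's own flow direction. This single convention makes composite sums
and venous/arterial comparisons sign-safe.

**Aliasing.** Velocity beyond the encoding limit `venc` wraps by
`2 venc`: a true `v` with `venc < |v| < 2 venc` is stored as
`v ∓ 2 venc`, i.e. reversed in apparent direction. A pixel-frame is flagged
as aliased when its sign opposes the vessel's flow direction *and* its
magnitude exceeds `0.75 venc` (the magnitude gate and the threshold are
configurable; the flagging rule is a documented surrogate, since clinical
descriptions only state that aliased pixels appear directed against the
flow). Flagged pixels are corrected by
`v_corrected = (2 venc − |v_err|) · (−|v_err|/v_err)`, which is exact for
single wraps. If more than half of the ROI pixels alias in any frame the
acquisition is rejected and — mirroring scanner practice — re-acquired with
doubled venc (the simulator can actually do this; at most two doublings).
Note that strongly oscillatory CSF legitimately reverses direction, so a
CSF acquisition whose velocities approach venc trips the 50% rule and is
re-acquired at the next venc rather than "corrected" into corruption.

**Segmentation.** The reference workflow uses semi-automated segmentation
based on flow properties, with operator oversight. The reproducible
stand-in here is waveform-correlation region growing: starting from a seed
pixel, 4-connected neighbours are admitted when their velocity-versus-time
waveform has Pearson correlation ≥ `r_min` (default 0.7) with the running
ROI-mean waveform *and* their temporal velocity SD exceeds a pulsatility
floor. Two engineering choices matter:

* *Matched filtering.* Both admission statistics are computed on
  cyclically boxcar-smoothed waveforms (5 of 32 frames). Smoothing leaves
  the cardiac waveform essentially intact but suppresses uncorrelated
  frame noise, which keeps weakly pulsatile lumens — venous sinuses can
  have tree pulsatility indices as low as a few hundredths — above the
  admission gates. Quantified curves always come from the raw data.
* *Automatic floor.* The floor defaults to 1.25× the median smoothed
  temporal SD over all pixels. Velocity images are background-dominated,
  so the median estimates the noise floor without any oracle knowledge of
  the scene. Seeding in static background fails the floor and raises an
  explicit error.

A provisional magnitude-based mask (flood fill of bright pixels around the
seed) precedes the waveform segmentation: it defines the ROI for aliasing
detection, and acts as the operator's contour when flow-based growth
under-segments — if the grown region recovers less than 98% of the
magnitude mask, the magnitude mask is used and the event logged. Without
this fallback, subjects whose venous pulsation sits at the noise floor
(which the reference cohort's own min–max ranges imply existed) would lose
their venous ROIs; with it, such subjects are quantified from the
anatomically correct lumen, as an operator would ensure in practice.

**Flow reconstruction.** The ROI mean velocity curve times the ROI area
gives volumetric flow: 1 cm/s × 1 mm² = 0.01 ml/s = 0.6 ml/min.

## Derived quantities

* **Composites**: ExtraACBF = both carotids + both vertebrals;
  IntraACBF = both carotids + basilar; measured ExtraVCBF = both jugulars;
  measured IntraVCBF = sagittal + straight sinus. Pointwise sums.
* **α venous correction**: measured venous drainage misses peripheral
  veins; under flow balance `α = mean(ACBF)/mean(VCBF)` and the theoretical
  venous flow is `α ×` the measured curve, so its mean equals the arterial
  mean exactly.
* **Arteriovenous flow and blood stroke volume**: the pointwise difference
  ACBF − theoretical VCBF has zero cycle mean by construction; its cyclic
  trapezoidal integral V(t) (periodic closure: sample 32 wraps to sample 1)
  is the intracranial blood volume change, and the blood stroke volume is
  `max(V) − min(V)` in ml per cardiac cycle ("ml/cc"). Reading the "total
  volume change during the cycle" as the range of V(t) is the standard
  convention and equals the positive-lobe area when the mean is zero.
* **CSF stroke volume**: mean of the two directional lobe areas of the
  signed CSF flow curve (trapezoidal, ml/s against seconds). A curve with
  no zero crossing is still integrated but flagged, since oscillatory CSF
  is assumed.
* **Pulsatility index**: Gosling's `PI = (max − min)/mean` on the raw 32
  samples, no interpolation (an interpolation scheme would be an invented
  degree of freedom); one PI per arterial tree and one per venous tree,
  computed on the composite curves.
* **Heart rate**: 60 / cardiac period.

## The synthetic cine generator

Scenes are circular lumens on a pixel grid (protocol geometry: 256 × 128
matrix, 0.55 mm pixels, 5 mm slice; venc 80 cm/s for blood, 10 cm/s
aqueduct, 5 cm/s C2–C3; 32 frames). Lumen pixels carry a spatially uniform
velocity `Q(t) / (A · 0.6)` where `A` is the *rasterized* area (pixel count
× pixel area), so ROI mean velocity × area reproduces the waveform exactly
and conservation tests hold to floating point. Velocities are wrapped into
`(−venc, venc]` exactly as a scanner would store them. Additive Gaussian
velocity noise models phase noise; an optional partial-volume ring halves
the lumen velocity one pixel outside the boundary, to emulate the
contamination that protocol design avoids.

Three waveform families are provided: a sinusoid (closed forms: a sinusoid
with mean M and half-range A has PI = 2A/M; a zero-mean sinusoid of
amplitude a ml/s has lobe volume aT/π), a gamma-variate systolic pulse on a
diastolic baseline for arterial realism, and a truncated Fourier series
with explicit coefficients (used for venous synthesis, below). Sinusoid and
gamma curves are renormalised so the cycle mean and the peak-to-trough
range are exact, making ground-truth metrics closed-form.

**Noise default.** The reference protocol reports no SNR. The default is
0.015 rad of phase noise, i.e. `venc · 0.015/π` ≈ 0.4 cm/s at venc 80 — a
high-SNR acquisition. The value was chosen so that the weakest venous
pulsations the cohort model produces remain above the waveform-correlation
detection gate, consistent with a workflow whose volumetric measurements
are repeatable to within a few percent; it is a stated assumption, not a
measured property of any scanner.

## The cohort simulator

`make_cohort()` draws per-subject parameters from group-level normal
distributions (defaults: the reference study's young/elderly group means and
SDs for composite flows, tree pulsatility indices, blood and spinal CSF
stroke volumes, heart rate; negative draws of positive quantities are
redrawn, heart rate is confined to the 45–100 BPM gate). Choices worth
stating:

* Composite flows are split across vessels by fixed anatomical fractions
  (carotids 72% of extracranial arterial inflow, jugulars 50/50, sagittal
  sinus 72% of sinus drainage, etc.); all vessels of a tree share the
  waveform shape and phase, so the tree PI is controlled exactly.
* Arterial and venous composite means are drawn independently; the α
  correction factor is therefore *emergent* per subject (the ratio), which
  is also why a cohort mean of per-subject α differs from the ratio of
  cohort mean flows — averaging ratios is not the ratio of averages.
* The venous composite waveform is *synthesized* per subject: a
  three-harmonic Fourier series whose range matches the drawn venous PI
  and whose arteriovenous volume range (against the subject's gamma
  arterial curve, after α scaling) matches the drawn blood stroke volume,
  found by multi-start Nelder–Mead on the two relative residuals. A fixed
  venous shape cannot satisfy both constraints: with a single harmonic the
  venous fundamental is pinned by the venous PI, which places a floor of
  roughly `M·|PI_a − PI_v|·T/(120π)` under the achievable blood SV — at
  the young group's intracranial means that floor (≈0.80 ml) already sits
  above the target (0.76 ml). Harmonic freedom removes the shape part of
  that floor; draw combinations that remain jointly unreachable (the
  parameters are drawn independently, so tails can be unphysiological)
  clamp to the nearest achievable pair, and the ground truth records the
  realized values.
* Aqueductal CSF stroke volume is drawn as a fraction of the spinal one
  (≈11.8% young, ≈9.8% elderly, SD 0.03), which also reproduces the
  strong aqueductal–spinal correlation seen in vivo.
* CSF waveforms are zero-mean sinusoids whose amplitude `60·π·SV/T`
  ml/min yields the drawn stroke volume in closed form.
* The cohort default matrix is a 96 × 96 crop around the vessels (the
  protocol's pixel size retained); single-plane simulations default to the
  full 256 × 128 protocol matrix. Simulation sizes used by the test-suite
  study conditions (16 + 19 subjects, 20 replicates) are the package's
  choice of a representative problem size.

What the generator does *not* emulate: k-space physics, eddy-current or
Maxwell phase offsets, motion, vessel curvature or through-plane
misalignment, intra-lumen velocity profiles (plug flow is assumed), and
waveform harmonics beyond the two shape families. Passing the recovery
suites therefore demonstrates the correctness of the measurement chain on
idealised data, not robustness to every in-vivo artifact.

## Statistical layer

Per-metric outlier exclusion implements the screening rule verbatim:
values strictly outside `[mean − 1.5·IQR, mean + 1.5·IQR]` are excluded in
a single pass (quartiles by linear interpolation, `stats::quantile` type
7). Centring the fence on the *mean* is nonstandard — on strongly skewed
data the fence chases the outlier and can exclude inliers — so the
classical Tukey quartile fence is available behind `tukey = TRUE`, off by
default. Exclusion is per metric, not listwise.

Comparisons are Shapiro–Wilk-gated at 0.05 on each sample: both normal →
Student t (paired or independent); otherwise Wilcoxon signed-rank or
Mann–Whitney. Two-sided, significance at p < 0.05, deliberately without
multiple-testing correction (matching the reference design; noted in the
report footer). Pearson correlations are classified by |r|: < 0.30
below-weak, 0.30–0.49 weak, 0.50–0.69 moderate, 0.70–0.89 strong, ≥ 0.90
very strong.

## Numerical choices and degenerate inputs

* Cyclic integrals close the cycle by wrapping sample 32 to sample 1;
  stroke volumes are invariant under cyclic rotation of the samples.
* `apply_phase_wrap` maps onto `(−venc, +venc]`; a stored 0 cannot be
  de-aliased (sign undefined) and is left unchanged with a warning.
* PI is undefined for zero-mean curves (error); CSF stroke volume of a
  unidirectional curve is computed but flagged.
* Exactly 50% aliased pixels is accepted (the rejection rule is strictly
  greater than half).
* Region growth is breadth-first in fixed pixel order; results are
  bit-reproducible under a fixed seed, as are whole cohorts.
* Zero-variance samples short-circuit the normality gate (treated as
  non-normal; a paired comparison of identical samples returns p = 1).

## A worked example

```{r example, eval = FALSE}
co <- make_cohort(16, 19, seed = 1)      # scenes + ground truth
metrics <- quantify_cohort(co)           # full imaging pipeline
report <- build_report(metrics)          # Table-1-style summary
report$ratios
```

Or end to end with artifacts on disk:

```{r pipeline, eval = FALSE}
res <- run_pipeline(run_config(n_young = 16, n_elderly = 19, seed = 1,
                               out_dir = "run1"))
```

## Known limitations

* The segmentation stand-in is deliberately simple; its admission
  threshold, smoothing width and floor are configuration, and the
  magnitude fallback assumes the magnitude image delineates the lumen
  cleanly (true in the phantom, approximate in vivo).
* The verbatim mean-centred outlier fence behaves poorly on skewed data
  (see above).
* Venous PI / blood SV pairs outside the waveform model's reachable set
  are clamped (ground truth records the realized values).
* Statistical power at the reference sample sizes is modest for some
  metrics — for spinal CSF SV the group means/SDs at n = 16/19 imply
  two-sample power near 0.7 even for an exact measurement — so
  single-cohort significance patterns vary across replicates and the
  expected match rate against the reference calls is around 0.9, not 1.
  This is a property of the design being emulated, not of the
  implementation.
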