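# cranioflow

Cerebral hydro-hemodynamics from cardiac-gated phase-contrast MRI (PC-MRI),
in R.

PC-MRI encodes fluid velocity in the image phase, gated to the cardiac
cycle. From four acquisition planes — extracranial vessels (internal
carotid and vertebral arteries, internal jugular veins), intracranial
vessels (carotids, basilar artery, sagittal and straight sinuses), the
cerebral aqueduct, and the C2–C3 subarachnoid space — one can reconstruct
volumetric flow waveforms for arterial blood, venous blood and
cerebrospinal fluid (CSF), and compare their derived parameters between
young and elderly adults. `cranioflow` implements that measurement chain
for researchers studying cranio-spinal flow dynamics and for anyone who
needs a fully testable PC-MRI flow-quantification pipeline:

* **velocity processing** — single-wrap aliasing detection
  (sign-opposition + magnitude gate, >50% aliased ⇒ re-acquire at doubled
  venc) and exact correction
  `V_corrected = (2·V_enc − |V_err|)·(−|V_err|/V_err)`;
  waveform-correlation region growing as a reproducible stand-in for
  semi-automated lumen segmentation;
* **flow quantification** — flow curves `Q = v̄ · A` (1 cm/s·mm² =
  0.6 ml/min); composite flows (ExtraACBF = 2 ICA + 2 VA, IntraACBF =
  2 ICA + BA, ExtraVCBF = 2 IJV, IntraVCBF = SSS + straight sinus); the
  venous correction `α = mean(ACBF)/mean(VCBF)` and theoretical venous
  flow; arteriovenous flow and blood stroke volume (range of the cyclic
  trapezoidal volume trace, ml per cardiac cycle); CSF stroke volume
  (mean of the directional lobe areas); Gosling's pulsatility index
  `PI = (max − min)/mean` per arterial and venous tree;
* **cohort statistics** — mean ± 1.5·IQR outlier screening, Shapiro-gated
  t / Mann–Whitney / Wilcoxon comparisons, Pearson correlations with
  strength bands, and a grouped summary report;
* **a synthetic cine generator** — pulsatile disk lumens rasterized into
  velocity + magnitude NIfTI cines with exact closed-form ground truth
  (including velocity wrap and phase noise), plus a two-group cohort
  simulator parameterized by group-level means and SDs, so the whole
  pipeline is validated end to end without scanner data.

## Worked example

```r
library(cranioflow)

co  <- make_cohort(16, 19, seed = 1)   # scenes + ground truth
m   <- quantify_cohort(co)             # full imaging pipeline
rep <- build_report(m)                 # grouped summary + tests + ratios
subset(rep$ratios, group == "HYV")
#>   group                                                        ratio     value
#> 1   HYV                                 aqueductal/spinal CSF SV (%)  11.65929
#> 2   HYV                       sinus drainage IntraVCBF/IntraACBF (%)  79.26560
#> 3   HYV                     jugular drainage ExtraVCBF/ExtraACBF (%)  63.64099
#> 4   HYV sinus-vs-jugular deficit (ExtraVCBF-IntraVCBF)/ExtraVCBF (%) -17.44460
```

The ratios read: in this simulated young group the aqueduct carries ~11.7%
of the spinal CSF stroke volume, the sinuses drain ~79% of the
intracranial arterial inflow and the jugulars ~64% of the extracranial
inflow; the negative deficit says this cohort's sinus drainage exceeded
its jugular drainage (one seeded 16-subject group; values vary with the
draws). Or end to end,
writing metrics, truth, report and logs to a run directory:

```r
run_pipeline(run_config(n_young = 16, n_elderly = 19, seed = 1,
                        out_dir = "run1"))
```

The numbered drivers under `analysis/` run the same workflow as a
three-step study (`01_simulate.R`, `02_quantify.R`, `03_cohort_stats.R`),
writing tables under `results/`.

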