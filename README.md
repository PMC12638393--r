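# csfpulse

Quantification of cerebrospinal-fluid (CSF) pulsatility from cine
phase-contrast MRI (PC-MRI), and the prognostic group comparison built on
it for Chiari malformation type 1 (CM1).

## The problem

In CM1, herniated cerebellar tonsils narrow the subarachnoid spaces at the
foramen magnum and disturb the oscillatory CSF flow that normally buffers
the systolic increase in intracranial blood volume. Whether a patient's
headaches will improve after posterior fossa decompression is hard to
predict from morphology alone; preoperative CSF *stroke volume* (SV) — the
volume of CSF displaced back and forth through a plane during one cardiac
cycle — is a candidate hydrodynamic predictor. `csfpulse` implements the
full measurement chain and the associated statistics for researchers who
want to reproduce, stress-test or extend this kind of analysis:

1. **Velocity reconstruction** — PC-MRI stores velocity in the signal
   phase: `v = venc · φ / π` (cm/s), where `venc` is the velocity
   encoding. Velocities beyond `venc` wrap by `2·venc`; a per-voxel cyclic
   temporal unwrap restores them. A constant eddy-current baseline is
   removed using static tissue.
2. **Segmentation** — the lumen is delineated semi-automatically:
   4-connected region growing on the peak-to-peak pulsatility map from a
   user seed, keeping voxels above a fraction (default 0.2) of the seed
   amplitude. Manual polygon ROIs are also supported.
3. **Flow quantification** — the flow curve `q(k) = Σ v(x,k)·A_pixel`
   (µL/s, 32 cardiac phases) is integrated by a periodic trapezoidal rule
   with zero-crossing subdivision into directional volumes `V⁺`, `V⁻`, and

   SV = (V⁺ + V⁻) / 2, net volume = V⁺ − V⁻  (µL per cardiac cycle).

4. **Morphometry** — Evans index (frontal-horn width / biparietal
   diameter) and the narrowest aqueductal cross-sectional area.
5. **Cohort statistics** — Welch/Student t tests from raw samples *or*
   published summary statistics, exact-enumeration Mann–Whitney for small
   samples, a Kolmogorov–Smirnov normality gate, threshold-exclusivity
   (dichotomisation) reports, and outcome definitions (headache relief =
   pain-VAS drop > 2 points plus quality-of-life improvement; Chicago
   Chiari Outcome Scale 13–16 = improved).

Because no patient data are deposited for this kind of study, the package
ships a **phantom generator** (pulsatile laminar flow through a small
lumen, with optional phase noise, background offset and venc aliasing,
with analytically known stroke volume) and a **cohort simulator** drawing
per-patient SVs from published group means ± SDs truncated at 0, so every
stage is testable end to end.

## Worked example

A 1.5 mm circular lumen with a 1 cm/s laminar sinusoidal waveform at
venc = 10 cm/s has closed-form stroke volume
`A·v̄₀·T/π = π·1.5²·10·1/π = 22.5 µL`:

```r
library(csfpulse)
sp <- phantom_spec(geometry = "circle", center_mm = c(8, 8),
                   radius_mm = 1.5, profile = "poiseuille",
                   waveform = list(amplitude_cms = 1, harmonic = 1,
                                   phase_rad = 0),
                   n_phases = 32, venc_cms = 10,
                   pixel_spacing_mm = 0.25, grid_shape = c(64, 64))
sim <- generate_cine_series(sp)
sim$truth$sv_true_ul
#> [1] 22.49999
res <- quantify_site(sim$series, seed = c(32, 32), site = "aqu")
res
#> stroke volume (aqu): 21.42 uL/CC  (V+ 21.42, V- 21.42, net -2.842e-14 uL)
```

The end-to-end chain recovers the analytic value within 5 % (the residual
comes from rasterising the lumen and thresholding its slow-moving rim).
Re-testing the published per-site group summaries (12 relieved vs 29
non-relieved patients) from their means ± SDs:

```r
published_summary_tests()
#>     site n1 n2 mean1 sd1 mean2 sd2       t    df p_value significant
#> 1    aqu 12 29    65  45    32  24  2.4029 13.67  0.0311        TRUE
#> 2    ppc 12 29   334 262   410 172 -0.9257 15.08  0.3692       FALSE
#> 3     fm 12 29   436 301   504 225 -0.7053 16.33  0.4906       FALSE
#> 4 nevrax 12 29   248 155   157 109  1.8530 15.70  0.0828       FALSE
#> 5   c2c3 12 29   485 163   613 166 -2.2755 20.95  0.0335        TRUE
```

Only the aqueduct (higher SV in relieved patients) and the C2-C3
subarachnoid space (lower SV in relieved patients) reach p ≤ 0.05 — both
print as p = 0.03 at two decimals.

## Analysis workflow

The `analysis/` directory holds the numbered study-replica drivers, each a
thin script over the package functions, writing its tables under
`results/`:

| script | what it does |
|---|---|
| `01_simulate_phantoms.R` | clean / noisy / aliased phantoms as NIfTI + sidecars |
| `02_quantify_phantoms.R` | full-chain SV recovery vs analytic truth |
| `03_simulate_cohort.R` | 12 + 29 patient cohort from published summaries |
| `04_group_comparison.R` | summary-statistic tests + per-patient pipeline |
| `05_threshold_analysis.R` | SV cut-off exclusivity and its replicate survival |

`run_study_replica()` performs the same composition in one call.

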