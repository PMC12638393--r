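---
title: "Quantifying CSF stroke volume from cine phase-contrast MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CSF stroke volume from cine phase-contrast MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfpulse)
```

## The measurement model

Phase-contrast MRI encodes through-plane velocity into the phase of the
complex MR signal: a voxel moving at the velocity-encoding limit `venc`
acquires a phase of exactly $\pm\pi$, so

$$v(x,k) = \mathrm{venc}\cdot\frac{\varphi(x,k)}{\pi} \quad [\mathrm{cm/s}],$$

for voxel $x$ and cardiac phase $k$. Cardiac gating resamples the cycle
onto $n$ uniform phases (32 here, the routine clinical frame count);
`venc` defaults to 10 cm/s at the aqueduct of Sylvius and 5 cm/s in the
wider cervical planes, where CSF moves more slowly per unit area but the
dynamic range matters less.

Two acquisition artefacts sit between the stored phase and a usable
velocity:

* **Aliasing.** True velocities beyond `venc` wrap by multiples of
  $2\cdot\mathrm{venc}$. `unalias_temporal()` unwraps each voxel's time
  series along the cardiac dimension: any frame-to-frame jump larger than
  `venc` is read as an alias crossing, and the whole series is then
  shifted onto the branch with the smallest absolute temporal mean —
  CSF flow is oscillatory and near zero-mean over the cycle, which is
  what disambiguates a series sitting entirely beyond `venc`. The
  operation is idempotent and a no-op when nothing wraps. Its known
  failure mode is a waveform whose *true* frame-to-frame change exceeds
  `venc`, which at 32 phases would require velocities far outside the
  physiological range of these planes.
* **Baseline offset.** Eddy currents add a slowly varying phase offset
  that does not cancel between the two encoding acquisitions.
  `background_correct()` removes a single scalar — the median velocity
  over a static-tissue mask across all frames. A per-frame mode exists,
  but the scalar default is deliberate: a per-frame correction estimated
  from a small mask can absorb genuine pulsatility into the baseline.

## Segmentation

Clinical flow software segments the CSF region "semi-automatically"
without publishing a criterion. The concretisation here is explicit and
has one parameter: compute the peak-to-peak velocity amplitude per voxel
(`pulsatility_map()`), then grow a 4-connected region from a user seed,
keeping connected voxels with amplitude at least `threshold_frac` (default
0.2) of the seed's. 4-connectivity is chosen over 8 because CSF
compartments are separated by thin septa that diagonal adjacency would
leak through. Coordinates are (row, col), 0-based, with voxel centres at
integer positions. A manual polygon ROI (`manual_roi()`, even-odd rule on
voxel centres) covers the morphometric use case.

The default threshold is a fixed reference value, not a claim of
equivalence with any particular vendor tool; it is user-overridable and
recorded in every result's provenance.

## Flow integration

For an ROI of voxel area $A$ (mm²),
$q(k) = \sum_{x\in\mathrm{ROI}} v(x,k)\,A$ converts as
1 cm/s·mm² = 10 µL/s. The directional volumes over one period $T$ are

$$V^+ = \int_0^T \max(q,0)\,dt,\qquad V^- = \int_0^T \max(-q,0)\,dt,$$

computed by a periodic trapezoidal rule after inserting the linear zero
crossings as extra nodes, and

$$\mathrm{SV} = \tfrac12\,(V^+ + V^-),\qquad
\mathrm{net} = V^+ - V^-.$$

Two numerical choices deserve comment:

* **Zero-crossing subdivision.** On a coarse 32-sample grid a plain
  trapezoid over $\max(q,0)$ clips every sign change, biasing both
  directional volumes low. Subdividing at the interpolated crossing
  removes the systematic part; what remains is the curvature error of
  linear interpolation, which scales with the square of the harmonic
  index. For fundamental-dominated waveforms (the physiological case) the
  32-sample SV agrees with $10^6$-sample quadrature to well under 0.5 %;
  a waveform whose third harmonic rivals its fundamental can err by a few
  per cent, which is a property of 32-point sampling, not of the
  integrator.
* **The SV convention.** "Integrating the flow curve" is ambiguous for
  oscillatory flow. $(V^+ + V^-)/2$ — the mean of the two directional
  displaced volumes — is adopted because it is symmetric in flow
  direction (so the sign convention of the velocity axis cannot change a
  result) and is the common summary for craniospinal CSF pulsatility. The
  consequence is documented rather than hidden: a purely unidirectional
  waveform yields SV equal to *half* the displaced volume. The convention
  is isolated in `stroke_volume()` so an alternative (e.g. the maximal
  excursion of the cumulative displaced volume) can be swapped in.

Units are fixed end to end: velocities cm/s, areas mm², flow µL/s,
volumes µL per cardiac cycle.

## The phantom generator

`phantom_spec()` + `generate_cine_series()` synthesise a cine series with
analytically known truth: a circular (or annular) lumen in static tissue,
mean-lumen velocity $\bar v(t)=\sum_j A_j \sin(2\pi h_j t/T+\phi_j)$, a
plug or Poiseuille (parabolic, centreline = 2× mean) spatial profile,
i.i.d. Gaussian phase noise, an optional constant background offset, and
honest wrapping of the stored phase to $[-\pi,\pi)$ so super-venc
phantoms genuinely alias. A voxel belongs to the lumen iff its centre
falls inside the geometry. The analytic flow curve is
$Q(t)=A_{\mathrm{lumen}}\,\bar v(t)$ and the reference SV comes from
$\ge 4096$-sample quadrature of $Q$.

What the phantom *does not* model — and therefore what passing tests do
not establish about patient data: Womersley (frequency-dependent) flow
profiles, through-plane angulation, partial-volume voxels at the lumen
rim, gating jitter and heart-rate variability, spatially varying coil
noise, and k-space acquisition effects. The phantom validates the
*processing*, not the acquisition.

Default test scale: 64×64 voxels at 0.25 mm, 32 phases, radius 1.5 mm —
an aqueduct-sized lumen where rasterisation keeps the discrete lumen area
within 10 % of $\pi R^2$. At these settings the noise-free end-to-end
recovery error is ≈ 4.8 %: about half from rasterising the lumen
boundary, half from the 0.2 amplitude threshold excluding the
slowest-moving Poiseuille rim voxels. With plug flow (uniform lumen
amplitude) the same chain is exact to ≈ 0.4 %.

## The cohort simulator

`generate_cohort()` draws each patient's five site SVs from
$\mathcal N(\mu_{s,g},\sigma_{s,g})$ truncated at 0, with $\mu,\sigma$
taken from the published group summary table (12 relieved / 29
non-relieved patients) by default. Truncation matters: several sites have
$\sigma$ comparable to $\mu$, and it shifts the expectation upward by
$\sigma\,\phi(\mu/\sigma)/\Phi(\mu/\sigma)$ (up to several µL here) —
recovery tests therefore compare sample means against the truncated-law
expectation, not the nominal $\mu$. Morphometrics are drawn from a single
shared distribution for both groups (Evans index
$\mathcal N(0.27, 0.03)$, aqueductal area $\mathcal N(2.6, 0.9)$ mm²,
both truncated to plausible ranges): the study reports only that these
indices did not differ between groups and gives no per-group values, so
the simulator encodes exactly that null structure with centre values in
the normal adult range. The simulated cohort emulates marginal
distributions only — no between-site correlation within a patient, which
real craniospinal hydrodynamics certainly has; power or exclusivity
estimates that depend on joint behaviour should be read accordingly.

## Statistics

* **t tests.** Both the Welch and the pooled-variance Student forms are
  implemented, from raw samples or directly from $(n,\bar x,s)$
  summaries. The default is **Welch**: recomputing the published per-site
  comparisons from their summary statistics, only the Welch form
  reproduces the published significance pattern (aqueduct $t=2.40$,
  $\nu\approx13.7$, $p\approx0.031$; C2-C3 $p\approx0.034$; the remaining
  three sites $p>0.05$), whereas the pooled form yields $p\approx0.004$
  at the aqueduct and would additionally flag the tonsillar site
  ($p\approx0.038$). The mismatch between the published method label
  ("Student's t-test") and the variant that actually reproduces the
  published p-values is recorded in the comparison metadata.
* **Mann–Whitney.** $U$ counts pairs $x>y$ (ties ½). For $n_1+n_2\le12$
  without ties the two-sided p is exact from the combinatorial null
  distribution of $U$; the test suite verifies it against brute-force
  enumeration of all $\binom{n_1+n_2}{n_1}$ group assignments. Larger or
  tied samples use the normal approximation with tie and continuity
  correction.
* **KS normality gate.** One-sample Kolmogorov–Smirnov distance against a
  normal with plug-in mean/SD, with the asymptotic p-value. Plug-in
  estimation makes this conservative as a normality test (the Lilliefors
  correction is deliberately not applied, keeping the classic form);
  the gate's operating characteristics are what the type-I simulation
  measures: the full gate-then-test pipeline holds 3–7 % empirical size
  at $\alpha=0.05$ for $n=12$ vs 29.
* **Multiplicity.** No correction by default — five sites are tested at
  $\alpha=0.05$ each, matching the source analysis; `holm = TRUE`
  enables a Holm adjustment for methodological comparison.
* **Outcomes.** Relief requires a VAS drop strictly greater than 2
  points *and* quality-of-life improvement; CCOS totals 13–16 count as
  improved, so 38 of 41 gives 92.7 %.

## Degenerate inputs and tie-breaks

Empty masks, non-pulsatile seeds, zero-area polygons, constant samples
in the KS test, and groups of fewer than two patients are errors with
specific messages. Two equal-SD, equal-mean summary groups give $t=0$,
$p=1$ rather than an error. The narrowest-slice search breaks area ties
toward the smaller slice index. The unaliasing branch tie-break prefers
the smaller shift, leaving a constant series at $0.9\cdot\mathrm{venc}$
untouched.

## Problem sizes used by the checks

The shipped tests and the reproduction script run phantoms at 64×64×32
(plus one 170×170 profile check), 20-seed noise ensembles, exhaustive
Mann–Whitney enumeration up to $n_1+n_2=10$, 2000 null simulations at
$n=12$ vs 29 for the empirical size, and cohorts of 600 per group for
parameter recovery — sizes at which every Monte-Carlo bound in the suite
has comfortable slack while the whole run stays interactive.

## Known limitations

* Spatial (2-D) phase unwrapping is out of scope; only temporal
  unwrapping is provided.
* No Maxwell-term, gradient-nonlinearity or through-plane angulation
  corrections.
* The segmentation criterion is a reference concretisation of an
  unpublished semi-automatic step; agreement with any specific clinical
  software is not claimed.
* Group-comparison conclusions from simulated cohorts inherit the
  simulator's independence assumptions; they demonstrate the machinery,
  not clinical effect sizes beyond the published summary statistics they
  are seeded with.
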