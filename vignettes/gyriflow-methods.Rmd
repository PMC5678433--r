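---
title: "Methods: gyrification, flow and oxygen delivery in gyriflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gyrification, flow and oxygen delivery in gyriflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gyriflow quantifies cortical development in the newborn brain from two
kinds of input: labelled tissue segmentations (NIfTI volumes whose integer
labels map to tissue classes and lobes) and phase-contrast velocity series
over the cardiac cycle with vessel regions of interest. From these it
derives three families of measurements — the three-dimensional
gyrification index (GI), regional tissue volumes, and cerebral blood flow
with the oxygen delivery it implies — and a statistical layer that
compares a disease group against matched controls and regresses
haemodynamics against cortical metrics. Because suitable clinical datasets
are not freely redistributable, every stage is validated against synthetic
phantoms with closed-form ground truth; this vignette records the models,
the tunable parameters and the design decisions behind them.

## Gyrification index

GI is defined as the ratio of the pial surface area (the outer boundary of
the cortical grey matter) to the area of a smooth superficial surface that
tightly encloses it. A convex brain has GI near 1; folding raises it. The
pipeline operates on the combined cortical grey / white matter mask of the
requested region:

1. **Cleaning** (`clean_mask`): a 3×3×3 volumetric median (majority)
   filter followed by retention of the largest 26-connected component.
   On a solid ball this changes the volume by under 1%; isolated voxels
   and pinholes disappear.
2. **Pial surface** (`extract_surface`): marching cubes at iso-level 0.5
   on the {0, 1} volume, vertices in physical mm via the voxel spacing,
   followed by light Laplacian smoothing (1 iteration at relaxation 0.5
   by default).
3. **Superficial (hull) surface** (`close_mask` + `extract_surface`):
   morphological closing by 3 dilations and 2 erosions with a 6-connected
   cross structuring element, meshed the same way, then smoothed more
   heavily (10 iterations at 0.5).
4. **GI** = pial area / hull area, with both areas reported alongside.

### Why both surfaces are smoothed, and unequally

Marching cubes on a binary mask produces a staircase whose area excess is
substantial and systematic: our regression tests measure +7% on a ball of
radius 40 voxels. Ten Laplacian iterations remove it almost exactly (the
smoothed ball mesh lands within 1% of the analytic sphere). Left
unsmoothed in only one branch, this bias does not cancel in the ratio:
with a raw hull the GI of a solid ball falls to about 0.88, well outside
the 0.93–1.02 band expected from pure convex geometry (the 3 − 2 closing
adds one net dilation, so the hull of a ball of radius R is a ball of
radius about R + 1 voxel).

The two surfaces, however, have different jobs. The hull is *meant* to be
the smooth envelope of the gyral crests — any corrugation it retains
between crests is reconstruction error, so heavy smoothing is appropriate
and brings the hull area onto the analytic envelope. The pial folds are
*signal*: at fold wavelengths near the resolvability limit imposed by the
closing radius (see the phantom guard below), ten smoothing iterations
measurably shrink genuine folds and bias GI low by 20–30% against the
quadrature oracle. One iteration knocks down roughly half the staircase
while leaving the folds nearly intact; combined with the heavily smoothed
hull, the sphere GI sits near 0.99 and the folded-phantom GI lands within
10% of its analytic value. Both iteration counts and the relaxation factor
are explicit parameters (`gi_params`), and every result carries them as an
attribute. The standalone `smooth_mesh` operation keeps the conventional
(10, 0.5) defaults.

### Surface extraction without imported tables

No installed library provides 3D iso-surfacing, so marching cubes is
implemented in compiled code with one twist: the 256-case triangulation
table is *derived at load time* rather than transcribed. For each corner
sign pattern, marching squares runs on the six cube faces; face saddles
are resolved by always isolating the inside corners (a rule both adjacent
cells apply identically, which guarantees watertightness); the segments
are linked into closed loops and fan-triangulated about their centroid.
For binary data at iso-level 0.5 all boundary vertices are cube-edge
midpoints, so vertices weld exactly between cells; the test suite asserts
that every mesh edge borders exactly two faces.

### Regional GI: two modes

For lobar values the default (`lobar_mode = "mask"`) reruns the pipeline
on the lobe-restricted mask. The flat cut faces then contribute to both
numerator and denominator, which dilutes every lobar GI toward 1; lobar
values are comparable between subjects but not with the whole-brain value,
and the whole-brain GI generally exceeds all of them. The alternative
(`"patch"`) reconstructs the whole-brain surfaces once and assigns faces
to lobes by the azimuthal quadrant of their centroid, so the lobar areas
partition the whole-brain areas exactly and the whole-brain GI provably
lies between the lobar extremes. Patch assignment by azimuth matches the
phantom's sector-based lobes; for anatomical lobe labels the mask mode is
the general tool.

## The folded-cortex phantom

The generator voxelises the radial surface

r(θ, φ) = R + a·m(φ)·sin(kθ)·sin(kφ)

with base radius R, fold amplitude a, integer angular frequency k, and a
per-quadrant amplitude multiplier m(φ) (the four azimuthal quadrants act
as "lobes"; with even k the fold vanishes on quadrant boundaries, so
stepwise multipliers leave the surface continuous). The outer ribbon of
stated thickness is labelled cortical grey matter, the interior white
matter, each split by quadrant. The pattern is symmetric in θ and φ so
that both fold directions share the same wavelength; the pial area and
solid volume follow from dense midpoint quadrature of the first
fundamental form, and the hull from the analytic envelope
Σ quadrants π(R + a·m)².

The envelope model is only honest when the morphological closing can
actually bridge the sulci: the generator refuses specs whose gyral spacing
π(R + a_max)/k exceeds three times the closing radius (3 dilation steps ×
voxel size). This guard, enforced in the oracle rather than the GI code,
pins the fold spacing to at most ~9 voxels — which is exactly why the
smoothing intensity matters above.

Defaults (R = 60 mm, a = 2 mm, k = 22, 1 mm voxels, 144³ grid, uniform
lobes) were fixed once against the quadrature oracle before any pipeline
comparison: the pipeline recovers the oracle GI to −2.3% at a = 1 and
−9.5% at a = 2, deterministically (the phantom has no random component).
What the phantom does *not* emulate: real neonatal sulci are tight slits
rather than open sinusoidal valleys, there is no anatomical atlas, no
deep grey matter, cerebellum or CSF compartment, and no segmentation
noise beyond voxelisation itself. Passing phantom tests therefore
demonstrates the geometry of the pipeline, not robustness to segmentation
error on clinical images.

## Flow and oxygen delivery

Vessel flow integrates signed through-plane velocity over the ROI per
cardiac phase (cm/s × cm² = cm³/s), averages over the cycle and converts
to ml/min; net flow is reported because phase-contrast velocities are
signed and no rectification rule is imposed. Total CBF is the sum over
left and right internal carotid and basilar arteries; the vertebral
contribution below the basilar confluence (a few percent of total brain
flow) is documented, not modelled.

The flow phantom gives each vessel a parabolic (Poiseuille) profile
v(r, p) = v_peak·m_p·(1 − (r/R_v)²) with a raised-sinusoid cardiac
modulation of mean 1, so the time-averaged flow has the closed form
(v_peak/2)·πR_v²·mean(m)·60. Defaults approximate neonatal vessels
(radii 1.0/1.0/0.9 mm, peaks 40/40/30 cm/s, 20 phases, 0.2 mm pixels —
one fifth of the smallest radius, at which the discretised flow is within
5% of the closed form, and well under the 140 cm/s encoding ceiling that
the spec-level validator enforces). Velocity series are stored as a single
multi-volume NIfTI (x, y, phase) because plain 2D NIfTI images do not
reliably round-trip pixel spacing.

Oxygen delivery uses CDO₂ = SaO₂ × Hb(g/dL) × 1.36 × CBF(ml/min), with
1.36 ml O₂ per gram of haemoglobin (Hüfner's constant). Neonatal CDO₂
values around 1600 "ml O₂/min" arise from evaluating this formula with Hb
per decilitre while CBF is per minute of millilitres — a factor-of-100
unit convention. The default `as_printed` mode reproduces that scale so
outputs are comparable with the literature; `si` mode divides by 10 for a
dimensionally conventional value, and g/L inputs are converted on entry.
Saturations must be fractions in (0, 1]; percent inputs are rejected with
a corrective message rather than silently rescaled. Indexed CDO₂ divides
by brain volume in units of 100 ml.

## Synthetic cohorts and the statistical layer

The cohort generator draws gestational and postmenstrual ages for two
groups, oxygen delivery for the disease group only (control flow data are
typically unavailable), and builds gyrification and grey-matter volume as
intercept + slope·CDO₂ + group offset + Gaussian noise, with controls
evaluated at the population-mean CDO₂ so the injected offsets *are* the
expected group differences. The population R² of a metric on CDO₂ is
(slope·sd)²/((slope·sd)² + noise²); defaults are tuned so grey-matter
volume sits near 0.48 and GI near 0.28, with group means around 132/122 ml
and 2.46/2.37 — magnitudes typical of term newborns scanned around 39
weeks. NIRS readings are drawn with a repeat-measurement population R² of
0.86. All generation is deterministic given the spec's seed and leaves the
caller's RNG state untouched.

Statistical choices:

* **Matching**: one-to-one case–control assignment minimising total
  Euclidean distance in (GA, PMA), solved exactly as a linear assignment
  problem by a Jonker–Volgenant-style shortest-augmenting-path solver
  (greedy matching is not optimal and is not used). Ties break
  deterministically by subject identifier; the test suite checks equality
  with exhaustive enumeration for all pool sizes up to 8.
* **Group comparisons**: per-outcome ordinary least-squares ANCOVA,
  outcome ~ group + PMA (+ optional extra covariates), with the group
  coded control = 0, disease = 1 so effects read as disease-minus-control.
  Listwise deletion with a reported count; singular designs are an error
  naming the collinear columns. With a single two-level factor plus
  continuous covariates the sums-of-squares type question does not arise.
* **Multiplicity**: only the four-lobe GI family is Bonferroni-corrected
  (0.05/4 = 0.0125); exploratory analyses are reported uncorrected, and
  the report flags the family and threshold per row.
* **Mann–Whitney**: exact two-sided p (twice the smaller tail, capped at
  1) whenever the product of sample sizes is ≤ 400, computed from the
  full permutation distribution of the rank sum by dynamic programming
  over doubled midranks — ties are exact, which `wilcox.test` does not
  offer; the normal branch applies tie and continuity corrections, and
  the two agree to within 0.01 at 15 per group.
* **Fisher's exact test**: two-sided by summing hypergeometric
  probabilities no larger than the observed table's, as implemented by
  `stats::fisher.test` (cross-checked against a manual hypergeometric
  sum in the tests).
* **Repeatability**: Pearson correlation of paired consecutive readings,
  reported with its square.

A null simulation (1000 replicates, 30 per group, no injected effects)
keeps the ANCOVA group test's type-I error near 5%, and parameter-recovery
simulations confirm injected offsets fall inside their 95% confidence
intervals; both run inside the acceptance script at the problem sizes
quoted there.

## Orchestration and reproducibility

`run_subject` composes volumetrics, GI and haemodynamics per subject;
failures are recorded per subject, never silently dropped. `run_cohort`
emits `cohort_metrics.csv`, `group_comparisons.csv`, `regressions.csv`
(CDO₂, indexed CDO₂ and rScO₂ against cortical metrics, plus the NIRS
repeat-reading repeatability row), `matching.csv`, optional
`failures.csv`, and a `manifest.json` carrying the full config, its MD5
and the seed — identical config and inputs give identical outputs. The
on-disk demonstration cohort (`demo_phantom_cohort`) uses 30 mm phantoms
at 1.25 mm voxels with group-distinct fold amplitudes (2.5 vs 1.5 mm), so
the whole run, including three flow phantoms per disease subject, stays
around ten seconds; the acceptance checks use the full 144³ phantoms.

## Known limitations

* Fold wavelengths are capped near nine voxels by the envelope guard, so
  the oracle comparison exercises the hardest resolvable regime but not
  coarse folding, and amplitude a = 2 mm sits within 10% of the oracle
  while deeper folding would not — a resolution limit, not a bug.
* Mask-mode lobar GI values are cut-face diluted (by design, following
  the restricted-mask definition) and must not be compared with
  whole-brain values.
* Background phase-offset correction, velocity anti-aliasing and vessel
  segmentation are out of scope; ROIs are taken as given.
* The cohort generator models linear effects with Gaussian noise only —
  adequate for parameter-recovery and calibration tests, not a clinical
  simulation.
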