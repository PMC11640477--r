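---
title: "Methods: synchronized contrast-enhanced 4DCT analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synchronized contrast-enhanced 4DCT analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ce4dct)
```

## The problem

Liver and pancreatic SBRT targets move with respiration (often 1–2 cm,
dominantly superior–inferior) and show poor soft-tissue contrast on
unenhanced CT. A 4DCT resolves the motion into ten respiratory phases
but not the visibility problem; a diagnostic contrast CT shows the tumor
but in a single, arbitrary breathing state. Synchronizing the contrast
injection with the 4DCT acquisition — so the scanner crosses the tumor
exactly at the desired post-injection contrast-phase time in every
phase — addresses both at once. The quantitative ingredients of that
workflow, and of the evaluation of how badly the conventional
(diagnostic-CT + unenhanced-4DCT) delineation misses the true motion
envelope, are what this package implements.

## The timing model

Three times are read off the baseline 4DCT: `t0` (first absolute
slice), `t1` and `t2` (first/last slice containing the tumor). The time
for the scanner to reach the tumor's craniocaudal center is

$$t_{scan} = \frac{t_1 + t_2}{2} - t_0,$$

and the injection must precede scan start by

$$t_{delay} = t_{phase} - t_{scan},$$

with `t_phase` the desired post-injection time of the target contrast
phase (initial defaults 50 s arterial, 70 s portal). Positive `t_delay`
is automated by the scanner countdown; negative requires a manual
(stopwatch) injection start before the scan. **Design choice:**
`t_delay = 0` is classified as automated — a zero delay needs no
stopwatch; the boundary is not specified by the workflow itself.
Contrast volume is `min(factor × weight, 140 mL)` with the per-kg factor
restricted to 1.8–2.0 mL/kg, injected at 2.5 mL/s — deliberately slower
than diagnostic protocols so the washout stretches and the usable
enhancement window widens.

`locate_tumor_slices()` defines `t1`/`t2` on the *union* of the phase
masks (the full respiratory extent), because the baseline 4DCT shows the
tumor across its motion range. Slice-to-time mapping assumes a constant
couch speed (uniform slice interval); pitch is accepted as metadata but
plays no role in the arithmetic, since the times are recorded directly
from the scan.

## Contrast kinetics

Aortic enhancement is measured in circular axial ROIs with two geometric
rules: diameter at least 5 mm, boundary at least 2 mm inside the aortic
edge. Both constraints are simultaneously satisfiable only for vessels
≥ 9 mm; narrower ones are rejected for manual review. Voxel membership
is by in-plane voxel center inside the disc — unambiguous at any
spacing.

The time axis of the extracted curve is
`t_delay + (slice_time − t0)` seconds post injection; it is affine in
slice index, and pre-injection slices legitimately yield negative times.

**Peak**: argmax of a centered moving average (default 3 samples), ties
to the earliest time, HU reported unsmoothed. **Plateau**: the earliest
time after the peak whose trailing window (default 10 s) has
least-squares slope within ±0.5 HU/s; the plateau HU is the window mean.
Two deliberate choices here: (i) the window must lie wholly after the
peak, because a window straddling the peak averages rise against fall
and fakes a flat segment; (ii) "plateau" has no standard quantitative
definition in this context, so both knobs are exposed as arguments.
Whether a clinically reported plateau HU is a window mean or a single
sample is equally unspecified; the window mean is the more stable
choice.

**Population refinement.** Across patients, `t_phase` is updated to the
median peak time (arterial) or median plateau time (portal), after
excluding outliers by Tukey fences (1.5 × IQR on the peak time, type-7
quantiles). Anomalous contrast kinetics occur in real cohorts without a
published defining criterion; Tukey fences are a standard parameter-free
stand-in, not a clinically validated rule — a known limitation.

## Masks, ITV, PTV

All structures live on regular grids with physical spacing and explicit
patient-axis semantics, canonicalized at construction to LPS order
(+x → L, +y → P, +z → S). Only axis-aligned orientations are accepted:
directional margins are defined on patient axes, and supporting oblique
grids would smuggle in a resampling step with its own ambiguities.
Voxel coordinates are voxel centers throughout; extents use face
coordinates (center ± spacing/2).

The ITV is the voxelwise union of the ten phase masks. The PTV adds an
isotropic margin by *Euclidean distance in millimetres* (a voxel joins
if its center is within the margin of an occupied center), implemented
as a structuring-element dilation whose offsets are exactly the lattice
vectors inside the ball — exact mm semantics on anisotropic spacing,
unlike a fixed-shape structuring element in voxel units. Anisotropic
(six-direction) expansion is the analogous box dilation with per-signed-
direction half-extents, separable per axis. Expansion that would leave
the grid is clipped with a warning rather than an error: finite phantom
grids make clipping routine and it is surfaced in the report.

## Comparison battery and margins

Dice, Jaccard (`dice = 2j/(1+j)` is asserted as an invariant), centroid
shift, percentage volume difference with the contrast-enhanced ITV1 as
denominator, and mean distance agreement (MDA). MDA is the *symmetric*
mean surface distance: boundary voxels (occupied with an unoccupied face
neighbor; grid-edge faces count as unoccupied) of each mask contribute
their nearest-boundary distance to the other mask, both directions
pooled, computed via an exact Euclidean distance transform
(lower-envelope algorithm with anisotropic spacing). Whether a given
clinical MDA is symmetric or one-directional is generally unstated;
symmetric is the common radiotherapy convention and is what the
all-pairs test oracle checks. No sub-voxel surface interpolation is
used — distances are between voxel centers, which keeps every metric
oracle-checkable. Both-masks-empty overlap is defined as perfect
agreement (1, 1) with a warning, avoiding 0/0 while surfacing the
degenerate case.

The six-direction margin for ITV2 to encompass ITV1 is defined as the
clipped bounding-extent difference per patient direction:
`margin_d = max(0, extent_d(ITV1) − extent_d(ITV2))` with `extent_d` the
outermost occupied-voxel face coordinate toward direction `d`. This is
one concrete reading of "geometric differences per direction"; a
surface-distance-percentile definition would be an alternative. The
bounding-extent form has the properties clinical margin tables exhibit —
independent per-direction values, zeros where already encompassed,
occasionally large single-direction values — and it guarantees by
construction that `expand_anisotropic(itv2, margins)` reaches ITV1's six
extremes, which `evaluate_with_margins()` re-checks and reports
(`encompassed`), warning rather than erroring so that user-supplied
margins (including zero) still produce a report. Margins on a shared
grid are automatically integer multiples of the voxel spacing; rounding
to 0.1 mm happens only at the reporting layer (half-away-from-zero, the
convention of printed margin tables).

## The digital phantom: what it emulates, what it does not

The phantom states the world the analysis assumes: a ~14 mm ellipsoidal
lesion (static ≈ 11.5 cc; with 10 mm SI motion the ITV lands near the
~19 cc scale of clinical medians) on a 1×1×2 mm grid; ten phases with a
cos⁴ displacement profile (more dwell time at exhale, the usual
respiratory asymmetry; for even phase counts the sampled profile spans
exactly the peak-to-peak amplitude — for odd counts it falls one sample
short, a documented restriction); a 20 mm aorta whose enhancement is a
gamma-variate first pass blended by a smoothstep onto a constant
recirculation plateau. Parameters default to a noiseless peak at
10 + 3 × 14.8 = 54.4 s and 292 HU with a 169 HU plateau from 70.3 s —
the enhancement pattern reported for slow-injection abdominal
protocols. Noise is additive Gaussian HU, seedable; acquisition is a
uniform helical timeline (default 1.5 s × 60 slices ≈ 88 s, inside the
57–107 s range of clinical 4DCT durations).

The phantom deliberately does *not* model sinogram formation and phase
binning, irregular breathing, deformable anatomy, partial-volume edges,
or beam-hardening — so a green phantom test establishes that the
*analysis chain* is correct (formulas, geometry, detection logic,
statistics), not that the clinical acquisition behaves. Cohort-level
clinical quantities (visibility rates, the −21.2 % ± 21.5 % volume
difference, 69 %/53 %/2.89 mm overlap medians, 54.5/70.3 s kinetic
medians) depend on patient images that are not publicly deposited; they
serve as emulation targets for the phantom defaults and as documented
context, and the test suite substitutes property-based criteria
(oracle equivalence, ground-truth margin recovery, parameter recovery,
encompassment) for them.

`generate_itv_pair()` constructs ground truth for the margin method:
ITV1 as the full-phase union, ITV2 with dropped phases and a known
whole-voxel translation, and expected margins from an independent
brute-force extent scan.

## Numerical choices

- Tie-breaks: peak detection returns the earliest of equal maxima;
  `which.max` semantics, asserted by test.
- Tolerances: grid equality 1e-9 (spacing) / 1e-6 mm (origin); disc and
  ball membership use a 1e-9 slack so exact-boundary voxels are included
  deterministically; distance comparisons in tests at 1e-9 mm.
- Round trips: timing arithmetic is exact for inputs representable in
  binary (asserted over 1000 random 0.25 s-multiple tuples).
- Statistics: sample SD (n−1) everywhere — the packaged reference
  cohort's printed SDs reproduce only under n−1, which the acceptance
  test exploits as a built-in convention check; paired t is the
  closed-form statistic with `2·pt(−|t|, n−1)`, checked against
  `stats::t.test`. The degenerate all-zero-difference case returns
  (t = 0, p = 1); constant non-zero differences are rejected.
- File formats: NRRD (attached header, raw/gzip/ascii) and NIfTI-1
  (sform only; qform-only files are rejected with an informative error)
  are implemented in-package against their published layouts, as no
  reader for either format exists in the declared dependency set.

## Known limitations

- The outlier rule and the plateau criterion are reasoned stand-ins for
  unpublished clinical judgment calls; their knobs are exposed.
- Margins are bounding-extent based and voxel-quantized; sub-voxel
  margin values cannot arise on a shared grid.
- No registration: mask pairs must share a grid; resampling is the
  caller's concern.
- Tumor-invisible baseline scans (delineation from anatomical markers)
  are surfaced as an error, not automated.
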