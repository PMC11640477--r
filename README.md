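# ce4dct

Analysis tools for **synchronized contrast-enhanced 4DCT (ce4DCT)
simulation** in abdominal stereotactic body radiotherapy (SBRT).

Abdominal tumors (liver, pancreas) move 1–2 cm with respiration and are
often nearly invisible on unenhanced CT. One way to delineate them
reliably is to inject intravenous contrast *synchronized* with the 4DCT
acquisition so that the scanner reaches the tumor exactly when it is
maximally enhanced, in every respiratory phase. This package implements
the quantitative chain around that workflow:

- **Personalized injection delay.** From the slice timing of a baseline
  4DCT — first slice at `t0`, first/last tumor-containing slices at
  `t1`/`t2` — the time to reach the tumor center is
  `t_scan = (t1 + t2)/2 − t0`, and the injection delay is
  `t_delay = t_phase − t_scan`, where `t_phase` is the desired
  post-injection contrast-phase time (defaults: 50 s arterial, 70 s
  portal). Positive `t_delay` → scanner-automated synchronization;
  negative → manual (stopwatch) start of injection before the scan.
  Contrast volume is `min(1.8–2.0 mL/kg × weight, 140 mL)` at 2.5 mL/s.
- **Aortic contrast kinetics.** Circular aortic ROIs (≥ 5 mm diameter,
  ≥ 2 mm inside the vessel edge) yield a time–density curve HU(t); the
  first-pass **peak** and washout **plateau** are detected
  (moving-average argmax; earliest post-peak trailing window with
  least-squares slope ≤ 0.5 HU/s over 10 s) and pooled across patients
  to refine `t_phase` (arterial → median peak time, portal → median
  plateau time, Tukey-fence outliers excluded).
- **Target volumes.** ITV = voxelwise union of the ten respiratory phase
  GTV masks; PTV = ITV ⊕ 5 mm (Euclidean distance, exact mm semantics on
  anisotropic grids).
- **ITV1 vs ITV2 comparison.** Volume, percentage difference
  `(V2 − V1)/V1 × 100`, centroid shift, Dice `2|A∩B|/(|A|+|B|)`, Jaccard
  `|A∩B|/|A∪B|`, and mean distance agreement (symmetric mean boundary
  distance). Six-direction margins (R/L/A/P/S/I) for ITV2 to encompass
  ITV1 are derived from per-direction bounding-extent differences and
  re-evaluated after anisotropic expansion.
- **Cohort reporting.** Per-direction mean ± SD margin tables, paired
  t-test, structured JSON/markdown run reports. A reference 12-patient
  margin table is packaged (`example_margin_table()`).
- **Digital phantom.** A synthetic 4DCT stand-in — ellipsoidal lesion
  with cos⁴ respiratory motion split into ten phases, enhancing aorta
  with gamma-variate-plus-plateau kinetics (noiseless peak 54.4 s /
  292 HU, plateau 169 HU from 70.3 s), helical slice timestamps — so the
  entire chain is testable without clinical data.

Masks are read/written as NRRD (raw/gzip/ascii encodings) or NIfTI-1
(`.nii`, `.nii.gz`), axis-aligned orientations only, canonicalized
internally to LPS patient axes.

## Worked example

```r
library(ce4dct)

# phantom stand-in for a patient 4DCT
spec  <- phantom_spec(seed = 1)
masks <- generate_phase_masks(spec)                  # ten phase masks
ts    <- (seq_len(spec$grid_dims[3]) - 1) * spec$slice_interval

loc <- locate_tumor_slices(masks, ts)
tim <- phase_timing(loc$t0, loc$t1, loc$t2, phase = "arterial")
tim
#> <phase_timing> t0=0 t1=31.5 t2=58.5 | t_phase=50  t_scan=45  t_delay=+5 (automated)

# aortic kinetics from the phantom CT volume
vol  <- generate_aorta_volume(spec, ts, t_delay = tim$t_delay,
                              noise_sd = 10, seed = 1)
rois <- lapply(seq_along(ts), function(k)
  build_aorta_roi(spec$aorta_diameter, k, spec$aorta_center_xy))
analyze_tdc(extract_tdc(vol, rois, ts, tim$t_delay, ts[1]))
#> t_peak 53.0 s / 292 HU, plateau 78.5 s / 169 HU

# ITV1 vs degraded ITV2, margins, re-evaluation
pair <- generate_itv_pair(spec, dropout_phases = c(0, 9),
                          known_shift_mm = c(2, 0, -4))
compare_masks(pair$itv1, pair$itv2)
#> vol1 17.69 cc | vol2 16.55 cc (-6.4%)
#> centroid shift 5.33 mm | Dice 0.781 | Jaccard 0.641 | MDA 2.49 mm
mg <- derive_margins(pair$itv2, pair$itv1)
mg
#> <margin_vector> mm: R=2.0 L=0.0 A=0.0 P=0.0 S=6.0 I=0.0
evaluate_with_margins(pair$itv2, mg, pair$itv1)$dice
#> 0.887  (post-margin Dice; extremes encompassed in all six directions)

# packaged reference cohort margins
summarize_margins(example_margin_table(), "all")
#>   direction mean  sd  n
#>           R  3.1 3.1 12
#>           L  2.7 2.8 12
#>           A  4.9 6.1 12
#>           P  4.0 4.9 12
#>           S  3.9 4.0 12
#>           I  4.3 3.5 12
```

The interpretation: the degraded delineation is 6.4% smaller than the
reference ITV and misses part of the motion envelope; the derived
directional margins restore coverage at all six extremes and raise the
Dice index from 0.78 to 0.89.

A command-line wrapper is installed as `exec/ce4dct`
(`ce4dct timing --t0 0 --t1 30 --t2 50 --phase arterial ...`; run with
no arguments for usage).

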