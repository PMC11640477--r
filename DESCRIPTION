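Package: ce4dct
Title: Synchronized Contrast-Enhanced 4DCT Timing and Target Volume Analysis
Version: 0.1.0
Authors@R:
    person("ce4dct", "developers", email = "ce4dct@example.org", role = c("aut", "cre"))
Description: Analysis chain for synchronized contrast-enhanced four-dimensional
    computed tomography (ce4DCT) simulation in abdominal stereotactic body
    radiotherapy: personalized contrast injection delay computation from slice
    timing, aortic time-density-curve peak and washout-plateau detection with
    population refinement of the target contrast phase, internal target volume
    (ITV) construction from respiratory phase masks with isotropic and
    anisotropic margin expansion, a geometric comparison battery (volume,
    centroid shift, Dice, Jaccard, mean distance agreement), six-direction
    margin derivation, and cohort-level reporting.  Includes a synthetic 4DCT
    digital phantom (moving ellipsoidal lesion, enhancing aorta with
    gamma-variate first-pass kinetics, helical slice timestamps) so the whole
    pipeline is testable without clinical data, and plain-text NRRD/NIfTI-1
    binary mask I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
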