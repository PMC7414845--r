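# paleocanid

Tools for the quantitative evidence used to separate early domestic dogs
from wolves in Late Glacial faunal assemblages. Distinguishing a small
adult dog from a small or juvenile wolf cannot rest on any single trait,
so the package implements the full set of complementary analyses as
reusable, tested components:

- **Biometry** — log-shape-ratio comparison of postcranial measurements
  (von den Driesch codes) against a standard skeleton:
  `d = log10(x / x_std)`, with the stated exclusion rules (reworked,
  burnt, unmeasurable specimens) applied and itemized.
- **MicroCT tissue proportions** — percent of crown dentine of the lower
  first molar, `Vcdp/Vc (%) = dentine / (dentine + enamel) × 100`,
  measured in a 3D slice between a cervix-parallel plane through the
  fossa floor and the level where the enamel cap splits into the two main
  cusps; with multi-Otsu segmentation, occlusal wear screening, and
  triple-reference reconstruction of teeth broken at the cervix.
- **BV/TV maturity screen** — bone volume over total volume of the
  proximal metacarpal epiphysis (porous = skeletally immature), with the
  TV envelope from morphological closing.
- **Outline geometric morphometrics** — 80 + 60 sliding semilandmarks on
  the crown outline constrained by two anchor landmarks, generalized
  Procrustes analysis, thin-plate-spline bending-energy sliding,
  between-group PCA with a-posteriori projection of unknowns, and
  allometry tests of bgPC scores on log centroid size.
- **Ancient-DNA authenticity** — fragment-length statistics, strand-aware
  terminal C→T / G→A deamination profiles, and reference coverage of an
  aligned read set (TSV or SAM).
- **Radiocarbon** — inverse-variance combination of replicate
  determinations with a chi-square consistency check, and calibration
  against an IntCal-format curve with highest-posterior-density ranges.

A seeded synthetic-data module (`gen_*` functions) generates every input
the pipeline consumes — outline populations, tooth and epiphysis voxel
phantoms, osteometric tables, damaged read sets, monotone calibration
curves — with ground truth attached, so each estimator is validated
against brute-force oracles without any external data.

## Worked example

```r
library(paleocanid)

# ancient-DNA signature of a simulated Late Glacial sample
rs <- gen_ancient_reads(read_sim_config(n_reads = 50000, seed = 42))
st <- fragment_length_stats(rs)
pr <- damage_profile(rs)
sprintf("reads: %d   mean length: %.2f bp", st$n, st$mean)
#> "reads: 49963   mean length: 57.60 bp"
sprintf("5' C>T: %.3f   3' G>A: %.3f", pr$ct5_rate[1], pr$ga3_rate[1])
#> "5' C>T: 0.371   3' G>A: 0.475"

# percent of crown dentine of a tooth phantom
ph <- gen_tooth_phantom(tooth_phantom_config(seed = 42))
seg <- segment_tissues(ph$gray, n_classes = 3)
sl <- extract_crown_slice(seg, ph$truth$cervix_plane)
dentine_percent(sl)
#> crown slice: Vcdp 1.306 mm^3 / Vc 3.048 mm^3 = 42.8% dentine (breadth 3.30 mm)

# radiocarbon calibration against a synthetic monotone curve
cc <- gen_calibration_curve(curve_sim_config(seed = 42))
calibrate_c14(c14_measurement(12175, 55), cc)
#> Calibrated date for 12175 +/- 55 BP (mode 12833 cal BP)
#> 95.4% HPD ranges (cal BP):
#>   12944 - 12726  (95.5%)
```

The mean fragment length sits at the configured 57.6 bp and the terminal
substitution rates recover the configured 0.38 / 0.48 within binomial
error — short fragments and high terminal deamination are the signature
of authentic ancient DNA. The dentine percent of 42.8% is the phantom's
true slice composition to within the voxel-counting tolerance. With a
real IntCal curve in place of the synthetic one, the same call reproduces
published calibrated ranges (see `read_intcal()`).

A full demo pipeline over all five stages, with a machine-readable JSON
report, is one call:

```r
run_pipeline(list(seed = 1, out_dir = "demo_run"))
```

and `inst/cli/paleocanid.R` exposes the same operations as a thin command
line (`simulate`, `biometry`, `tissue`, `damage`, `calibrate`, `run`).

## Documentation

The methods vignette (`vignettes/paleocanid-methods.Rmd`) describes the
models and procedures, the tunable parameters and their defaults, what
the synthetic generators do and do not emulate, and the numerical and
design choices, with known limitations.
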