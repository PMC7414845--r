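---
title: "Methods: separating Late Pleistocene dogs from wolves"
author: "paleocanid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: separating Late Pleistocene dogs from wolves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

paleocanid implements, as reusable and tested components, the quantitative
lines of evidence by which small Late Glacial canids are told apart from
wolves: postcranial biometry against a standard skeleton, microCT tissue
proportions of the lower carnassial, trabecular bone maturity screening,
crown-outline geometric morphometrics, ancient-DNA authenticity summaries,
and radiocarbon calibration. Each stage is paired with a seeded synthetic
generator that produces inputs with known ground truth, so every claim the
package makes about its estimators is checked against quantities that can
be computed by brute force.

## Biometry: log shape ratios

Osteometric measurements (von den Driesch codes, mm) are compared with a
single designated standard individual through
$d = \log_{10}(x / x_{\mathrm{std}})$, the classic Simpson log-ratio
diagram: negative values mark specimens smaller than the standard. Base-10
logarithms are used because that is the axis convention of log-ratio
diagrams in the zooarchaeological literature. Specimens flagged as
reworked, burnt, or unmeasurable are excluded before analysis and each
removal is itemized; missing measurements are omitted, never imputed,
since only measured variables are plotted. Both specimen-level profiles
and per-population summaries (n, mean, sd, range per measurement) are
produced, since a log-ratio diagram can plot either. Two invariants pin
the arithmetic down: a common rescaling of all values and the standard
leaves every $d$ unchanged, and a noise-free population generated with
size factor $f$ has mean $d = \log_{10} f$ exactly.

The bundled standard individual (`canid_standard()`) is synthetic: a
plausible set of postcranial measurements for an adult female wolf of
about 67 cm shoulder height. It exists to give generated populations a
fixed reference; it is not measurement data from any real skeleton.

## MicroCT tissue proportions of the lower carnassial

Grayscale volumes are segmented by multi-level Otsu thresholding
(exhaustive search over a 256-bin histogram). The "semi-automatic"
contract of threshold segmentation in virtual dental histology is kept by
reporting the chosen thresholds and accepting manual overrides; a
degenerate histogram (zero variance, or fewer distinct intensities than
classes) is an error that names the offending statistic rather than a
silent empty class.

The percent of crown dentine is measured in a 3D slice bounded by two
cross-sections parallel to the cervix plane. The cervix plane itself is a
total-least-squares fit to the cervix point set, extracted as enamel
voxels touching both dentine and background (the enamel margin at the
enamel-dentine junction). Cross-section 1 passes through the lowest point
of the occlusal valley between the paraconid and protoconid: the surface
height is sampled along the straight segment between the two cusp apices,
per voxel column, and minimized. Cross-section 2 is the lowest
cervix-parallel level at which the enamel cap above it splits into two
26-connected components, found by bisection; "the level where the cusps
separate" is a geometric phrase, and connectivity of the cap gives it a
testable operational meaning. Apices are found deterministically: the top
decile of enamel voxels by height is split by farthest-point clustering
and each cluster contributes its highest voxel. The slice is the set of
tooth voxels strictly between the planes, and

$$ \mathrm{Vcdp/Vc}\,(\%) = \frac{V_{dentine}}{V_{dentine} + V_{enamel}}
\times 100 $$

with volumes as voxel counts times the cubed voxel size. Pulp or void
space inside the slice is not part of Vc: the formula names dentine and
enamel only. All geometry is done in signed heights above the plane, so
the measurement is invariant to axis relabelling (90-degree rotations)
and to voxel-size rescaling, which the tests verify to 0.5%.

**Wear screening.** Occlusal wear appears as flat facets with locally
thinned or absent enamel. Above cross-section 2 the tooth is binned into
columns along the plane normal; in each column whose surface lies above
the section, the occlusal enamel thickness is the distance from the
surface voxel to the nearest dentine voxel (zero when dentine is exposed
at the surface). A tooth is flagged worn when dentine is exposed or when
the minimum column thickness falls below a configurable fraction (default
0.5) of the median thickness. The distance-to-dentine definition was
chosen over a vertical enamel run because the run length through a
steeply sloping shell overestimates thickness by the secant of the slope,
which made the min/median statistic unstable at this voxel resolution.

**Broken cervix.** When the cervix is partly missing its plane cannot be
fitted directly. The preserved cervix points are aligned to the cervix of
each of three intact reference teeth by a similarity transform (rotation,
translation, uniform scale) estimated by iterated closest points with
Umeyama least-squares updates, initialized from the fitted plane normals
and centroid/RMS-radius matching. Each alignment carries the reference's
cervix plane back into the target's coordinates (re-oriented toward the
target's own enamel, since a ring-symmetric alignment can come back
flipped), the slice is extracted under that orientation, and the dentine
percent computed - three estimates per broken specimen, as in the
triple-reference reconstruction the protocol prescribes.

**BV/TV.** For metacarpal epiphyses, bone volume over total volume is
computed on the proximal side of a separation plane. TV is the volume
inside the outer bone envelope, obtained by morphological closing of the
bone mask with a Euclidean ball (radius 5% of the epiphysis diameter,
configurable), padded so dilation is never clipped at the grid edge; BV
is the bone voxel volume. Closing with a Euclidean ball rather than
iterated 6-neighbourhood steps matters: the iterated (L1) element carves
diagonal directions deeper and biases TV. The maturity call uses a
configurable threshold whose default, 0.65, is the midpoint of the
default young (porosity 0.5) and adult (porosity 0.2) phantom cohorts;
no numeric cutoff is available from real data, only the ordering porous =
immature.

Group comparisons of tissue values use the Mann-Whitney U test with an
exact permutation distribution for combined n of 25 or fewer, computed by
a shift algorithm over doubled midranks so ties are exact (two identical
tied samples give p = 1); larger samples use the normal approximation
with tie and continuity correction.

## Crown-outline geometric morphometrics

Occlusal crown outlines carry two homologous anchor landmarks that split
the outline into two curves, resampled to 80 and 60 semilandmarks equally
spaced by arc length (142 points with the anchors). Orientation is
normalized to counter-clockwise and right teeth can be mirrored to left,
since semilandmark homology requires a common traversal frame.
Generalized Procrustes analysis removes translation, scale (to unit
centroid size, sizes kept for allometry) and rotation; 2D rotations are
solved in closed form in the complex representation, and the tests check
the two-shape solution against both an SVD oracle and a 0.01-degree
brute-force rotation grid.

Semilandmarks then slide along their local outline tangents to minimize,
by default, the thin-plate-spline bending energy between each specimen
and the Procrustes mean - the classical criterion of the sliding
semilandmark tradition - with the Procrustes-distance criterion
selectable. Sliding and re-superimposition alternate; the recorded
objective sequence is non-increasing by construction (an iteration that
fails to improve is discarded and iteration stops), and anchors never
move. Sliding is a tangent-space linearization, so very large slides
would leave the outline; at the slide magnitudes the generator produces
this is negligible.

Between-group PCA takes the principal axes of the group mean shapes with
groups weighted equally, giving at most g - 1 between-group axes;
individuals, and a-posteriori specimens of unknown affiliation, are
projected onto those axes without ever influencing the means. With two
groups there is exactly one between-group axis; additional axes shown by
the model are PCA axes of the within-group residual and are explicitly
flagged `"residual"` rather than silently appended - the package does not
guess how a second axis might have been obtained elsewhere. Group
assignment is by nearest group mean in between-group score space, with a
permutation-style typicality ((r+1)/(n+1)) per group and an overlap flag
when a score sits inside more than one group's 95th distance percentile.

Allometry is tested by regressing each score axis on log centroid size
(log, because shape ratios scale multiplicatively; the choice is
conventional and documented rather than prescribed), reporting slope,
R-squared and the F-test p-value.

## Ancient-DNA summaries

Only read-level summaries of a given alignment are computed - mapping,
merging and consensus calling are upstream concerns. Fragment-length
statistics are taken on the read strings. The damage profile counts, at
each of the first K positions from the 5' end, reads carrying T where the
read-oriented reference has C, over reads whose read-oriented reference
has C there - and symmetrically G to A from the 3' end. Reverse-strand
reads are handled by reverse-complementing the reference window, so
damage is always measured in the molecule's own frame; the terminal
(position 1) rates are the primary quantities, with the whole K-position
profile reported. Coverage is summarized as the fraction of reference
positions with depth of at least 1 and the mean depth over all positions,
zero-depth positions included (the wording "average coverage" is
ambiguous; including zeros is the documented choice here).

## Radiocarbon

Replicate determinations of one sample combine by inverse-variance
weighting, with a chi-square consistency check on the weighted residuals;
an inconsistent pair still returns the combination but carries a warning.
Calibration interpolates the curve linearly (in both mean and error) to a
1 cal-yr grid - IntCal grids are 5 to 20 years, too coarse for stable HPD
endpoints - and evaluates the posterior
$p(t) \propto \exp\!\big(-(y-\mu(t))^2 / 2(\sigma^2+s(t)^2)\big)$ under a
uniform prior. Highest-posterior-density ranges are the smallest
density-ranked set of grid ages reaching the requested mass (default
0.954), merged into contiguous ranges; each grid point stands for a
one-year cell, so ranges extend half a step beyond the outermost selected
points. Endpoints are not otherwise rounded; OxCal rounds them to 5 or 10
years, so comparisons with published ranges should allow that much slack.
On wiggly curves the frequentist coverage of the HPD sits slightly below
the posterior mass (the uniform-in-calendar-age prior is not uniform in
radiocarbon age, and curvature shifts the credible set); the coverage
check's tolerance accommodates this known, small effect. The identity-curve limit (posterior normal,
95.4% range = age plus or minus two sigma) and the linear-curve limit
(HPD width inversely proportional to slope) are both tested, and
frequentist coverage of the 95.4% HPD is checked over 1,000 simulated
dates on a synthetic curve.

The package reads calibration curves in the IntCal comma-separated
format. No calibration curve is bundled: IntCal is third-party data, so
the user supplies `intcal13.14c` (or any successor) and
`read_intcal()` ingests it.

## The synthetic-data generators

Every generator is seeded and returns the ground truth needed to compute
downstream expected values by direct counting or closed form.

*Outlines* are truncated Fourier series on the polar radius around a
fixed base crown shape (an elongated outline with two cusp bumps), which
guarantees closed star-shaped curves; group contrast, within-group noise
and allometric displacement all act on the Fourier coefficients. Group
sample sizes default to 21 and 23, the dog and wolf sample sizes of the
crown-outline analysis this emulates. A contrast of "3 times the
within-noise" is defined as an offset vector whose norm is three times
the expected norm of a within-group deviation vector
($\sigma\sqrt{2n_f}$); defining it per-coefficient instead would make the
between-group mean distance smaller than the mean within-group deviation
and the qualitative group separation unreproducible. The magnitudes of
within- and between-group shape variance are not known from real data;
the defaults are calibrated only to reproduce the qualitative overlap
pattern of two close but separable groups. The allometric slope for a
target R-squared is derived in closed form from the variance
decomposition of the leading between-group score (group term, isotropic
noise, allometric term), and the recovery check judges the mean fitted
R-squared over 20 replicate datasets of n = 44: a single replicate's
R-squared has a sampling standard deviation near 0.11 at this n, so only
the replicate mean is a meaningful recovery target.

*Tooth phantoms* build the crown as the maximum of two Gaussian cusps and
two lateral crests over an elliptic footprint tapering to the cervix,
with a dentine root below the cervix plane. The crests enclose the fossa
so that the valley floor (cross-section 1) genuinely lies below the
cap-split level (cross-section 2), as in a real trigonid; without them
the two levels coincide and the slice is empty. Enamel is the set of
crown voxels within the configured thickness of the outer surface,
realized by Euclidean-ball erosion. Wear is a planar truncation of the
cusp tips; a cervix break removes a slab at the mesial end of the cervix
band. Ground-truth fossa and split levels are computed numerically from
the continuous surface (fine-grid bisection with 2D connectivity), and
the true slice composition by direct voxel counting.

*Epiphysis phantoms* are ellipsoids of bone in which a fraction
`porosity` of trabecular-compartment voxels are void. By default the
whole epiphysis is trabecular (uniformly porous tissue): skeletally
immature bone is porous in both its trabecular and cortical compartments,
and this choice keeps the identity BV/TV = 1 - porosity exact for the
phantom, which the voxel-count checks rely on. A solid cortical shell of
any thickness can be requested instead. The default ellipsoid spans about
59 voxels across: at substantially coarser resolution the discrete
closing that defines TV systematically misses void voxels in the
high-curvature surface layer and biases BV/TV upward by 0.01-0.02.

*Reads* have lognormal fragment lengths (positive, right-skewed, as
observed ancient-DNA length distributions are), moment-matched to the
configured mean and sd, filtered at 30 bp; the default sd (12 bp) is
small enough relative to the filter that truncation moves the retained
mean by well under 0.1 bp. Deamination applies C-to-T at the 5' end and
G-to-A at the 3' end with per-position probability decaying exponentially
inward - the canonical damage-profile shape the estimator must recover.
Defaults (terminal rates 0.38 and 0.48, mean length 57.6 bp) are the
magnitudes reported for authentic Late Glacial material.

*Calibration curves* are a linear cal-to-14C trend plus smooth
random-phase sinusoids, damped until strictly monotone so the true
calendar age is recoverable; the inverse mapping is returned for
round-trip tests.

What the generators do **not** emulate is worth stating: no beam
hardening, ring artifacts or partial-volume blur in the volumes (only
Gaussian intensity noise); no digitization error model for outlines
beyond coefficient noise; no library-preparation or contamination
structure in the reads; no plateau or reversal structure in the
calibration curves beyond sinusoidal wiggles. Passing the recovery tests
therefore shows the estimators are correct and well calibrated under
clean, known-truth conditions - not that they are robust to every
artifact of real material.

## Numerical choices and problem sizes

GPA converges when the mean shape changes by less than 1e-10; sliding
stops at a relative objective change of 1e-6 or 10 iterations, and the
linear solves carry a 1e-10 ridge. The bending-energy matrix uses the
kernel $U(r) = r^2 \log r^2$. Otsu searches a 256-bin histogram.
Bisections (cap-split level, curve damping) run to a quarter-voxel or
better. The Mann-Whitney exact path enumerates via dynamic programming up
to combined n = 25 and switches to the corrected normal approximation
beyond.

The test suite and the acceptance script size their simulations to run on
one CPU in a few minutes while keeping Monte-Carlo error well inside each
tolerance: 50,000 reads for damage recovery (binomial error ~0.004 on a
0.38 rate), 1,000 simulated dates for HPD coverage (~0.007), 500
replicates for the allometry type-I rate (~0.010), 20 replicates of n=44
for R-squared recovery (~0.025 on the mean), tooth-phantom cohorts of 21
and 23 at 0.1 mm voxels, and epiphysis cohorts of 7 young and 8 adult.
The isometric type-I simulations use a reduced semilandmark scheme (20 +
15) because the size-independence of the scores, not the landmark count,
is what that test exercises.

## Known limitations

Sliding is tangent-linearized and does not re-project onto the original
outline curve. The cervix ICP can settle into the ring's near-symmetric
flip; the plane is re-oriented afterwards, which is sufficient for
slicing but means the mesial/distal identity of a reconstruction should
not be read off the transform. bgPCA with small samples in high
dimensions is known to exaggerate group separation when groups are truly
identical; the package reports typicality and overlap rather than a
classifier and keeps residual axes labelled. The wear screen is a
screen: it flags thinning and exposure, it does not segment or stage
facets. Calibration assumes a uniform prior and a single determination;
sequence modelling, reservoir corrections and wiggle matching are out of
scope.
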