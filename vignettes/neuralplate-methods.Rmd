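---
title: "Methods: quantifying planar polarity, rosettes and morphometrics in segmented neural plate epithelia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying planar polarity, rosettes and morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuralplate)
```

# Scope and data model

`neuralplate` quantifies tissue organisation in single-plane projections of
the neural plate's apical surface. Its substrate is a **label image**: a
watertight 2-D raster in which every pixel carries the positive integer
identity of the cell that owns it, the native output of seeded-watershed
segmentation of junctional (ZO1) staining. Label 0 is reserved for
optionally masked regions. All downstream computation is defined on label
adjacency, so the validator insists that each cell's pixel set is
4-connected (a label split into islands is a broken segmentation and is
reported by name) and that no background gaps separate cells.

Two axis conventions matter throughout. Image rows and columns follow R's
matrix indexing with row 1 at the top; by default image **columns are the
embryo's mediolateral (ML) axis** and rows the anteroposterior (AP) axis.
Because embryo mounting fixes the ML axis per image, the convention is a
parameter (`ml_axis`), not an assumption.

# The junction graph

A **boundary pixel** is one whose 8-neighbourhood (own pixel included)
contains at least two distinct labels. Boundary pixels seeing exactly two
labels are attributed to that unordered cell pair; pixels seeing three or
more labels are **vertex pixels**. Junction segments are the 8-connected
components of same-pair boundary pixels, vertices the 8-connected
components of vertex pixels (incident cells = the union of labels seen in
their neighbourhoods). Vertex pixels are excluded from junction pixel sets,
so two junctions of the same cell pair separated by a vertex remain
distinct, and every boundary pixel belongs to exactly one junction or one
vertex — a partition property the test suite checks directly.

Two connectivity choices are deliberate: 8-connectivity for neighbourhood
label counting (diagonal meetings at vertices must be seen) and
4-connectivity for label validity (8-connected cells would admit degenerate
single-pixel diagonal bridges). Note that this boundary definition is
two-sided: an interface contributes boundary pixels on both of its flanks,
so a junction's pixel count is roughly twice its geometric length.

**Orientation.** A junction's orientation is the principal
(total-least-squares) axis of its pixel coordinates — the eigenvector of
the coordinate scatter matrix with the larger eigenvalue — folded into
[0°, 180°) and measured from the ML axis. TLS was preferred over an
endpoint chord because it is robust to curved junctions and approximates
what a user-drawn measurement line captures. Junctions with fewer than two
pixels or perfectly isotropic scatter have no defined axis; they are
flagged (`NA`) and excluded from binning rather than assigned an arbitrary
angle. Junctions shorter than `min_length = 4` pixels (configurable) are
also excluded from polarity analysis: at that scale the raster, not the
tissue, dictates the angle.

# The planar polarity statistic

Each analysable junction contributes the arithmetic mean of the channel's
grey values over its pixel set — the digital analogue of a 1-pixel line
profile. Orientations are partitioned into four half-open bins,

* Bin 1 = [0°, 45°), Bin 2 = [45°, 90°), Bin 3 = [90°, 135°),
  Bin 4 = [135°, 180°),

with bins 1 and 4 classed mediolateral and bins 2 and 3 anteroposterior.
The half-open convention resolves the boundary ambiguity of "between 0°
and 45°" descriptions: 45°, 90° and 135° land deterministically in bins 2,
3 and 4. One consequence, stated rather than hidden: junctions lying
*exactly* on a bin boundary (e.g. perfect raster diagonals at 45°)
necessarily change axis class under a reflection of the image, so the
reflection symmetry of the statistic holds for junctions in bin interiors.

ML and AP junction intensities are compared with a **two-tailed, unpaired,
pooled-variance Student's t-test**, with the junction as the statistical
unit, pooled across embryos; s.e.m. is the sample standard deviation of the
pooled junction set divided by √n. Whether one should instead average
within embryos first is a genuine design fork; the package pools junctions
(matching "n ≥ 200 junctions from ≥ 3 embryos" style reporting) and
reports `n_embryos` alongside so an embryo-level summary can be
reconstructed. The headline effect size is the ratio of ML to AP bin-mean
intensities. Scaling the channel by any positive constant scales means and
leaves t and p unchanged.

Saturated projections bias junction means, so channels whose maximum sits
at the 16-bit ceiling are flagged on read — flagged, not rejected, since
the decision belongs to the analyst.

# Junctional vs medial fluorescence

The junctional zone is the band within Chebyshev distance 1 of any
boundary pixel. The medial zone of a cell is its mask eroded so that no
pixel of *another* cell lies within Chebyshev distance `margin` (default
2 px: one pixel to clear the band plus one guard pixel; the inset is not
dictated by the measurement itself, so it is exposed). The image frame
does not erode — cropping an embryo is not a cell boundary. Pixels in
neither zone are excluded and counted; cells whose medial zone erodes away
are dropped with a warning count. The reported `junctional_fraction` is
junctional sum / (junctional + medial sum), which on rendered tissue
recovers the generator's junctional share within the tolerance the guard
ring allows (±0.05 in the tests).

# Rosettes: coordination numbers by ROI expansion

The rosette statistic asks how many cells meet at a shared vertex once
cell outlines are allowed a small tolerance. For expansion radius *k*
(2 and 3 px are both computed, mirroring the dual-threshold presentation):

1. dilate every cell mask by the closed metric ball of radius *k*
   (Euclidean disk by default; Chebyshev square available — the expansion
   of a hand-drawn ROI is isotropic, but no metric is canonical, so it is
   a parameter);
2. pixels covered by ≥ 3 dilated masks are candidate-vertex pixels;
3. clusters are the 8-connected components of candidate pixels;
4. a cluster's members are all cells whose dilated mask intersects it —
   a direct transcription of "overlap";
5. a cell's coordination number is the size of the largest cluster its
   dilation touches; cells touching no cluster get the natural floor of 2
   (purely bicellular contacts). Interior cells of a generic tessellation
   get 3 (tricellular vertices); rosettes read out as 5 and above.

Increasing *k* can merge nearby vertices into one cluster. That is not an
artefact to suppress — it is exactly how a coarser overlap tolerance
increases apparent rosette cellularity — and it yields two provable
monotonicity facts, which the tests assert on every tessellation they
touch: a cell's coordination number is non-decreasing from *k* = 2 to
*k* = 3, and every *k* = 2 cluster is contained in some *k* = 3 cluster of
at least its cellularity. The *total number* of clusters, by contrast, may
fall when clusters merge even as new weak ones appear, so no monotonicity
is claimed for it.

Because the expansion-overlap machinery is the package's scientific core,
an independent **brute-force oracle** (`coordination_oracle()`) computes
the identical contract by directly evaluating, for every pixel, which
cells lie within metric distance *k* — no morphological shortcuts, a
different component-labelling routine — and the suite requires exact
agreement of cells and clusters on dozens of seeded tessellations at both
radii. Consistency with the junction graph is also asserted: every vertex
with *m* incident cells seeds a cluster of coordination ≥ *m*.

One ambiguity inherited from the source analysis: ROIs "with an average
area of 800 pixels" expanded by 2–3 px could be read as a scale
normalisation before expansion. The package does not rescale; `radius_k`
is in pixels of the input image, and users of differently scaled images
should choose *k* accordingly.

**Apical areas** are per-cell pixel counts (× `pixel_size`² when physical
units are set), averaged over interior cells only — border-touching cells
are cropped by the field of view and excluded by default.

# Embryo-level morphometrics

* **Penetrance** is 100·affected/total. Printing follows the field's
  habit: round half away from zero to one decimal and drop trailing zeros
  (9/24 → 37.5, 9/12 → 75), with an integer mode for whole-percent
  reporting (3/9 → 33). Groups below n = 4 warn.
* **m/w axis ratio**: each mutant embryo's axis length (2nd cervical
  vertebra to pelvic girdle) divided by its wildtype littermate's. When a
  litter holds several wildtypes the package uses their mean — a stated
  deviation from the literal "a wildtype littermate", chosen because it
  uses all of the litter's information; `normalizer = "first"` restores
  the literal reading. A litter without a wildtype is an error naming the
  litter.
* **Spina bifida severity** is open-cord length / axis length ∈ [0, 1].
  Craniorachischisis embryos (entire axis open) have no defined spina
  bifida length: they count toward penetrance and are excluded from
  severity.
* **students_t()** wraps the pooled-variance two-sample t-test
  (df = n₁ + n₂ − 2, two-tailed); an independent textbook-formula
  evaluation serves as the oracle in the tests. Zero pooled variance with
  equal means returns t = 0, p = 1; with unequal means it is an error.

# The synthetic-tissue generator

The generator exists so that every stage can be tested against known
ground truth; its defaults define the package's simulated study
conditions.

**Tessellation.** Cells are the rasterised nearest-seed (Voronoi) cells of
a jittered **rectangular** seed lattice; ties go to the lowest seed index.
A rectangular lattice was a deliberate choice over a hexagonal one: its
junction orientations concentrate near 0° and 90° — emulating the chains
of mediolaterally aligned junctions that motivate the 4-bin scheme — and
under the cos² rendering law (below) that concentration makes the ML/AP
bin-mean ratio a consistent estimator of the true anisotropy. A hexagonal
lattice concentrates orientations near {30°, 90°, 150°} (or
{0°, 60°, 120°}), for which the bin-mean ratio systematically
underestimates a 2-fold anisotropy by 12–20% even noise-free; with the
4-bin statistic fixed by the analysis, lattice geometry is the only place
consistency can live. The default `jitter_sd = 0.75` px (≈ 4% of the
default ~18 px seed spacing) breaks the degenerate four-fold vertices of
an exact grid while keeping orientations within ~±10° of the axes; larger
jitter broadens the angle distribution and biases the recovered ratio
toward 1 — real, less ordered epithelia sit somewhere along that slope,
which is a stated limitation, not an accident.

`area_scale` multiplies the mean cell area by scaling the canvas by
√`area_scale` at fixed seed count, so cell count stays exactly at
n_rows × n_cols. **Rosettes** are injected by replacing a lattice seed with
`rosette_cellularity` seeds on a circle of radius 3 px, which forces those
wedge cells to meet around one point; centres must sit at least two
spacings apart, placement retries 10 times and then fails loudly rather
than silently omitting a rosette. Rasterising thin wedges can pinch a cell
into islands, so the generator repairs connectivity deterministically:
each label keeps its largest 4-connected component and every minor island
is handed to the neighbour with the longest shared border. Ground truth
records per-cell areas, per-pair junction orientations (a Voronoi edge is
perpendicular to its seed displacement), and rosette membership.

**Rendering.** Junction pixels of a junction at orientation θ receive the
noise-free mean

$$I(\theta) = B\,\bigl(1 + (\rho - 1)\cos^2\theta\bigr),$$

so I(0°)/I(90°) = ρ exactly; ρ = 1 renders an unpolarised tissue. The law
is smooth and anchored at the axes; with the generator's near-axis angle
distribution the ML/AP bin-mean ratio recovers ρ within 10% for
ρ ∈ {1, 1.5, 2} at n ≥ 200 junctions and noise up to 20% of signal (tested
at fixed seeds). Vertex pixels, whose orientation is undefined, receive
the angular mean B(1 + (ρ−1)/2). The painted skeleton is widened to the
Chebyshev-1 band (non-skeleton band pixels inherit the brightest adjacent
skeleton value; skeleton pixels keep their exact law value, so noise-free
junction means are exact). A fraction 1 − `junctional_fraction` of each
cell's total signal is then spread uniformly over the cell interior, and
Gaussian noise and an optional Gaussian PSF blur are applied last. Values
are clipped to the 16-bit range on write.

**Cohorts.** Each genotype row draws NTD status Bernoulli(p), axis length
Normal(μ, σ) truncated at zero (rejection sampling), and spina bifida
length as a fixed fraction of axis length for affected spina-bifida
embryos. Embryos are dealt into litters with wildtypes spread first so
every litter can normalise its mutants. The fixture cohort uses NTD
probabilities 0.375 and 0.75 for its two mutant genotypes — the worked
penetrance levels — and a shortened axis in the double-insult genotype.

**Determinism.** Every stochastic operation takes an explicit integer seed
and restores the caller's RNG state; identical parameters and seed give
bit-identical rasters, channels and tables, and the full pipeline is
byte-deterministic given config and seed — asserted by hashing its output
files.

# Presets and the analysis workflow

`make_fixture()` materialises three presets: *wildtype* (ρ = 2, junctional
fraction 0.9, B = 100, two 7-cell rosettes), *shroom3_mutant*
(`area_scale` 1.48, junctional fraction 0.5, B = 60 — i.e. 40% dimmer
junctions with half the signal medial — two 5-cell rosettes, ML bias of
the remaining junctional signal retained), and *unpolarized* (ρ = 1,
otherwise wildtype-like). The numbered scripts under `analysis/` run the
complete workflow over these presets and write their tables under
`results/`. Note the two mutant presets differ in rosette cellularity *as
well as* cell size, so the preset-vs-preset area ratio mixes the two
effects; the clean `area_scale` recovery (within 5% over ≥ 300 interior
cells per group) is computed on rosette-free tessellations in the tests
and the acceptance script.

# Problem sizes and numerical choices

The test suite and acceptance script run at deliberately modest sizes,
chosen as the smallest that exercise each property convincingly: polarity
recovery on 11 × 11-cell tessellations of 200 × 200 px (≈ 220–300
analysable junctions, comfortably above the n ≥ 200 condition);
oracle-equivalence on fifty 64 × 64 px tessellations at k ∈ {2, 3};
unpolarised-tissue calibration over 100 seeded runs (the ML-vs-AP test at
α = 0.001 must stay non-significant in ≥ 95% of them); area recovery on
21 × 21-cell tessellations (361 interior cells per group); cohort
calibration with power ≥ 0.9 for a 20% axis effect and a false-positive
rate ≤ 1% over 200 null seeds.

Other numerical conventions, collected: nearest-seed ties break to the
lowest seed index; TLS orientation uses the image-moment closed form
0.5·atan2(2µ₁₁, µ₂₀ − µ₀₂); degenerate orientations are flagged `NA`,
never defaulted; metric balls are exact offset sets (no approximate
brushes), so Euclidean k = 2 reaches 13 pixels and k = 3 reaches 29;
connected components use union-find with path halving (the oracle uses an
independent queue-based flood fill); penetrance printing rounds half away
from zero (R's own `round()` is half-even).

# Known limitations

* The generator's junction-angle distribution is implicit in lattice
  geometry. Real neural plates are less ordered; as the angle distribution
  broadens, the 4-bin ML/AP ratio increasingly understates the true
  anisotropy. Passing recovery tests demonstrate correctness of the
  pipeline under the generator's conditions, not unbiasedness on arbitrary
  tissue.
* All junctions passing the length filter are measured. A user-drawn-line
  workflow measures a selected subset; whether such selection biases bin
  means cannot be settled here, and the package makes the inclusive
  choice.
* Synthetic channels have uniform per-junction intensity, additive
  Gaussian noise and an optional isotropic PSF; they do not emulate
  intensity gradients along junctions, out-of-focus light, segmentation
  error, or cell-to-cell expression variability.
* 2-D only: no 3-D tissue, no time-lapse, no mechanical (vertex-model)
  simulation of convergent extension; rosette dynamics (formation vs
  resolution) are invisible to a single snapshot.
* The severity model ties spina bifida length deterministically to axis
  length within genotype; it tests the measurement conventions, not
  biological variance in severity.

```{r session}
sessionInfo()
```
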