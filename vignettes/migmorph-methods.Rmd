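---
title: "Methods: automated 3D microglia morphometry with migmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated 3D microglia morphometry with migmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(migmorph)
```

`migmorph` quantifies microglial ramification from single-channel confocal
Z-stacks. This vignette explains the models and procedures behind each
stage, the tunable parameters and their defaults, what the synthetic
phantoms emulate (and what they do not), and the numerical choices made
where the design was genuinely open.

## Coordinate and intensity conventions

Stacks are numeric 3D arrays in (z, y, x) axis order with voxel spacing
`(dz, dy, dx)` in micrometres; the default grid is 0.3 × 0.3 μm in-plane
with 1 μm optical sections, a typical confocal configuration. The physical
coordinate of a voxel is its centre. Intensities are photon-count-like
non-negative values treated as 16-bit on disk; TIFF files are written with
a JSON sidecar carrying the spacing, which takes precedence over TIFF
resolution tags on reading (conflicts are reported). Label maps are 16-bit
with 0 = background; skeletons are exported as SWC in physical μm.

## Segmentation chain

**Local contrast enhancement.** Contrast-limited adaptive histogram
equalization is applied per z-slice (`clahe_block_radius_px = 63`,
`clahe_max_slope = 3`), the behaviour of the slice-wise enhancement tools
this chain emulates. Two degenerate cases pass through unchanged: exactly
constant slices, and quasi-constant slices where one histogram bin holds
more than 90% of the pixels — equalizing those only amplifies noise or is
undefined.

**Global threshold.** The Li minimum-cross-entropy threshold iterates
`t ← (μ_f − μ_b)/(ln μ_f − ln μ_b)` (below/above-threshold means of the
minimum-shifted intensities) from the image mean to a 0.5-gray-level
tolerance, then snaps to the neighbouring discrete minimum of the exact
cross-entropy. The minimum shift makes the result exactly
shift-equivariant. Initializing at the mean follows the reference
implementations; we deliberately do **not** return the global minimizer of
the cross-entropy, because on contrast-enhanced noisy stacks the global
minimum can sit inside the background noise distribution. For
well-separated histograms whose background mode lies near the intensity
floor — the regime of thresholdable fluorescence data — the mean-initialized
fixed point and the global minimizer coincide (up to plateau ties where
several thresholds attain the same objective). The threshold is computed
once per 3D stack by default (`li_per_slice` switches to per-slice).

**Mask simplification.** Binary opening then closing with discrete disk
elements per z-slice (radii `opening_radius_px = 1`,
`closing_radius_px = 1`), the slice-wise behaviour of the standard binary
stack tools — a 3D ball at 1 μm axial spacing would erase every
single-slice-thick process. The opening is an *opening by partial
reconstruction*: after erosion–dilation, one conditional dilation inside
the original mask restores the one-pixel rims that a plain opening shaves
off 2–3-pixel-wide processes, while noise specks smaller than the element
stay removed. Components below `min_object_volume = 4` μm³ are then
discarded as specks.

**Soma detection.** The Phansalkar local threshold
`t(x) = m(x)(1 + p e^{−q m(x)} + k(s(x)/R − 1))` is evaluated per slice in
a disk of `phansalkar_radius_px = 20` pixels on intensities normalized to
[0, 1] by the stack maximum, with the algorithm's published constants
k = 0.25, p = 2, q = 10, R = 0.5. Voxels strictly above threshold are
opened in-plane with a 3 px disk (removing thin processes, which would
otherwise stay connected to the soma), grouped by 3D 26-connectivity and
volume-gated to 25–1500 μm³. The gates bracket the phantom somata
(radius 2.5–3.5 μm, flattened in z) after the detection opening; for real
data they are configuration parameters to re-examine.

**Instance separation.** A marker-controlled watershed floods the negated
Euclidean distance transform of the mask (physical-unit distances,
separable exact algorithm) from the detected soma voxel sets. Seeds enter
the priority queue in increasing soma id and equal-relief ties resolve by
insertion order, so the split is deterministic; on two overlapping spheres
the basin boundary is the midplane. Foreground components with no path to
any marker — detached dystrophic fragments and spheroids — are then
*adopted* by the nearest basin within `fragment_adoption_um = 6` μm;
without adoption the fragmentation and spheroid criteria could never fire,
because a flood can only reach connected voxels.

**Individual-cell filter.** Basins are rejected if they touch the stack
border, contain a number of somata different from one, or fall outside
100–20000 μm³ (bracketing ramified and deramified phantom cells; a
deramified cell is only ~140–230 μm³). Rejection reasons are recorded
per cell.

## Skeletonization and the skeleton graph

Thinning removes simple, non-endpoint border voxels in six directional
sub-iterations until stable, with the Bertrand–Malandain simple-point test
(one foreground 26-component in the 26-neighbourhood; one background
6-component in the 18-neighbourhood adjacent to the centre). Thinning works
on the voxel grid ignoring anisotropy, as the standard 3D skeletonization
tools do; lengths are computed physically afterwards. Voxels are classified
by 26-neighbourhood degree: 1 endpoint, 2 slab, ≥3 junction, 0 isolated.

The graph builder merges 26-adjacent junction voxels into single junction
nodes (cluster centroids), collapses every skeleton voxel inside the soma
radius into one soma node (so the soma's thinning residue does not inflate
the segment count), and traces edges through slab runs; edge length is the
sum of voxel-centre steps under the anisotropic spacing. Grid-scale
artifacts of thinning are then cleaned at the graph level:

* terminal spurs shorter than `prune_terminal_um = 1` μm are pruned, but a
  spur is never pruned if its anchoring junction would drop below degree 3
  — this preserves the second prong when a tip cap thins into a small fork;
* junction–junction connectors shorter than `merge_junction_um = 1.2` μm
  are contracted (one anatomical branch point can thin into two clusters a
  voxel apart);
* forked tips whose two endpoints nearly coincide are collapsed to the
  longer prong, parallel edges between one node pair (thinning ladders)
  keep the shorter edge, and degree-2 pass-through junctions are spliced.

The defaults differ from a no-cleanup baseline deliberately: at 0.3 × 1 μm
sampling every thinning algorithm leaves sub-micrometre spurs and split
junctions that are properties of the grid, not of the cell. Both scales are
configuration parameters. Sequential directional thinning is only
approximately equivariant under grid rotations; segment counts and longest
paths vary by a few percent when the volume is permuted, which the test
suite checks at that tolerance.

The longest path is the weighted graph diameter (maximum over components of
all-pairs shortest-path length).

## Sholl analysis

Branch counts are crossings of true Euclidean spheres in physical μm about
the soma centroid at radii `r = step, 2·step, …` with `sholl_step = 1` μm.
A crossing is a strict sign change of (radial distance − r) along an edge
polyline: an edge crossing a sphere several times contributes each
crossing, a polyline vertex exactly on the sphere does not interrupt a
crossing, and a tangency that touches without passing counts zero. The same
convention is used by the analytic tree oracle, so the two routes agree
exactly on ground-truth graphs. Slab/junction/endpoint densities per
spherical shell (counts divided by shell volume) are emitted alongside.

The per-cell area under the curve is the trapezoidal integral of the
branch-count curve from r = 0 (count defined as 0) to one step past the
last non-zero radius; AUC was chosen over density-curve integrals as the
primary scalar because it carries the units of the reported group
comparisons (branches·μm). The curve maximum and its radius are also
reported.

## Classification rules

The visual criteria for activation and dystrophy are operationalized as
explicit thresholds so results are reproducible; the mapping is an
interpretation, stated here and in the function documentation:

* **activated** ⟺ soma volume > `soma_volume_threshold` (200 μm³) **and**
  longest path < `process_length_threshold` (30 μm), both strict
  (hypertrophy with process shortening);
* **dystrophic** ⟺ at least one of: fragmentation (component count > 1),
  deramification (segment count < `deramification_threshold` = 12), or
  detached spheroids (compact components ≤ 65 μm³ with volume over
  bounding-sphere volume ≥ 0.2 — a sphericity surrogate that needs no
  surface meshing). Gnarling and beading have no measurable surrogate and
  are not operationalized.

The thresholds are calibrated on the phantom regimes (they separate the
planted young-like and aged-like labels with ≥ 90% balanced accuracy at the
default imaging conditions) and must be re-examined for real data. The
activation percentage is reported per field and averaged per animal, with a
warning when an animal has fewer than `min_fields_per_animal = 4` fields.

## Group statistics

Per-cell metrics are pooled by condition with sample ids retained (cells
are the statistical unit, as pooled; the sample id allows animal-level
re-aggregation). The omnibus test is Kruskal–Wallis with mid-rank ties and
the standard tie correction; the p-value always uses the chi-square
approximation with k − 1 degrees of freedom. At n = 10 per group that
approximation is slightly conservative (true null rejection ≈ 0.045 at
α = 0.05), a documented trade-off against exact small-sample tables.
Pairwise contrasts are Dunn z-statistics on pooled ranks with tie
correction; the default multiplicity adjustment is Holm–Šidák step-down
(`adjusted_(i) = max_{j≤i} 1 − (1 − p_(j))^{m−j+1}`), with classic
Bonferroni–Dunn selectable. Both procedures are provided because each is
standard for this kind of morphometric comparison; Holm–Šidák is the
default as the uniformly less conservative of the two.

## The phantom generator

The generator is the package's study-condition definition, not a
convenience fixture. A cell is a rooted tree: `n_primary` processes leave
the soma in mostly-lateral directions and grow as meandering polylines with
per-order radius taper (0.8 μm tapering by 0.85 per order, floored at
0.6 μm); at each segment end the process bifurcates with an order-specific
probability. The probabilities are solved at construction time from the
expected-tip recursion `E_o = (1 − p_o) + 2 p_o E_{o+1}` so that the mean
tip count equals the regime target. The four condition presets target
13.1, 8.4, 5.6 and 4.9 tips per cell — the reported magnitudes for young
naive, young inflamed, aged naive and aged inflamed microglia — with
segment lengths of 6 ± 1.5 μm (young-like) and 4.5 ± 1.2 μm (aged-like)
and somata of radius 2.5–3.5 μm. In aged-like regimes each distal segment
is independently rendered with a proximal gap of at least 2.4 μm with
probability 0.5 (fragmentation), so every fragmentation event adds one
connected component.

Rendering draws processes as tapered capsules and the soma as a flattened
ellipsoid into a 16-bit stack, blurs with an anisotropic Gaussian PSF
(σ = 0.15 μm in-plane, 0.6 μm axial), and adds Poisson shot noise plus
Gaussian read noise scaled so that (soma peak − background)/σ_read equals
the configured `snr` (default 12); `snr = Inf` disables both noise terms
and, with the PSF off, thresholding the render at background + ε recovers
the ground-truth mask voxel-exactly. Every terminal tip is capped with a
bulb of at least 1 μm radius: a growth-cone-like enlargement that also
guarantees a tip is at least one z-slice thick, so thinning always forms an
endpoint there.

Three phantom design choices matter for interpreting test results:

* **Self-avoidance.** Growing processes steer away from (and, failing
  that, stop short of) approaches closer than 2 μm to already-drawn
  processes, with z-differences down-weighted (axial voxelization inflates
  the rendered tube) and an extra 0.6 μm clearance demanded around segment
  ends, where terminal bulbs fuse sooner. A child branch that cannot be
  placed resolvably is retried in fresh directions and otherwise not
  drawn, its sibling spliced through the branch point. The ground-truth
  tree therefore *is* the rendered morphology. Real microglia processes
  can approach each other below the resolution of a 0.3 × 1 μm grid; on
  such data, touching processes will merge into shared skeleton branches,
  and the recovery rates measured on phantoms are upper bounds.
* **Calibration is in physical units only.** No pixel size is associated
  with the reported morphometric magnitudes being emulated, so regime
  calibration targets tips-per-cell counts, not pixel-level appearance.
* **What noise the phantoms do not contain:** autofluorescence structure,
  staining heterogeneity along processes, other labelled structures, or
  tissue-level intensity gradients. Passing tests demonstrate correctness
  of the measurement chain on resolvable morphologies, not robustness to
  every property of real tissue.

The master seed splits into per-cell seeds as
`(master + 7919 · i) mod (2^31 − 1)`, so cohorts are reproducible
cell-by-cell; every generator output is a pure function of (spec, seed).

## Degenerate inputs and tie-breaking

Constant images have no threshold (error); empty masks cannot be
skeletonized (error); empty graphs produce an all-zero Sholl profile with a
warning; somata outside the mask are rejected with a warning, and a field
with no usable marker yields an empty label map rather than a guess. All
values exactly at classification thresholds are non-activated /
non-dystrophic (strict inequalities). Watershed ties on equidistant ridges
resolve by seeding order (lowest soma id first); pure-cycle skeleton
components are anchored at their first voxel in scan order. Groups in which
every observation is identical give H = 0, p = 1 with a degenerate flag.

## Problem sizes used in validation

The packaged tests and the acceptance script validate on: 20 randomized
two-Gaussian histograms for the threshold oracle; 100 phantom trees for the
exact Sholl equivalence; 100 noiseless single-cell renders for topology
recovery (endpoints and segment counts within ±1 for at least 90% of
cells); 30 trees for the longest-path brute force; 10,000–20,000 null
simulations for Kruskal–Wallis calibration; and a 4 × 20-cell cohort at the
default imaging conditions for the end-to-end ordering and significance
pattern (young naive > young SI > aged conditions; omnibus p < 0.05; aged
naive vs aged SI nonsignificant after adjustment). These sizes give stable
Monte-Carlo estimates while keeping a full validation run to a few minutes
on one CPU.

## Known limitations

* Noisy renders positively bias segment counts (noise spurs survive the
  1 μm pruning scale); the bias is uniform across conditions, so group
  contrasts are unaffected, but absolute counts from noisy data should not
  be compared against noiseless ground truth.
* Thinning-based skeletons retract tips by roughly the local tube radius;
  longest paths are correspondingly conservative.
* The classification thresholds are phantom-calibrated interpretations of
  qualitative visual criteria; real-data use requires re-calibration
  against expert annotation.
* The chi-square omnibus approximation is conservative below n ≈ 10 per
  group.
* The CLAHE stage is only beneficial when slices contain structure;
  stacks dominated by empty background rely on the quasi-constant-slice
  bypass.
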