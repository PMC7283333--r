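---
title: "Models and methods behind nucleome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nucleome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleome)
```

`nucleome` implements the computational side of multiplexed FISH experiments
that jointly image chromatin traces, RNA species and nuclear landmarks in
tissue sections. This vignette explains the models and the numerical choices;
the README shows the worked example.

## The measurement model

A chromatin trace is the ordered set of 3D positions (nm) of probed genomic
regions in one chromosome copy. Loci may be missing: every pairwise statistic
in the package uses pairwise deletion and records, per entry, how many copies
contributed. Voxel indices are 0-based and the physical position of voxel
`(i, j, k)` is `(i, j, k) * voxel_size`; the default voxel pitch is
107.9 nm laterally and 200 nm axially, so thresholds stated in nm
(150 nm contacts, 200 nm associations) apply directly and both thresholds are
strict (`<`): a pair at exactly 150.0 nm is not a contact.

## Image operators

* **Cell segmentation** (`segment_cells`): the membrane channel is z-averaged,
  min-max normalized, lightly denoised (Gaussian, sigma 1 px), divided by an
  adaptive local-mean background (sensitivity 0.1, 41 px neighborhood),
  clipped at the 1st/99th intensity percentiles, morphologically closed (disk
  radius 15 px) and watershed-transformed on the inverted image, so that cell
  interiors become basins. Segments with area outside the open interval
  (2500, 20000) px or touching the field edge are flagged and excluded from
  analysis. The "adaptive background" used throughout is pinned as a
  box-filter local mean scaled by `1.5 - sensitivity`; the literature this
  pipeline descends from names sensitivity values but not the underlying
  local statistic, so the mapping is fixed here for reproducibility.
* **Nuclear-edge mask** (`nuclear_edge_mask`): per plane, background-divided
  and quartile-clipped intensity is cleaned by opening-by-reconstruction,
  then the 2D gradient magnitude is smoothed (sigma 5 px) and adaptively
  binarized. Two numerical guards matter on clean synthetic input: quartile
  clipping falls back to full-range rescaling when the interquartile window
  is numerically degenerate, and the binarization requires the gradient to
  exceed 10% of the plane maximum so FFT round-off in flat regions cannot
  binarize. Opening-by-reconstruction erases any object whose cross-section
  is smaller than its brush; the default radius (25 px) suits full-scale
  nuclei, and smaller phantoms should scale it down (the tests use 10 px).
* **Nucleolus mask** (`nucleolus_mask`): one adaptive threshold profile is
  derived from the median-filtered maximum projection and applied to every
  median-filtered plane after normalization by the stored projection
  maximum, with a small absolute floor against numerical noise.
* **Spot fitting** (`fit_spots_3d`): least-squares 3D Gaussian (isotropic in
  xy) plus constant background in a local window, via
  Levenberg–Marquardt. A fit fails when the window is clipped too small, the
  optimizer diverges, or the amplitude does not exceed the background.
* **Drift correction** (`estimate_drift`): fiducial beads are detected per
  round, coarsely aligned to the reference round by integer
  cross-correlation, matched by nearest neighbor within 5 px, and the
  per-round offset is the median bead displacement — robust to individual
  mismatches. Beads are fit in 2D for decoding and 3D for tracing.
* **Trace linking** (`link_traces`): within a nucleus, positions are
  agglomerated by single linkage and cut at 1.5 times the expected territory
  radius (default 1500 nm), capped at the two clusters expected of a diploid
  nucleus (largest two kept, ties broken by fit amplitude); each trace keeps
  at most one position per readout, brightest first. The linkage rule is a
  design choice of this package: only "spatial clustering" is prescribed by
  the source methods, so the cutoff and the two-cluster cap are documented
  here as the departure point.

## Barcode decoding

RNA species carry 16-bit barcodes of Hamming weight 4 and pairwise distance
at least 4 (`validate_codebook` checks both, naming offenders). Each round is
binarized per plane: morphological-opening background (disk radius 5 px) is
subtracted, regional maxima above an intensity threshold are kept, and the
binary image is dilated by a 3x3 square. Per voxel, the 16-bit word across
rounds is matched exactly against the codebook; optional single-bit
correction accepts words at Hamming distance 1 from a unique codeword and is
off by default, because exact matching is the reference behavior of the
pipeline this reimplements. Same-gene pixels merge within a z-plane
(8-connectivity, never across planes). Threshold calibration
(`calibrate_thresholds`) screens 20 log-spaced values between the 90th and
99.9th intensity percentile per round, initialized so per-round on-pixel
loads match the codebook-predicted loading from reference abundances, then
coordinate-ascends the log-scale Pearson correlation between decoded totals
and the reference. The two published calibration criteria (round loading,
count correlation) have no stated precedence; here loading initializes and
correlation decides.

Per-cell counting erodes each cell by a 3 px disk before assigning molecules
(boundary molecules stay unassigned), and flags cells with area outside
(2500, 20000) px, touching the edge, or with fewer than 10 molecules.

## Distance matrices and compartment scores

`mean_distance_matrix` averages pairwise Euclidean distances over informative
copies; `contact_probability` is the fraction of informative copies closer
than the threshold. `compartment_scores` follows the imaging analogue of the
Hi-C compartment call: fit `distance = A * genomic^k` by ordinary least
squares in log–log space (diagonal excluded; genomic distance between region
midpoints), normalize the observed matrix by the expectation, take the
Pearson correlation matrix between its rows, and extract the first principal
component of that correlation matrix (columns as variables, mean-centered —
the matrix is symmetric, so the rows-versus-columns choice is immaterial and
asserted by test). The unit-norm coefficients are the compartment scores,
sign-oriented so that they correlate positively with gene density: positive
scores are compartment A. The whole construction is invariant to a global
rescaling of distances, which the amplitude absorbs.

`min_pairs` defaults to 20 for full-scale data and the tests use 2–5 on small
phantoms; entries below it are treated as missing, and compartment scoring
refuses matrices with missing off-diagonal entries rather than imputing.

## Single-chromosome architecture metrics

The **polarization index** of one chromosome copy is
`PI = sqrt((1 - V_S/V_A)(1 - V_S/V_B))`, with `V_A`, `V_B` the volumes of the
convex hulls of the A- and B-compartment loci and `V_S` their intersection
volume: 1 means fully side-by-side, 0 means coincident or nested hulls. The
hull engine is an incremental quickhull; the intersection volume is computed
exactly by hulling the candidate vertex set (vertices of either hull inside
the other plus edge–facet crossing points), with a seeded uniform-sampling
estimator (200,000 samples, fixed internal seed) as cross-check and fallback
for numerically degenerate intersections — both engines agree to better than
1% on analytic box overlaps. Groups need at least 4 non-coplanar loci;
degenerate copies are excluded with a reason, never silently imputed.
Randomization controls permute compartment labels across loci while
preserving the number per compartment, and observed-versus-control
distributions are compared with a two-sided Wilcoxon rank-sum test.

Association ratios call a locus "associated" when its distance to the nearest
TRUE mask voxel center is strictly below 200 nm, computed against voxel
centers with the anisotropic physical spacing. Chromosome-level B-compartment
association uses the any-B rule: a copy's compartment B is associated if any
of its B loci is. Chromosome-surface calls mark a locus as surface-exposed
when it is a vertex of the convex hull of all detected loci of its copy —
extreme points only; a point lying inside a facet is interior.

## The lattice polymer model

A chromosome is a self-avoiding chain of 50 monomers on the integer lattice,
with consecutive monomers at Euclidean distance in [1, 4] (the lower bound is
vacuous for distinct integer sites). Each monomer carries a compartment
score; positive scores are A. The interaction energy as conventionally
printed is

```
E = sum_{AA contacts} g_aa S_i S_j + sum_{BB contacts} g_bb S_p S_q
  + sum_{A on surface} g_as (S_m - mean S_A)
  + sum_{B on surface} g_bs (mean S_B - S_n)
```

with contacts = same-compartment pairs strictly closer than 2 lattice units
(squared distances 1, 2, 3; Euclidean, the default reading of "closer
than 2") and surface = hull-vertex monomers of the whole chain. Taken
literally, minimizing this expression would make the described interactions
repulsive, contradicting the intended physics (B monomers *favoring* B
neighbors, i.e. an energy decrease per contact). The package therefore
defaults to `sign_mode = "attractive"`, minimizing the negation of the
printed expression — equivalently accepting when `p < exp(E_new - E_now)` on
the printed energy — and retains `"as_printed"` for comparison. Only the
attractive convention reproduces the documented qualitative outcomes of the
three presets.

Moves pick a uniform monomer and one of its six axis neighbors; proposals
that collide or break a bond are abandoned without Metropolis evaluation and
do not count toward the accepted-move budget. Runs simulate 60,000 accepted
moves; ensembles are 100 independent runs seeded `base_seed + run`. Pair
terms are bookkept incrementally and re-verified against a full recomputation
at the end of every run (tolerance 1e-9, enforced in compiled code); the
surface term is recomputed per evaluated proposal via the hull engine.
Presets: `bb_only` (0, 50, 0, 0), `aa_bb` (50, 50, 0, 0), `full`
(50, 50, 40, 25) for `(g_aa, g_bb, g_as, g_bs)`.

Under the synthetic score profile below, the trailing 10,000 accepted moves
still carry a small residual drift in ensemble-mean energy (about 5% for
`aa_bb`); runs flatten by roughly 150,000 moves. The 60,000-move budget is
kept as the reference condition, and `equilibration_trend` (block-mean trend
test) is provided as the diagnostic.

## What the synthetic data emulate — and what they do not

* `gen_scene` builds a packed monolayer: cells are Voronoi tiles of jittered
  grid centers separated by thin bright membrane walls inside a tissue rim,
  each with an ellipsoidal nucleus and one or two nucleoli strictly inside
  it. Photon levels (background 20, membrane 150, nucleus 100, nucleolus 200
  counts) with Poisson shot noise mimic realistic camera counts. Not
  emulated: optical aberrations, bleed-through, autofluorescence, 3D cell
  overlap.
* `gen_traces` samples loci as fractional Brownian motion per axis, whose
  Hurst index is exactly the planted distance-scaling exponent (default
  0.33), with adjacent-locus mean distance 350 nm; compartment polarization
  displaces positive- and negative-score loci in opposite directions along a
  random axis (centroid separation up to 1200 nm); localization noise is
  isotropic Gaussian (sigma 50 nm, the scale of FISH fitting precision) and
  loci drop out uniformly at 10%. Real chromosomes are not Gaussian
  processes; what passing tests show is that the estimators recover planted
  first- and second-order structure, not that they certify real data.
* `gen_merfish_stacks` renders molecules as 3D Gaussians in exactly the four
  on-bit rounds, plus drifting fiducial beads. A diffraction-limited spot
  spans neighboring z-planes, and decoding is per-plane by design, so a
  molecule may be counted once per plane it is visible in; counting tests
  plant single-plane spots.
* `planted_block_scores` is the synthetic stand-in for a measured
  compartment-score profile: a unit-norm vector with 13 alternating A/B
  blocks whose magnitudes dip to a 0.12 floor at block boundaries. It was
  designed so the polymer model reproduces the qualitative preset regimes
  (radial organization under B-B only, polarized under A-A + B-B,
  strengthened polarization with surface couplings); the partial-separation
  regime of `aa_bb` is the most sensitive to the exact profile.

## Problem sizes and determinism

Tests and the acceptance script use 512x512x6 scenes (9 cells), 100–250
traced copies of 30–50 loci, 256x256x3 decoding phantoms with 500 molecules,
and polymer ensembles of 100 runs x 60,000 accepted moves. Every generator
and the Monte Carlo engine are pure functions of their seed arguments (the
engine draws from R's RNG stream), so identical seeds give bit-identical
outputs; the Monte Carlo intersection-volume fallback carries its own fixed
seed so the polarization index is deterministic.

## Known limitations

* Trace linking assumes at most two chromosome copies per nucleus and a
  roughly known territory radius.
* Decoding merges molecules within, never across, z-planes.
* The hull-based surface definition counts only extreme points; loci exactly
  on a facet interior are classified as interior.
* Compartment scoring requires a complete distance matrix after the
  `min_pairs` filter and at least some deviation from the fitted power law.
* The polymer model is a minimal, dimensionless lattice description: no
  loop extrusion, no excluded-volume beyond single-site occupancy, chain
  length fixed at the number of scored regions.
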