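# nucleome

Analytics for multiplexed imaging of nucleome architecture in single cells.
Experiments of this kind trace the 3D folding of a chromosome (sequential
DNA-FISH of dozens of loci), count RNA molecules of >100 species via 16-bit
combinatorial barcodes (MERFISH-style), and image nuclei, nucleoli and cell
boundaries — all in the same tissue section. `nucleome` provides the
computational chain from raw z-stacks to biology:

* **Imaging**: watershed cell segmentation from a membrane stain,
  nuclear-edge and nucleolus voxel masks, sub-voxel 3D Gaussian spot fitting,
  fiducial-bead drift correction, and linking of locus positions into
  per-chromosome traces.
* **Decoding**: validation of weight-4 / minimum-Hamming-distance-4
  codebooks, per-round image binarization, pixel-based barcode decoding with
  optional single-bit error correction, adaptive threshold calibration
  against reference abundances, and QC-flagged per-cell expression counting.
* **Tracing statistics**: mean spatial-distance matrices with pairwise
  deletion, contact probabilities (strict 150 nm threshold), length-normalized
  Hi-C contact frequencies, power-law fits, and A/B **compartment scores** —
  the unit-norm first-principal-component coefficients of the Pearson
  correlation matrix of the expectation-normalized distance matrix, oriented
  so compartment A (positive scores) correlates positively with gene density.
* **Architecture**: the convex-hull **polarization index**
  `PI = sqrt((1 - V_S/V_A)(1 - V_S/V_B))` of the A/B compartments of a single
  chromosome copy, label-randomized controls with rank-sum tests, lamina and
  nucleolar association ratios (strict 200 nm to the nearest mask voxel
  center), chromosome-surface ratios (hull-vertex membership), and the
  A-to-B axis projection.
* **Polymer model**: Metropolis Monte Carlo of a 50-monomer self-avoiding
  lattice chain with compartment-score-weighted A-A / B-B contact energies
  and A-surface / B-surface couplings, with named presets (`bb_only`,
  `aa_bb`, `full`) and ensemble summaries (polarization medians, score vs
  surface-ratio correlations).
* **Phantoms**: seeded generators for tissue scenes, chromatin traces with
  planted power-law scaling and polarization, barcode image stacks and
  synthetic Hi-C counts, so every stage is testable against ground truth.

The compute-heavy geometry (incremental quickhull, exact hull-intersection
volumes) and the Monte Carlo engine are in C++ (Rcpp).

## Worked example

```r
library(nucleome)

# a phantom tissue scene with 9 cells, and its segmentation
scene  <- gen_scene(9, fov_shape = c(512L, 512L, 6L), seed = 1)
labels <- segment_cells(scene$stacks$membrane)
labels
#> <cell_label_map> 10 labels (9 retained, 1 excluded)
segmentation_jaccard(labels, scene$truth$label_map)$jaccard |> round(2)
#> [1] 0.95 0.95 0.95 0.95 0.92 0.94 0.96 0.95 0.95

# traces with planted compartment structure -> compartment scores
scores <- planted_block_scores(50)
traces <- gen_traces(150, scores, polarization_strength = 1, seed = 16)
dm     <- mean_distance_matrix(traces, min_pairs = 5)
cr     <- compartment_scores(dm, synthetic_regions(50))
cr
#> <compartment_result> 50 regions (25 A / 25 B), distance ~ genomic^0.21 [sign not oriented: no gene density]

# polarization of single chromosome copies vs label-randomized control
rp <- randomized_polarization(traces, scores, seed = 1)
c(observed = median(rp$observed$pi), control = median(rp$control$pi))
#> observed  control
#>    1.000    0.314

# the lattice polymer model, full preset
ens <- simulate_ensemble(scores, "full", n_runs = 20,
                         n_accepted = 60000, base_seed = 1)
glance(ens)[, c("median_pi", "median_pi_control",
                "r_score_surface_a", "r_score_surface_b")]
#> # A tibble: 1 × 4
#>   median_pi median_pi_control r_score_surface_a r_score_surface_b
#>       <dbl>             <dbl>             <dbl>             <dbl>
#> 1     0.764             0.311             0.862            -0.807
```

The polarization index runs from 0 (compartments coincident or nested) to 1
(fully side-by-side); planted fully-polarized traces reach PI 1 while their
label-shuffled controls sit near 0.3-0.4. In the polymer ensemble the `full`
preset yields polarized conformations whose strong-A monomers sit on
the chromosome surface (positive score/surface correlation) while strong-B
monomers avoid it. Results shown were produced by the code above.

Result objects are tibble-friendly: `tidy()` gives long per-observation
tables, `glance()` one-row summaries, and `autoplot()` /
`plot_surface_vs_score()` standard ggplot figures. A thin command-line
wrapper lives in `exec/nucleome` (`simulate`, `decode`, `architecture`,
`pipeline` subcommands), and `pipeline_run()` chains the stages on a phantom
scene with per-stage manifests.

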