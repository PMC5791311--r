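# migmorph — automated 3D microglia morphometry

Microglia shift between a surveillant state (small soma, long, highly
ramified processes) and activated or dystrophic states (hypertrophic soma
with retracted processes; deramification, fragmentation, cytoplasmic
spheroids). Quantifying that shift from Iba1-stained confocal Z-stacks by
hand is slow and rater-dependent. `migmorph` implements an automated 3D
morphometry pipeline for single-channel confocal stacks, aimed at
neuroimmunology labs comparing microglial ramification across experimental
groups (e.g. young vs aged, naive vs inflamed).

## What the pipeline computes

For a stack *I(z, y, x)* with voxel spacing *(dz, dy, dx)* in μm:

1. **Segmentation** — slice-wise CLAHE contrast enhancement; a global
   threshold *t* by Li's minimum-cross-entropy iteration
   *t ← (μ_f − μ_b)/(ln μ_f − ln μ_b)*; slice-wise open/close mask
   simplification; soma detection by the Phansalkar local threshold
   *t(x) = m(x)(1 + p·e^(−q·m(x)) + k(s(x)/R − 1))* at radius 20 px;
   marker-controlled 3D watershed on the negated Euclidean distance
   transform splits touching cells; only individual, complete cells are
   kept.
2. **Skeletonization** — topology-preserving 3D thinning; skeleton voxels
   labelled slab / junction / endpoint by their 26-neighbourhood degree
   (2 / ≥3 / 1); a physical-unit skeleton graph with per-cell segment
   count, component count and longest path (weighted graph diameter).
3. **Sholl analysis** — branch counts *N(r)* crossing concentric spheres at
   a 1 μm radial step from the soma, per-class densities per shell, the
   trapezoidal area under *N(r)* (AUC, branches·μm), and the curve maximum.
4. **Classification** — activated iff soma volume > threshold and longest
   path < threshold; dystrophic iff fragmentation (≥2 components),
   deramification (segment count below threshold) or detached spheroids.
5. **Group statistics** — per-cell metrics pooled by condition (3–7 cells
   per sample), Kruskal–Wallis omnibus, Dunn pairwise z-tests with
   Holm–Šidák step-down (or Bonferroni) adjustment, mean ± SEM summaries.

A synthetic-data module generates ground-truth branching cells ("young-like"
highly ramified, "aged-like" deramified and fragmented), rasterizes them
into confocal-like stacks (anisotropic voxels, PSF blur, Poisson + Gaussian
noise), and provides exact analytic oracles (Sholl crossings, tree
topology, longest path), so the whole pipeline is testable without
microscopy data.

## Worked example

```r
library(migmorph)

spec <- phantom_spec("young_like")   # ramified regime, calibrated branching
tree <- generate_cell_tree(spec, seed = 21)
tree
#> cell_tree [young_like]: 28 segments, 16 tips, 12 junctions, soma r 3.29 um

ras <- rasterize_cell(tree, spec, seed = 22)   # confocal-like noisy stack
res <- run_pipeline(ras$stack, pipeline_config(), field_id = "demo")
res
#> pipeline_result: 1 accepted cell(s)
#>      cell_id segment_count sholl_auc max_branches longest_path activated dystrophic
#> 1 demo_cell1            39       128           13     58.36753     FALSE      FALSE

res$profiles[[1]]
#> sholl_profile: step 1 um, 24 radii, max 13 branches at 10 um, AUC 128.0
```

The accepted cell's skeleton has 39 segments (the ground-truth tree has 28;
noise adds short spur branches, a positive bias that is uniform across
conditions), a Sholl AUC of 128 branches·μm with at most 13 simultaneous
branches at 10 μm from the soma, and a 58 μm longest path. Neither the
activation rule (soma 140 μm³ is below the 200 μm³ hypertrophy cutoff and
the 58 μm longest path is far above the 30 μm shortening cutoff) nor any
dystrophy feature fires, so the cell is classified as surveillant — as
planted.

Cohort-level analysis:

```r
coh <- generate_cohort(cohort_conditions(), n_cells = 20, out_dir = "sim", master_seed = 1)
res <- analyze_cohort(read.csv("sim/manifest.csv"), pipeline_config())
res$stats      # Kruskal-Wallis + Holm-Sidak pairwise tables per metric
```

A command-line front end is installed with the package
(`system.file("cli", "migmorph", package = "migmorph")`) with subcommands
`simulate`, `run`, `sholl`, `stats`.

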