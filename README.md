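# azstorm

Eye-specific synapse detection and spatial analysis for volumetric
super-resolution (serial-section STORM) imaging of the developing visual
thalamus.

## What it does

During the first postnatal week, retinal ganglion cell axons from the two
eyes compete for territory in the dorsal lateral geniculate nucleus (dLGN).
Four-channel STORM volumes of this tissue — Homer1 (postsynaptic density),
Bassoon (presynaptic active zone, AZ), VGluT2 (retinal vesicle pool), and CTB
(an anterograde tracer marking the injected eye) — resolve individual release
sites at ~15.5 nm lateral / 70 nm axial voxels. `azstorm` turns such aligned
voxel stacks into biology:

* **Segmentation** — per-section histogram normalization, two-level Otsu
  thresholding (three intensity classes; exhaustive maximization of
  between-class variance), anisotropic 3D connected components, watershed
  splitting of fused clusters, cell-body exclusion, and a CTB convex-hull
  neuropil mask.
* **Synapse identification** — the retinogeniculate *input* is one contiguous
  VGluT2 vesicle cluster plus all of its Bassoon/Homer1 release-site pairs.
  Homer1 and Bassoon clusters are paired by OPTICS density clustering in
  (centroid distance, 140-nm-shell intensity) feature space; paired AZs are
  associated to the VGluT2 cluster whose 140-nm surface shell contains their
  weighted centroid. Inputs with one AZ are **sAZ** synapses, with 2–4 AZs
  **mAZ** inputs; CTB-paired inputs are **dominant-eye**. VGluT2 volume
  within 70 nm of each AZ is the docked-vesicle proxy.
* **Spatial analysis** — counts of like-eye sAZ neighbors within expansion
  shells (1–4 µm, measured from the cluster surface to neighbor centroids),
  clustered/isolated labels at the 1.5-µm cutoff, nearest-clustered-mAZ
  distances, near/far sAZ classes, and a position-shuffled null model (sAZ
  centroids resampled uniformly over the neuropil) with empirical p-values.
* **Statistics** — replicate-level paired t-tests with Cohen's d, two-sample
  Kolmogorov–Smirnov tests with rank epsilon-squared, and Benjamini–Hochberg
  FDR control within condition families (α = 0.05).
* **Synthetic scenes** — a first-class generator
  (`generate_scene`/`render_volume`) that plants ground-truth inputs with
  Poisson class/eye counts, linear vesicle-volume scaling
  (volume = AZ count × volume-per-AZ), like-eye clustering, imperfect tracer
  labeling, cell bodies and background labels, and renders them to the same
  four-channel voxel format — so the whole chain is testable without the
  multi-terabyte raw image deposits.

The methods vignette (`vignettes/methods.Rmd`) describes the model,
parameters, numerical conventions, generator realism and limitations.

## Worked example

Simulate a ~40 × 40 × 4.2 µm field (512 × 512 × 60 voxels at 78 nm / 70 nm)
at the default study conditions and run the full pipeline with a 200-iteration
shuffle null:

```r
library(azstorm)
geom <- imaging_geometry(c(512, 512, 60), voxel_xy = 78, voxel_z = 70)
cfg  <- run_config(geom, scene = scene_params(), n_iterations = 200, seed = 42)
run  <- run_pipeline(cfg)
print(run)
```

```
azstorm pipeline run
  neuropil volume: 4885.9 um^3
  clusters: homer1 245, bassoon 245, vglut2 154, ctb 100
  inputs: 154 (61 mAZ / 93 sAZ; 100 dominant-eye)
  clustered at 1.5 um: 50 of 154
```

154 retinogeniculate inputs were assembled from 245 Homer1/Bassoon release
sites; 100 carried tracer (dominant eye). Group summaries give eye-specific
densities over the neuropil volume and per-class vesicle pools:

```r
run$group_summary[, c("eye", "input_class", "n", "density_per_um3",
                      "median_vesicle_volume_um3", "mean_az_count")]
#            eye input_class  n density_per_um3 median_vesicle_volume_um3 mean_az_count
# 1 non_dominant         mAZ 23          0.0047                      0.26           2.5
# 2 non_dominant         sAZ 31          0.0063                      0.12           1.0
# 3     dominant         mAZ 38          0.0078                      0.26           2.3
# 4     dominant         sAZ 62          0.0127                      0.12           1.0
```

mAZ inputs carry ~2.5 release sites and vesicle pools roughly 2× the sAZ
median — the linear volume-per-AZ scaling the generator plants and the
pipeline recovers. The shuffle null shows the planted like-eye clustering:

```r
run$null_ensemble$summary[, c("radius_um", "observed_clustered_fraction",
                              "null_mean", "p_empirical")]
#   radius_um observed_clustered_fraction null_mean p_empirical
# 1       1.0                       0.098      0.11       0.657
# 2       1.5                       0.541      0.23       0.005
# 3       2.0                       0.672      0.37       0.005
# 4       3.0                       0.787      0.63       0.005
# 5       4.0                       0.902      0.80       0.025
```

At the 1.5-µm cutoff, 54% of mAZ inputs have a like-eye sAZ neighbor versus
23% under position shuffling (empirical p = 0.005) — the excess is largest in
the 1.5–2 µm window, as expected when half of sAZ synapses are placed near a
like-eye mAZ input. Tables (inputs, active zones, clustering records, null
summary, group summary) and a JSON manifest with all data-driven thresholds
are written by `run_pipeline(cfg, out_dir = ...)` or `write_tables()`; ground
truth for scoring comes from `run$scene` via `match_ground_truth()`.

Real volumes enter through `read_volume_tiff()` (one multi-page 8-bit TIFF
per channel plus a `geometry.json` sidecar) and take the identical code path.
A thin command-line wrapper lives at `inst/cli/azstorm.R`.

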