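---
title: "Detecting and classifying eye-specific retinogeniculate synapses in volumetric STORM stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying eye-specific retinogeniculate synapses in volumetric STORM stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

During the first postnatal week, retinal ganglion cell axons from the two
eyes compete for territory in the dorsal lateral geniculate nucleus (dLGN).
Serial-section STORM imaging of this tissue yields aligned four-channel 8-bit
voxel volumes — Homer1 (postsynaptic density), Bassoon (presynaptic active
zone, AZ), VGluT2 (retinal vesicle pool), and CTB (an anterograde tracer
injected into one eye) — at roughly 15.5 nm lateral and 70 nm axial
resolution. The unit of analysis is the *retinogeniculate input*: one
contiguous VGluT2 vesicle cluster together with all of its paired
Bassoon/Homer1 release sites. Inputs with a single AZ are *sAZ synapses*;
inputs whose vesicle cloud serves two to four AZs are *mAZ inputs*. CTB(+)
vesicle clusters belong to the injected ("dominant") eye.

`azstorm` implements the full chain from voxels to statistics:

1. per-section histogram normalization and two-level Otsu segmentation with
   anisotropic watershed splitting (`normalize_section_histograms`,
   `two_level_otsu`, `detect_clusters`, `split_touching_clusters`);
2. cell-body exclusion and a CTB-derived neuropil mask
   (`cell_body_mask`, `neuropil_mask`);
3. separation of synaptic clusters from non-specific labels in
   (log volume, signal density) space (`select_synaptic_population`);
4. OPTICS-based pre/postsynaptic pairing and CTB eye assignment
   (`compute_pair_features`, `select_pairs`, `assign_eye`);
5. AZ-to-vesicle-cloud association within a 140-nm surface shell, sAZ/mAZ
   classification and docked-vesicle quantification (`associate_azs`,
   `classify_inputs`, `docked_vesicle_volume`);
6. expansion-shell clustering analysis against a position-shuffled null
   (`shell_neighbor_counts`, `label_clustered`, `shuffle_null`,
   `nearest_clustered_maz_distance`, `near_far_saz`);
7. replicate-level paired statistics with Benjamini-Hochberg FDR control
   (`paired_t`, `ks_two_sample`, `bh_fdr`, `replicate_summary`,
   `eye_paired_tests`).

Because the raw imaging volumes are multi-terabyte archive deposits, the
package ships a synthetic scene generator (`generate_scene`,
`render_volume`) that emulates the statistical structure the analysis
assumes, so every stage is testable end to end on a laptop.

## Segmentation model

All length scales are physical. Gaussian kernels and distances are specified
in nanometers and converted per axis (`sigma_voxels = sigma_nm /
voxel_size_axis`), so the anisotropy of serial sections (e.g. 15.5 nm
laterally vs 70 nm axially) is respected everywhere, including the distance
transform, the watershed, and all shells.

Per channel, `detect_clusters` applies, in order: (1) cell-body exclusion;
(2) a background filter keeping voxels above the *lower* two-level Otsu
threshold of the channel's conventional-image counterpart; (3) Gaussian
smoothing at 77.5 nm and binarization at the *higher* two-level Otsu
threshold; (4) 3D connected components (26-connectivity); (5) watershed
splitting of oversized components; (6) removal of clusters spanning fewer
than two physical sections; (7) removal of clusters touching the volume
border. Cluster volume, total intensity, signal density (fraction of
in-cluster voxels with positive raw intensity) and the intensity-weighted
centroid are measured on the raw pre-smoothing image.

`two_level_otsu` maximizes three-class between-class variance by exhaustive
search over threshold pairs on a 256-level histogram. For non-8-bit inputs
the histogram is binned over `[0, max]`; thresholds are returned in intensity
units. Degenerate histograms (fewer than three occupied levels) are an
error, surfaced to callers as an empty segmentation.

Cell bodies are detected on the Homer1 channel (they accumulate non-specific
label) after 140-nm smoothing, as connected components above a size cutoff.
The cutoff's default derives from a 3 um^3 physical volume: synaptic
clusters are well below ~1 um^3 and cell bodies (~10 um radius scale in
tissue, several um even when clipped by the volume border) are far above, so
the filter is insensitive to the exact value — a property the test suite
checks by sweeping the threshold over an order of magnitude. A voxel-count
override (`cellbody_min_voxels`) is exposed for users who prefer the raw
knob.

The neuropil mask — the region all densities and the shuffle null refer to —
is the per-z-plane convex hull of thresholded CTB signal minus detected cell
bodies. The tracer fills the labeled projection's neuropil, so its hull
delimits the analyzable territory.

**Watershed splitting.** Improperly merged clusters are split by
marker-controlled watershed on the anisotropic Euclidean distance transform
of the component mask. Markers are distance maxima at least 200 nm apart;
because a smooth elongated blob can carry several spurious maxima along its
ridge, fragments whose shared watershed line is deep (more than 0.6 of the
shallower fragment's peak interior distance) are merged back. A dumbbell
splits at its neck; a convex blob survives intact. The split is applied only
to components above the 99th volume percentile (or a configured absolute
volume), since "oversized" is scale-dependent. The paper trail does not say
whether the original analysis ran watershed on intensity or distance; the
distance transform is used here as the better-conditioned choice for
near-binary masks.

**Synaptic population selection.** True synaptic structures form a
population of larger, denser clusters in (log10 volume, signal density)
space; sparse non-specific labels are small and dim. The automatic gate fits
a two-component Gaussian mixture (via mclust) and keeps the component that is
distinctly greater on *both* axes (at least 0.3 decades of volume and 0.08 of
signal density). When the two components do not separate on both axes — for
example in noise-free renders where every cluster has signal density 1, or
when a mixture split reflects AZ-number structure rather than background —
all clusters are kept with a warning and downstream pairing provides the
specificity. A manual polygon gate is available for users who prefer the
original interactive workflow; repeated runs are deterministic either way.

## Pairing and input assembly

For every cluster of one synaptic channel, `compute_pair_features` records
the centroid distance to its nearest opposing-channel cluster and the mean
opposing-channel raw intensity within a 140-nm shell around the cluster's
surface (surface-based, consistent with the AZ-association shell; the
cluster's own voxels are excluded). Genuinely apposed Bassoon/Homer1
partners sit at tens of nanometers with bright shells; unpartnered clusters
sit at hundreds to thousands of nanometers with background-level shells.

`select_pairs` orders the standardized features with OPTICS (`min_samples =
5`) and extracts density components by the xi method (`xi = 0.05`). A
component is labeled *paired* when its median centroid distance is within
1.5x the shell scale and its median shell intensity is positive — the
physical signature of apposition; points unreachable at the chosen xi stay
unpaired. Two fallbacks keep small inputs well defined: with fewer than
`min_samples` features, or when no component carries the apposition
signature, pairing falls back to the hard rule
(distance <= 140 nm and positive shell intensity), with a warning. Pairing is
reconciled one-to-one: when two clusters claim the same partner, the smaller
centroid distance wins and the loser re-queries its next-nearest free
partner, kept only if it is no farther than the largest winning distance.

Eye assignment applies the same machinery to (VGluT2, CTB): tracer-paired
vesicle clusters are dominant-eye inputs, the rest non-dominant.

Bassoon clusters that survived Homer1 pairing are the active zones. Each is
associated to a VGluT2 cluster when its weighted centroid falls within a
140-nm shell extended from the cluster's surface voxels (centroid-in-shell
membership, the convention the source analysis states explicitly for the
clustering search; a voxel-overlap alternative was considered and rejected
for consistency). An AZ within reach of two vesicle clouds is assigned to
the nearer surface, so no AZ inflates two inputs. VGluT2 clusters with no
associated AZ are not retinogeniculate inputs and are dropped; inputs with
more than four AZs are kept but flagged. The docked-vesicle proxy is the
volume of binarized VGluT2 within 70 nm of each AZ's surface, including
voxels overlapping the AZ cluster itself (the conservative reading of an
ambiguous convention; the alternative differs only by the tiny AZ-interior
overlap).

## Spatial analysis and the shuffle null

The clustering analysis measures, for each center input and search radius
(1 to 4 um), the number of like-eye sAZ synapses whose VGluT2 weighted
centroid lies within the radius of the center's cluster surface — the
asymmetric surface-to-centroid rule. At the 1.5-um cutoff an input with at
least one such neighbor is *clustered*, otherwise *isolated*. The same
convention serves the distance from each mAZ input to its nearest like-eye
clustered mAZ, and the near/far (<= 1.5 um, boundary inclusive)
classification of sAZ synapses relative to mAZ inputs.

`shuffle_null` holds centers fixed and resamples every sAZ centroid
uniformly over neuropil-mask voxels (with sub-voxel jitter; shuffled
positions are points, not re-rendered clusters — the minimal faithful
reading of shuffling "positions"). Each iteration preserves the observed
sAZ count; summaries report the null mean, SD, central 95% band and the
empirical p-value `(1 + #(null >= observed)) / (1 + iterations)`, which never
returns an exact zero at finite iterations. The default 1000 iterations is a
configuration choice. Calibration is verifiable in closed form: for
complete spatial randomness at intensity lambda and point-like centers, the
clustered fraction at radius r is `1 - exp(-lambda * 4/3 * pi * r^3)`
(about 0.507 at lambda = 0.05 per um^3 and r = 1.5 um), and the test suite
checks both this value and that CSR data fall inside the null band at every
radius. Uniform resampling does not exclude positions overlapping existing
clusters; at realistic densities the overlap probability is a fraction of a
percent and does not measurably bias the band.

## Replicate statistics

Biological conclusions rest on N = 3 replicates per condition, so the
package reduces per-input tables to one value per (replicate, measurement,
arm) — densities over the neuropil volume, mAZ fractions, median vesicle
volumes, mean AZ counts, volume per AZ, clustered fractions, mean nearby-sAZ
counts — and compares eyes within replicates by two-tailed paired t-tests
(Cohen's d on the within-replicate differences, 5/95% confidence interval of
the mean difference). Cumulative distributions are compared by two-sample
Kolmogorov-Smirnov tests with the asymptotic p-value and a rank-based
epsilon-squared effect size (`H / ((n^2 - 1)/(n + 1))`, the standard rank
formulation, since the source names the measure without a formula).
Benjamini-Hochberg FDR correction at alpha = 0.05 is applied separately
within each experimental-condition family; family membership defaults to
"all measurements of one condition" and is override-able, since the exact
20-34-measurement family lists are not enumerable from the source. The
pooled-input linear mixed-model comparisons of the original analysis are a
routine library fit and are deliberately out of scope; the replicate-paired
analysis is the primary reporting route here.

At n = 3 replicates the paired t-test is exact under normality but weak:
the analytic power at a true standardized effect of d = 2 is 0.471
(`power.t.test`), and the suite checks the simulated rejection rate against
that value rather than against a round 50%.

## What the generator emulates — and what it does not

`scene_params` defaults define the study conditions: Poisson input counts at
class- and eye-specific densities (defaults around 0.004-0.008 per um^3 per
arm, a realistic developing-dLGN scale); an AZ-count distribution over
{2, 3, 4} of (0.8, 0.15, 0.05) — most multi-AZ boutons carry two release
sites, few carry four; exact linear scaling of vesicle-pool volume with AZ
count (0.15 um^3 per AZ by default); like-eye clustering in which half of
sAZ synapses are placed within 1.5 um of an existing like-eye mAZ input
(rejection-sampled against a hard-core minimum separation so that planted
clusters never merge); CTB labeling of eye-A inputs at 97% efficiency (the
binocular-control labeling rate); two ~3-um cell bodies rendered into the
Homer1/Bassoon channels; sparse dim background labels in every channel; and
sparse speckle noise.

Rendering choices worth knowing:

* Vesicle clouds are axis-aligned ellipsoids with mild random eccentricity
  (volume preserved exactly), plus a 15-nm *edge-precision skirt*: single
  molecules at a cloud boundary are rendered with finite localization
  precision, so the suprathreshold cloud extends slightly beyond its nominal
  volume. Without the skirt, the measurement convention (77.5-nm smoothing
  then upper-Otsu threshold) erodes 30-40 nm of boundary and biases measured
  volumes 15-30% low; with it, the pipeline's volume estimate is
  approximately unbiased and the volume-per-AZ slope is recovered within a
  few percent.
* AZs are compact thresholded Gaussian puncta placed on the cloud surface at
  pairwise angular separations of at least 80 degrees, each with a Homer1
  punctum 50-150 nm outside it along a jittered outward direction (the
  outward bias keeps postsynaptic densities extracellular; the trans-synaptic
  distance is a generator choice, placed well inside the 140-nm association
  shell).
* CTB is rendered co-extensive with VGluT2 for labeled inputs, over a sparse
  axonal speckle backdrop spanning the input territory — the backdrop is what
  gives the neuropil hull its support, as the diffuse tracer does in tissue.
* Background labels are small, dim and internally speckled, so they sit below
  the synaptic population in both volume and signal density.

The generator does **not** emulate optical PSFs, localization-precision
distributions, drift, chromatic aberration, section loss or alignment error
(the pipeline consumes already-aligned stacks by design), nor axon
morphology, and its blobs are convex — so passing tests demonstrate the
correctness of the measurement chain under the stated statistical structure,
not robustness to every artifact of real serial-section STORM data. Real
volumes enter through `read_volume_tiff` and follow the identical code path.

## Problem sizes and numerical conventions

The test and acceptance workloads run a 512 x 512 x 60-voxel field at 78-nm
lateral voxels (about 40 x 40 x 4.2 um, ~150 inputs at default densities; a
coarser grid than the native 15.5 nm so that a field large enough for
spatial statistics stays desk-sized), a 400+ mAZ cohort on the same grid for
AZ-count recovery, and small 31-nm-voxel fields for unit tests of the
fine-scale geometry. Internally all distances are nm and all volumes um^3;
user-facing tables report um and um^3. Voxel centers sit at
`(i - 0.5) * spacing`. Ties in Otsu's objective resolve to the lowest
threshold pair; the watershed's flooding order is deterministic, and every
stochastic stage takes an explicit seed derived from the run seed, making
whole-pipeline reruns byte-identical.

## Known limitations

* The xi-extraction of OPTICS components fragments diffuse groups on small
  feature sets; the physical apposition criterion on component medians (plus
  the small-n threshold fallback) makes pairing robust to this, but the
  component labels themselves are not a stable clustering of feature space.
* Histogram matching preserves the zero level (background) and matches only
  positive intensities; channels whose background is nonzero would need a
  baseline subtraction first.
* The convex-hull neuropil mask is per-plane (2D), a polygonal mask per
  section; a strongly non-convex projection territory would be over-covered.
* At 78-nm voxels the 70-nm docked-vesicle shell is thinner than one voxel
  laterally; docked volumes on that grid are quantization-dominated and are
  meaningful comparatively, not absolutely. Unit tests of the shell run on
  finer grids.
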