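---
title: "Latent encoding models on cortical surfaces: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent encoding models on cortical surfaces: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsrmap)
```

## The model

`plsrmap` implements a neural encoding analysis in which a low-dimensional
behavioral description of visual object concepts predicts vertex-wise fMRI
responses on the cortical surface. Concepts are described twice: by a
stimulus embedding `X` (concepts × dimensions; e.g. a 66-dimension embedding
derived from similarity judgments) and by surface responses `Y` (concepts ×
cortical vertices, hemispheres concatenated). Partial least squares
regression (PLSR) inserts a k-dimensional latent space between the two:

* latent scores `L = X R_x` (concepts × k),
* stimulus loadings `B_X` (dimensions × k) relating the embedding to the
  latent space,
* neural loadings `B_Y` (vertices × k) relating the latent space to the
  surface, so predicted responses are `Ŷ = L B_Y'`.

Components are extracted in order of predictive power for `Y`. Both blocks
are z-scored per feature, with the training and test sets standardized
independently, so loadings are in standardized units.

The fit is regression-mode PLS2 with both-block deflation. One numerical
choice matters: the NIPALS inner loop is a power iteration whose fixed point
is the dominant left singular vector of the deflated cross-covariance `E'F`.
Power iteration stalls when the residual spectrum is nearly degenerate —
precisely the regime reached when the grid search probes more components
than the data support — so `fit_plsr()` computes that singular vector
directly by SVD. The result is the NIPALS fixed point (the test suite checks
equality with an independently coded iterative NIPALS to 1e-8), without an
iteration-count failure mode. Each component's sign is fixed by making the
largest-magnitude entry of its x-weight vector positive, so loadings are
reproducible across runs and platforms.

`B_X` is reported as the x-loadings `P`; the x-weights `W` are exported
alongside, since toolchains disagree on which matrix they call "loadings".

## Model-order selection

`grid_search_components()` nests a 5-fold cross-validation inside the
training set. Per fold and candidate k it records the maximum R² over all
vertices of the inner-test prediction — peak whole-map accuracy — and
reports mean ± sd per k. Because components are nested, one fit at
`max(k_range)` serves every candidate.

`selected_k` uses the one-standard-error rule: the smallest k whose mean
peak R² is within `sd/sqrt(n_folds)` of the best mean. We initially
considered a one-sd band, but the peak statistic saturates (some vertex is
always nearly fully explained by few components), leaving the gain at the
true dimensionality comparable to the fold sd: in simulation the one-sd
band under-selects in roughly a quarter of runs, while the 1-SE rule
recovered the true k in 80/80 seeded simulations. The 1-SE rule is also the
canonical form of this heuristic. For data shaped like the motivating study,
five components is the expected choice; the rule is an automatic stand-in
for reading the plateau off the curve.

## Inference

**R² maps.** Prediction accuracy per vertex is `R² = 1 − SS_res/SS_tot` over
held-out concepts, with `SS_tot` about the measured test mean (values may be
negative). Familywise error over the whole surface is controlled with a
maximum-statistic permutation test: each permutation shuffles the rows of
the training stimulus matrix against the fixed training responses, refits
the PLSR at the same k (model-order selection is not re-run), predicts the
unpermuted test set and retains the map-wide maximum R². The significance
threshold is the `ceiling((1 − alpha) · n_perms)`-th smallest maximum — the
empirical 95th percentile at alpha = 0.05 with no interpolation — and
significance requires strict exceedance; ties at the threshold are not
significant. This convention guarantees an exceedance probability of at most
alpha under exchangeability. The observed statistic is not appended to the
null.

**Searchlight decoding.** Discs are built per hemisphere around every
mask-included vertex, with membership decided by shortest-path distance
along mesh edges (Euclidean edge weights). Edge-graph distances slightly
overestimate true polyhedral geodesics, a standard and well-understood bias;
in exchange the disc membership is exactly testable against a brute-force
Dijkstra oracle. Within a disc, predicted and measured patterns for n test
concepts give an asymmetric n × n correlation matrix `R`; pair (i, j) is
decoded correctly when `R[i,i] > R[i,j]` strictly (ties count as errors),
and the disc's accuracy — assigned to its center vertex — is the mean over
all ordered pairs. The permutation null relabels the measured concepts once
per iteration, shared across all searchlights (required for a valid maximum
statistic), and retains the map-wide maximum accuracy. Internally the
relabeling permutes the columns of each disc's cached `R`, which is
algebraically identical to recomputing the whole map and is verified against
direct recomputation in the tests.

**RSA.** Representational dissimilarity matrices use correlation distance
(`1 − r`) for multi-feature representations and absolute score differences
for single components. RSA correlations are Pearson on strictly-lower
triangles (Spearman by flag). The permutation null applies one shared
concept reordering to the target RDMs per iteration and retains the maximum
correlation over all target × layer comparisons.

## Component-level analyses

* **Held-out GLM.** Test concepts are projected into the latent space with
  the training rotation; the projected scores, demeaned, form a GLM design
  (with intercept, matching standard toolchain behavior) fit per vertex to
  measured test responses. The slope matrix has the shape of `B_Y` and
  measures reproducibility of the loadings across data partitions.
* **Hemispheric symmetry.** Right-hemisphere maps are transported to
  left-hemisphere indexing through an explicit vertex correspondence table
  (for synthetic data, the generator's identity pairing; surface
  registration is out of scope). The ROI is the intersection of the
  thresholded R² maps on the left and mirrored-right hemispheres, and all
  left and mirrored-right loading columns are correlated across ROI
  vertices. Pearson correlation is used for loading maps (the field's
  default for spatial map similarity).
* **Property correlations.** Spearman correlations (mid-rank ties) between
  each latent component and each of 12 object-property ratings, Holm-
  adjusted over the full k × 12 family by default (the conservative choice;
  per-component families are available). P-values use exact enumeration up
  to n = 7 and the t-approximation above; enumeration beyond n = 7 is
  infeasible and a Monte-Carlo p would make result tables non-deterministic.
  Every intended use has n in the hundreds.

## The synthetic generator

`generate_dataset()` draws the data the pipeline is validated on:

* Latent scores `Z` (concepts × k_true) are standard normal and shared
  exactly between blocks — the premise that behavioral dimensions drive the
  neural response, giving clean parameter-recovery ground truth.
* The stimulus block is `X = Z A_x' + ε`, `A_x` orthonormal. The default
  stimulus noise (`noise_x_sd = 0.02`) is small against the per-dimension
  signal variance (≈ k_true/66) and keeps `X` full-rank, as a real
  behavioral embedding is; with exactly zero noise `X` has rank k_true and
  no component count beyond k_true can even be probed.
* Hemispheres are icospheres (default subdivision 3, 642 vertices each,
  radius 100 mm), the right one an exact mirror of the left with an identity
  vertex correspondence. Icospheres stand in for the 10,242-vertex template
  surfaces of real analyses: geometry-faithful but desk-scale.
* Vertex loadings `A_y` are unit-variance Gaussian maps smoothed by
  iterated neighbor averaging along mesh edges (`smoothness` steps; mesh-
  agnostic and cheap, in place of explicit heat kernels), optionally
  mirrored across hemispheres, and restricted to a contiguous signal patch
  (`signal_fraction` of vertices, grown breadth-first).
* At each signal vertex the noise draw is centered, decorrelated from the
  realized signal and rescaled so the realized signal-to-noise variance
  ratio equals `snr` exactly; non-signal vertices are unit-variance noise.
  The cross-validated R² ceiling at signal vertices is therefore the
  analytic `snr/(1 + snr)` — e.g. 0.5 at snr = 1 — which the recovery tests
  use.
* Ratings are fixed strictly monotone transforms of single latent columns
  (alternating sign, plus noise), with the assignment recorded; pseudo-layer
  activations mix a shared nuisance block with a replicated copy of `Z`
  under a depth profile of weights, so latent alignment rises with depth by
  construction. Replication preserves row-wise correlation, so a fully
  latent-weighted noiseless layer reproduces the latent RDM exactly.

Everything is drawn from one seeded stream; equal configurations regenerate
bit-identical datasets.

What the generator does **not** emulate: hemodynamics, trial-level noise
structure, spatially correlated noise, retinotopy, inter-subject variation,
and realistic cortical folding. Passing recovery tests therefore shows the
pipeline's statistics behave as designed under the stated model — correct
calibration, recovery of planted structure — not that real cortical data
satisfy that model.

## Conventions and degenerate inputs

* Vertex indices are 1-based in memory (the R convention); GIFTI files store
  triangles 0-based as the format requires, and readers/writers convert.
  Hemisphere concatenation is always left-then-right, with every column
  tagged by (hemisphere, vertex id).
* Standardization uses ddof = 1 (sample sd) by default, configurable to 0;
  constant columns are an error naming the feature. Train and test sets are
  always standardized independently.
* Delimited text is tab-separated UTF-8 with '.' decimals, first row =
  feature labels, first column = concept ids; numbers are written at full
  precision (`%.17g`) so write-then-read is bit-exact. GIFTI I/O supports
  the ASCII encoding.
* Searchlights with fewer than three member vertices have undefined
  accuracy: they are flagged and excluded from maps and nulls. A
  disconnected mask-included region warns and is processed per component.
* Pipeline stages derive their seeds from one global seed
  (`seed · 10 + stage index`), and reruns of a configuration are
  byte-identical; the run manifest records config, per-stage seeds and
  summary statistics.

## Problem sizes

The shipped demo configuration uses 300 concepts, 66 stimulus dimensions, 3
latent components, 642 vertices per hemisphere and 200 permutations per
test; the recovery analyses use up to 720 concepts, k_true = 5 and snr = 1
(the study-shaped 480/240 split), and calibration checks use 100 null
datasets × 200 permutations. These sizes were chosen so a complete
validation run finishes in minutes on one CPU while keeping every statistic
in the regime where its calibration is measurable.

## Known limitations

* Exact polyhedral geodesics (and hence millimetre-faithful disc sizes on
  irregular meshes) are not implemented; edge-graph distances are used
  throughout.
* Surface registration (subject-to-template or symmetric-template) is out
  of scope; hemispheric comparisons require an explicit correspondence
  table.
* Only ASCII-encoded GIFTI is read and written; binary/compressed GIFTI and
  volumetric (NIfTI) data are out of scope.
* The linear-regression baseline requires more concepts than stimulus
  dimensions and a full-rank design.
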