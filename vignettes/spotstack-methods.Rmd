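---
title: "spotstack: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spotstack: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

spotstack implements the computational core of a spot-based spatial
transcriptomics workflow: tissue masking of H&E images, automatic rigid
alignment of serial sections, spot neighbor-graph statistics (spatial-lag
autocorrelation ranking, region-neighbor extraction, rank-sum differential
expression), non-negative matrix factorization with ICA initialization on
Pearson residuals, HSV multi-feature rendering, and 3D nuclei point-cloud
assembly. This vignette explains each model and the design choices behind
it; everything quantitative stated here is computed by the package's test
suite or by `scripts/acceptance.R`, never asserted from memory.

## Data model

A dataset (`st_dataset`) bundles a genes × spots count matrix, a spot table
(tibble), per-section images and the array spacing. Spot pixel coordinates
are full-resolution, 0-based, origin top-left, with `px_x` the pixel column
and `px_y` the pixel row; the positions file's `pxl_row_in_fullres` maps to
`px_y`. Stating this once avoids the classic transposed-overlay bug. Images
carry a `scale` (raster pixels per full-resolution pixel) so that spot
coordinates can be projected into any raster. Spots flagged out-of-tissue
by the platform are loaded but dropped from analysis by default
(`filter_tissue()`), mirroring platform behavior. Visium positions files
come in a headerless v1 and a headered v2 dialect; both are detected by
inspecting the first row. Gzipped matrix/TSV inputs are accepted
transparently. By default the low-resolution image and its matching scale
factor are loaded — masking operates at 400 px width anyway, so the
high-resolution raster adds nothing but memory.

## Tissue masking

The pipeline is downscale → grayscale → contrast normalization → isotropic
blur → SLIC superpixels → k-means (k = 2):

* **Downscale** to a working width of 400 px with preserved aspect ratio
  (bilinear, antialiased). The image `scale` is updated so spot coordinates
  keep mapping correctly.
* **Grayscale** with Rec.601 luminance weights 0.299/0.587/0.114 — a
  standard choice; the stain-specific alternative (color deconvolution) is
  out of scope.
* **Otsu threshold** over a 256-bin histogram, maximizing between-class
  variance. A constant image has no threshold and raises a degenerate-image
  error. The threshold is not used to binarize directly: it anchors a
  piecewise-linear contrast normalization mapping the threshold to mid-gray
  (0.5), so the downstream stages see a stain- and exposure-independent
  intensity scale. Using the threshold as a contrast anchor rather than a
  hard cut keeps boundary information for the superpixel stage.
* **Gaussian blur**, σ = 2 px on the 400-wide image. The blur is isotropic;
  σ is exposed as a parameter.
* **SLIC superpixels** (default 1000 segments, compactness 10): local
  k-means over combined color and position with distance
  `dc² + (ds/S)²·m²`, implemented in C++ (`src/slic.cpp`) with the usual
  connectivity-enforcement pass that merges fragments smaller than `S²/4`
  into an adjacent segment. Channels in `[0, 1]` are scaled to a 0–100
  range internally so compactness 10 behaves like the conventional
  Lab-space setting.
* **k-means with k = 2** on the per-superpixel *median* of the unblurred
  normalized intensity splits superpixels into tissue and background. The
  median rather than the mean, because boundary-straddling superpixels
  contain partial-volume pixels from both sides: a segment that is ¾
  tissue should classify as tissue, and its median ignores the minority
  pixels where a mean would drift toward the class boundary. The
  clustering feature comes from the unblurred raster for the same reason —
  the blur exists to stabilize superpixel shapes, and reusing it for the
  class feature would smear the tissue boundary into a gradient. Which
  cluster is tissue is decided by two cues: stained tissue is darker, and
  it touches the image border less. When the cues disagree the luminance
  cue wins (ties in luminance fall back to the border cue).
* **Post-processing**: tissue specks and background holes smaller than 1%
  of the image area are removed/filled. This step goes beyond the minimal
  pipeline and is documented as such; it makes the mask robust to isolated
  stain debris.

On the synthetic H&E-like fixtures (pink blob, dark nuclei, near-white
background) the mask reaches IoU ≥ 0.9 against the generating truth across
seeds — the acceptance suite measures this on 10 sections.

## Serial-section alignment

Tissue edges are the mask minus its 8-neighborhood erosion — exactly the
nonzero-gradient pixels of the binary raster, a parameter-free equivalent
of gradient-based edge detection on a mask. Edge sets larger than 2000
points are subsampled with a seed (the cap is this package's choice; it
bounds the cost of nearest-neighbor search without visibly affecting
accuracy).

Registration is iterative closest point: alternate nearest-neighbor
correspondence (transformed source → target, one-directional, no trimming)
with a least-squares rigid fit by SVD (Kabsch) under an explicit
determinant constraint. Reflections are handled by a two-branch search —
the det = +1 and det = −1 branches are optimized separately and the lower
final RMSD wins — rather than letting the SVD flip freely, which guarantees
every iterate is a valid rigid transform. Each branch restarts from a small
fan of coarse initial rotations (−40° to 40° in 20° steps) about the source
centroid; plain ICP from a single start has a basin of attraction narrower
than the ±45° perturbations the stack may contain, and the multi-start is
the cheapest reliable escape. The recorded RMSD trace is non-increasing by
the classic ICP argument (each correspondence step and each fit step can
only reduce the matched objective). Non-convergence within `max_iter` is
not an error; the best iterate is returned with `converged = FALSE`.

Images follow their masks via backward warping with bicubic (Catmull-Rom,
a = −0.5) interpolation: every output pixel samples the input at the
inverse-transformed location, so integer translations are exact and no
holes appear. Out-of-frame samples take a white fill matching the H&E
background. Spot coordinates are lifted through the same transform by
scaling into the working frame, transforming, and scaling back; array
coordinates are untouched.

## Spot neighbor graph and spatial statistics

Physical spot positions derive from array coordinates with proper
hexagonal geometry — odd rows offset by half the spacing in x, row pitch
`spacing·√3/2` — because Visium's column index alone is not Euclidean.
Spots of the same section within 150 μm (default threshold, against the
100 μm center-to-center spacing) are joined; on a regular lattice an
interior spot gets exactly its six hexagonal neighbors. Sections are never
joined, so multi-section graphs are block-diagonal.

The **spatial lag** of a gene at a spot is the *sum* (not mean) of its
expression over the spot's neighbors; edge spots consequently have smaller
lags, which is accepted and inherited from the definition. The
**autocorrelation ranking** orders genes by the Pearson correlation
between expression vector and lag vector across all pooled spots
(per-section mode behind a flag); genes with zero variance in either
vector are undefined and sort last, ties break by gene identifier. The
ranking input should be normalized expression — clipped Pearson residuals
(`pearson_residuals()`) by default. There is no significance test on the
correlation; the method is a ranking, by design.

**Region neighbors**: given region labels, the outer neighbors are spots
outside the region adjacent to at least one region spot; the inner border
are region spots adjacent to at least one outside spot. Both are computed
from the adjacency matrix and verified against a brute-force double loop
in the tests.

**Differential expression** between two spot groups uses a two-sided
rank-sum test: exact enumeration of all `C(n, n_a)` assignments when both
groups have at most 8 spots (ties handled through midranks; the two-sided
p is the null mass at least as far from the expectation as observed), and
a tie-corrected normal approximation with continuity correction otherwise.
Genes expressed in less than 10% of both groups are skipped; adjustment is
Benjamini–Hochberg by default with Bonferroni behind a flag (the upstream
tool this mirrors defaults to Bonferroni). A numerical note measured by
the acceptance suite: at group sizes ≤ 8 the exact null is discrete with
probability steps of 1/C(n, n_a) ≥ 0.01, so the normal approximation
cannot track it to 0.01 uniformly — gaps of a few hundredths arise at the
distribution extremes. That is why the exact path, not the approximation,
is the default whenever both groups are small.

## Normalization and factor analysis

Counts are filtered gene-first (gene totals, then spot totals over the
surviving genes — a spot can drop below threshold only after gene removal;
the order dependence is deliberate and tested). Normalization is the
analytic negative-binomial Pearson residual
`(x − μ)/√(μ + μ²/θ)` with `μ = gene_total · spot_total / grand_total`, a
single global dispersion θ (default 100) and clipping at ±√(n_spots). A
full per-gene regularized NB regression is intentionally not
re-implemented: normalization is an imported step around the factorization
this package exists for, and the analytic residual with global θ is fully
specified, testable (closed form, Poisson limit as θ → ∞) and feeds the
same downstream operations.

NMF minimizes the Frobenius loss `‖A − WH‖²_F` by multiplicative updates —
chosen over other NMF loss families for its monotone-update guarantee,
which the tests assert numerically on every run (tolerance 1e-10 relative,
the round-off allowance for the `eps` guard in the update denominators).
Input is the non-negative transform of the residuals: clipping at zero by
default (a shift-by-minimum mode exists behind a flag; clipping keeps the
sparsity interpretation — only above-expectation expression drives
factors). Initialization runs fast ICA with k components. ICA centers the
data, so each component is bipolar, and a component can encode *two*
non-negative patterns at once: two spatially disjoint expression programs
appear as one positive/negative contrast. The initializer therefore
splits every component `s m'` into its positive-part pair `(s⁺, m⁺)` and
its flipped pair `(s⁻, m⁻)` and keeps the k candidates with the largest
norm product — the sign-aligned positive part of each component always
enters first, and an anti-correlated partner pattern claims a slot only
when it carries real mass. Exact zeros are nudged to 1e-6 so
multiplicative updates can move them, and an ICA failure falls back to a
seeded random initialization rather than aborting (flagged in the
result). The number of factors k is a required user parameter — no
automatic selection is offered. On output W columns are unit-L2 with the
compensating scale in H. Driver genes of a factor are the top-loading
genes of its W column. Multiplicative updates converge quickly to the
factorization's neighborhood but have a slow terminal tail; the tests
that demand near-exact reconstruction of an exactly-factorizable matrix
run tens of thousands of sweeps, while practical fits stop at the
relative-decrease tolerance long before.

Factor recovery is validated on planted ground truth: spatially disjoint
Gaussian-bump patterns, each owning 10 genes at `baseline·(1 + effect ·
pattern)`, NB noise. After optimal one-to-one matching (exact assignment
over permutations on cosine similarity, `match_factors()`), mean cosine
similarity and driver-gene overlap are reported by the acceptance suite
(5 seeds, 800 spots × 200 genes, θ = 10, effect 5).

## Rendering

The HSV multi-feature view assigns feature i (of k) the hue `(i−1)/k`,
min-max rescales each feature to `[0, 1]` across all spots of all sections
jointly (so colors are comparable between sections; per-feature rescaling
absorbs any positive scaling of a feature), and colors each spot by its
argmax feature at saturation 1 with the rescaled value in the V channel.
All-zero spots are black; ties go to the lowest feature index; constant
features rescale to zero rather than erroring. The HSV→RGB conversion is
done in double precision so these identities are exact.

As a rendering extension, `feature_surface()` interpolates a per-spot
feature onto a fine grid by barycentric blending over each grid node's
three nearest spots — on a hexagonal lattice exactly the local Delaunay
triangle — giving smooth surfaces between spots; it is exact for fields
linear in position and returns `NA` beyond the lattice hull.

Nuclei segmentation is deliberately simple: within the tissue mask, Otsu
on the in-mask intensities, darker-than-threshold pixels become connected
components, components of ≥ 2 px are reported by centroid. Touching nuclei
are not declumped — the goal is tissue morphology for the 3D stack, not
cell counting. The 3D stack gives section i the plane `z = (i−1)·Δz` with
user-chosen Δz, so the stack can be contracted toward physical spacing or
expanded for visual separation; points are exported as CSV or ASCII PLY.

## The synthetic study conditions

The generator exists so every method is testable offline with known truth,
and its defaults are the study conditions used throughout the tests:

* **Section images**: thresholded low-frequency Gaussian noise as the
  tissue blob (target area fraction 0.35 by default), H&E-pink tissue over
  a near-white speckled background, nuclei as dark disks of radius 2 px
  placed by dart-throwing with a minimum center separation (2r + 2) so
  each nucleus has a well-defined centroid. Serial sections share one blob;
  later sections are rigid perturbations (rotation ± 20°, shifts ± 15 px in
  the bundled preset) of the reference, as on a real slide stack.
* **Counts**: NB with variance `μ + μ²/θ` (matching the residual model),
  baseline mean 5, planted factors as peak-normalized Gaussian bumps with
  σ equal to a quarter of the lattice extent, centers spread by greedy
  farthest-point selection. Effect size 5 and θ = 10 are the recovery
  conditions; effect 0 is the exchangeability null, which the tests check
  by rank uniformity of the nominally-planted genes.
* **Problem sizes** in tests and acceptance: 10×10 lattices for graph
  structure, 500 spots × 1000 genes for ranking power (20 seeds), 800
  spots × 200 genes for NMF recovery (5 seeds), 200×160 px sections for
  masking (10 seeds) and 320×256 px for registration (20 perturbations) —
  sizes at which every property is measurable in seconds to a couple of
  minutes while leaving the mechanisms identical to full-size data.

What the generator does *not* emulate — realistic H&E color statistics,
stain variability, partial section overlap, lattice-breaking tissue
detachment, or cell-type-structured count covariance — bounds what a green
suite shows: the pipeline recovers truth under its own model of the data.
On real sections the masking and alignment stages are the ones most
exposed to that gap.

## Degenerate inputs and numerical choices

Constant images raise a degenerate-image error from the Otsu stage; empty
and full masks are rejected for edge extraction (no boundary exists);
fewer than 3 points reject ICP; all-zero spot columns are rejected by
normalization (filter first); an empty mask yields an empty — not
erroneous — nuclei set. Seeds parameterize every stochastic step (k-means
restarts, edge subsampling, ICA, generators); identical seeds give
identical results on one platform. ICP convergence is relative RMSD change
below 1e-6; NMF convergence is relative objective decrease below 1e-5 with
a 200-iteration cap.

## Known limitations

Registration is rigid only — no deformable model, so tissue distortion
between sections remains as residual error. The masking k-means assumes
exactly two intensity populations; faint tissue on bright arrays can fall
below the Otsu split. The ranking has no null calibration (by design).
NMF is a local optimizer; different seeds can land on different but
similar-quality factorizations, which is why recovery is asserted after
optimal matching rather than factor-by-factor. The CLI holds whole
sections in memory; it is not a streaming tool.
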