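---
title: "Methods: iterative maximum-entropy detection of lipid droplets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iterative maximum-entropy detection of lipid droplets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropletquant)
```

## The problem

Lipid droplets stained with a lipophilic dye (BODIPY 493/503), perilipin
reporters, or immunolabeled nuclei appear as bright, roughly circular
puncta in confocal sections of whole-mount *Drosophila* brains. Two
properties make them awkward to count automatically. Their brightness is
heavy-tailed: within one brain, droplet intensities span an order of
magnitude or more, so no single global threshold is both sensitive and
clean. And because a droplet is larger than the optical section spacing, a
single droplet reappears on several consecutive slices of a z-stack; naive
per-slice counting inflates the count severalfold.

`dropletquant` treats these with, respectively, iterative
detect-and-erase thresholding and explicit z-dimension doublet removal.

## Detection model

Each slice is processed independently, inside a tissue region of interest
(ROI).

**Smoothing.** A working copy of the slice is convolved with a separable
Gaussian (default sigma 1 px, kernel truncated at 3 sigma, reflect
boundary). The blur consolidates each punctum into a single connected
super-threshold component; all measurements (area, perimeter, intensity
statistics) are made on the original pixels, never the smoothed ones —
the smoothed image exists only to decide *where* particles are.

**Maximum-entropy threshold.** The within-ROI histogram of the smoothed
working copy is binned into 256 equal-width bins spanning its observed
min–max range (this makes 8-bit, 16-bit and real-valued smoothed data
behave identically, and mirrors the 256-bin convention of common image
analysis platforms). The Kapur–Sahoo–Wong criterion picks the bin index
$t$ maximizing $H_{bg}(t) + H_{fg}(t)$, where each class entropy
$H = -\sum_i p_i \ln p_i$ is computed from the bin probabilities
renormalized within the class (background: bins $\le t$; foreground: bins
$> t$). Conventions, fixed so that results are reproducible and the
independent brute-force oracle in the test suite can mirror them exactly:

- $0 \ln 0 \equiv 0$; thresholds that would empty a class are
  inadmissible.
- Natural logarithm; the base rescales both entropies equally and cannot
  change the argmax.
- Ties break to the smallest $t$ (inclusive foreground, deterministic).
- A histogram with fewer than two populated bins is *degenerate*: the
  slice is treated as particle-free (a classed condition, not a crash).

**Extraction.** Foreground components are labelled with 8-connectivity
(the usual particle-analysis convention). A component is kept if its area
lies in `[min_area, max_area]` (defaults 4 and 10,000 px), its
circularity is at least `min_circularity` (default 0: circularity is
reported, not filtered on), and it satisfies the ROI containment rule
(default: the centroid pixel lies inside the ROI; `"full"` requires every
pixel inside).

**Erasure and iteration.** Every super-threshold component — kept or
filtered — is erased from the working copy, i.e. overwritten with the
slice's background level (default: the median of the original slice
inside the ROI; `"zero"` is available). The erased region is dilated by
`erase_dilate_px` (default 3 px): a thresholded component is only the
core of a blurred spot, and without removing its point-spread skirt the
next, lower threshold re-detects ring fragments of the same object as
spurious particles. After erasure the histogram of the working copy spans
a narrower range, the next maximum-entropy threshold falls, and dimmer
particles surface. Default `max_iterations` is 3.

**Stopping.** Iteration ends early when (a) the histogram is degenerate,
(b) no particle passes the filters, or (c) the proposed threshold would
select more than `max_fg_fraction` (default 20%) of the ROI as
foreground. Guard (c) reflects a genuine property of the entropy
criterion: once no real particles remain, the histogram is a unimodal
noise peak, and the Kapur objective is maximized by splitting that peak —
selecting half the tissue as "foreground". A threshold that claims a
fifth of the brain is droplets is not a detection; it is the criterion
running out of work.

## ROI delineation

Whole-mount brains image as one bright region on a dark background. The
mask is computed once from the maximum-intensity projection over z:
Gaussian smoothing (sigma 8 px), a global threshold, binary closing (disc
radius 5 px), hole filling, and keeping the largest connected component;
the result is shared by all slices (the anatomy is stable across a short
stack, and a shared mask avoids slice-to-slice flicker in the density
denominator). If the mask comes out empty the full frame is used, with a
warning (this fallback can be disabled).

The default threshold is **Otsu's method**. The tissue/exterior split is
a two-class problem, and Otsu handles it whether the tissue appears as a
broad tail or as a second histogram mode. The triangle method is also
provided, but it is reliable only for unimodal-skewed histograms: when
the tissue is uniform enough to form its own histogram spike (as in flat
synthetic fixtures), the triangle construction thresholds at the base of
the wrong peak and clips the mask well inside the tissue boundary. On the
package's synthetic disc fixtures the Otsu mask matches the planted
tissue area to within about 1%; the test suite asserts ±10%. Users
quantifying a hand-framed sub-region (e.g. one antennal lobe) should
supply their own mask, which bypasses delineation entirely.

## Doublet removal

Detections on nearby slices whose centroids lie within `link_radius`
(default 5 px) and whose slice indices differ by at most `max_z_gap`
(default 1: adjacent or same slice) are linked; connected components of
this graph are clusters, so chaining is transitive — a droplet spanning
three or more sections collapses to one object even though its extreme
sections are far apart in z. Centroid distance, not pixel overlap, is
used because consecutive cross-sections of one droplet differ in size.
Each cluster retains exactly one particle: the one with the largest pixel
count, ties broken by lower slice, then lower centroid y, then x.
Discarded doublets stay in the output table flagged
`kept_after_dedup = FALSE`, so the CSV remains a complete audit trail;
summaries exclude them. The operation is idempotent, and the test suite
checks it against a brute-force pairwise-closure oracle on randomized
particle sets.

Same-slice linking (z gap 0) is intentional: halo fragments or split
components of one droplet on a single slice merge into its cluster
rather than inflating the count.

## Measurements

- **Perimeter** is the Moore chain-code boundary length, axial steps
  weighted 1 and diagonal steps $\sqrt 2$. On a digital disc of radius
  15 px this gives circularity $\approx 0.91$; the crack-edge
  (inter-pixel) perimeter was considered and rejected because it
  overestimates boundary length by roughly $4/\pi$ on smooth shapes,
  pushing the circularity of an ideal disc down to about 0.62 — a poor
  anchor for a descriptor whose purpose is "1 means circular".
- **Circularity** is $4\pi A / P^2$, clamped to 1; a single-pixel
  particle (zero chain length) is circular by convention.
- **Density** is the retained-particle count divided by the true-pixel
  count of the 3-D mask, so padding a stack with empty-mask slices leaves
  it unchanged. With a pixel size available, areas and densities are also
  reported in µm².
- **"Droplet surface"** is deliberately reported both ways — per-brain
  total and per-particle mean of the 2-D cross-sectional areas — since
  group comparisons in this field use either without always saying which.
- **Fold changes** divide every brain's metric by the control-group mean,
  so control fold changes average to exactly 1 and the comparison is
  invariant to any common rescaling (e.g. detector gain).

## The synthetic benchmark

The generator renders: a dark exterior at `background` (default 10) with
Gaussian read noise (sd = background/5), a flat tissue disc at
`tissue_level` 25 (radius 200 px, centered) — 2.5× the exterior, a
typical autofluorescence contrast — and `n_droplets` spheres with radii
uniform in 2–6 px and brightness log-uniform in 3–20× background.
Droplets are rendered at *absolute* intensity, combined with the tissue
by maximum: punctum brightness reflects dye concentrated in the droplet,
largely independent of the autofluorescence underneath. This choice is
what creates the regime the iterative detector exists for — the dimmest
droplets (≈3× background) sit just above the tissue level, below the
first-pass threshold, and are only recovered on later passes; the test
suite asserts exactly this (first-pass dimmest-decile recall is strictly
lower than the three-pass value).

Each droplet is a sphere in voxel space with a z step of `z_aspect`
(default 1.5) lateral pixels per slice, so a radius-r droplet spans
$2\lfloor r / 1.5 \rfloor + 1$ consecutive slices with shrinking
cross-sections — every benchmark droplet is a doublet (or longer chain)
that the dedup stage must collapse. Droplet centers are rejection-sampled
at least `min_separation` (16 px) apart and inside the tissue with a
margin, keeping planted objects individually resolvable so that
precision/recall against truth is well defined at the 4 px matching
tolerance. Slices are blurred with a per-slice Gaussian PSF (sigma 1 px),
noise is added, and the scene is quantized to 8 bits. Rendering is a pure
function of the spec (including its seed) and restores the caller's RNG
state.

The standard benchmark (`benchmark_spec()`) is 60 droplets over 12 slices
of 512 × 512, seed 101. On it the test suite requires precision ≥ 0.90,
recall ≥ 0.90, absolute count error ≤ 6, a strict dimmest-decile
improvement from iterating, and a raw (pre-dedup) count exceeding the
planted count.

**What the generator does not emulate** — and what passing its tests
therefore does not establish: textured or graded tissue autofluorescence,
touching or clustered droplets, anisotropic or depth-varying PSFs,
bleaching across slices, and non-spherical droplets. Results on real
stacks depend on choosing `sigma`, area bounds, and `link_radius` to
match the imagery; the provenance sidecar records every value used.

## Scoring

Detections (after dedup) are matched to planted droplets greedily by
ascending lateral centroid distance, one-to-one, accepting pairs within
the tolerance (default 4 px). Precision is the matched fraction of
detections — defined as 1 for an empty detection set, so a conservative
detector is not penalized on empty scenes; recall is the matched fraction
of truth. Size error compares detected cross-section area with the
planted central cross-section. Per-decile recall bins the truth by peak
intensity (decile 1 dimmest).

## Numerical and engineering notes

- Detection contains no randomness; two runs on the same input write
  byte-identical particle CSVs (row order is fixed to slice, centroid y,
  centroid x).
- The CSV/coordinate contract is 0-based (z, y, x), origin at the
  top-left of slice 0.
- 16-bit stacks are processed natively; nothing is rescaled on input, and
  TIFF round trips are bitwise lossless for voxels and masks.
- 8-connectivity labelling is built by merging the diagonal adjacencies
  of a 4-connected labelling; the merge is exercised directly in the unit
  tests.
- Known limitation: dim droplets whose central slice lies at the extreme
  ends of the stack are the most likely misses — they are truncated
  spheres with fewer chances to be seen, and their slices' later
  iterations may hit the background-splitting guard before reaching them.
  This is visible in the benchmark, where the few misses cluster at the
  first and last slices.
- Test-suite problem sizes: the full 12 × 512 × 512 benchmark is
  generated once per run and shared across the tests that need it;
  unit-level fixtures use 4 × 160 × 160 scenes, which exhibit the same
  iteration and doublet structure at a fraction of the cost.
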