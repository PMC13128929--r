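---
title: "Quantifying hyaloid vessel regression: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hyaloid vessel regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyaloidr)
```

## The measurement problem

Postnatal regression of the mouse hyaloid vasculature is scored on
en-face immunofluorescence flatmounts: DAPI for nuclei, CD31 for the
endothelium, TUNEL for apoptotic cells, plus nuclear (LEF1, ZEB1) and
membrane (VE-cadherin) markers. Much of the classic readout chain is
interactive — vessel areas outlined by hand, regressing segments judged
by eye, the retinal plexus enclosed with an oval selection tool. This
package replaces each interactive step with an explicit, seeded rule so
that the same image always yields the same numbers, and so that every
rule can be tested against synthetic scenes with known ground truth.

## Imaging model and assumptions

The pipeline assumes flat, co-registered 2-D channel rasters with an
isotropic physical pixel size (tile stitching, z-projection and shading
correction are upstream concerns). Intensities are arbitrary units;
every decision is made on relative intensities within one channel of one
image, so no cross-image calibration is required.

**Solid vessel mask.** CD31 is smoothed (Gaussian, `smoothing_sigma_px`,
default 1 px), thresholded (Otsu by default; the method is configurable
because the original interactive area selection leaves the effective
rule unknown), closed with a 3-px disc, and holes up to
`max_hole_area_um2` (default 1000 µm²) are filled. The size limit is the
package's answer to a scale separation in these images: collapsed lumina
and staining voids inside a vessel profile are tens to a few hundred
µm², while the avascular meshes *between* vessels are thousands of µm²
and must stay open — unlimited hole filling would flood every closed
loop of the network. Objects below `min_mask_object_area` (50 µm²) are
discarded as debris.

**Nuclei.** DAPI is smoothed and thresholded with IsoData
(Ridler–Calvard iterative intermeans, computed on the raw intensity
values), touching nuclei are split by watershed on the Euclidean
distance transform, and components below `min_nucleus_area` (10 µm²)
are dropped — an explicit stand-in for the visual exclusion of staining
artifacts. Per nucleus the pipeline records area, perimeter (measured on
the boundary-following contour, as in Fiji) and the circularity index
`4πA/P²`, clipped at 1 because digitization can push the raw value
slightly above it. Classification: a nucleus whose **centroid** lies
inside the solid mask is endothelial; outside the mask, circularity
≤ 0.6 makes it a pericyte, otherwise it is other-non-endothelial.
Centroid membership (rather than full-pixel containment) was chosen
because endothelial nuclei commonly overhang the vessel edge; a single
point rule is unambiguous and robust to mask erosion.

**Marker intensities.** For nuclear markers the background is the mean
marker intensity *inside the vessel mask excluding all nuclear pixels*;
each nucleus gets `sum(pixels) − background · n_pixels`. Negative
corrected values are retained — clipping would bias group means upward.
The per-flatmount summary is the class median (robust to the occasional
bright debris); membrane markers are summarized as mean-inside minus
mean-outside of the mask, one value per field. Intensities are always
measured on the raw channel: smoothing exists only to stabilize
segmentation.

**TUNEL puncta.** Yen's maximum-correlation threshold, preceded by
smoothing at the punctum scale (`puncta_smoothing_sigma_px`, default
1.5 px — matched filtering, the standard spot-detection choice), then
watershed on the masked intensity so touching puncta with distinct
maxima separate. A punctum whose centroid falls outside the vessel mask
is extravascular.

## Vessel topology and the regressing-segment rule

The solid mask is thinned to a one-pixel skeleton (Zhang–Suen), spurs
shorter than `prune_length_um` (15 µm) are removed, and the remaining
pixels are organized into a multigraph whose nodes are junction-pixel
clusters and endpoints and whose edges are the branch-to-branch vessel
segments. Two implementation details matter for correctness and are
worth stating:

* pixel adjacency uses *minimal* 8-connectivity — a diagonal link is
  dropped whenever an orthogonal two-step path exists — because naive
  8-neighbour counting declares spurious junctions along every diagonal
  staircase;
* thinning resolves one anatomical branch point (especially 4-way
  crossings) into several nearby triple-points; branch-to-branch stubs
  shorter than `junction_merge_factor` (2.5) times the summed local
  vessel radii (distance-transform values at the two nodes) are
  contracted back into a single node, and any node left with exactly two
  incident segments is dissolved by splicing them. The radius-scaled
  criterion avoids a fixed length constant that would break on vessels
  of a different calibre.

Each intravascular punctum is assigned to the segment whose skeleton
path is nearest to its centroid, if within `corridor_halfwidth_um`
(10 µm ≈ one vessel diameter); near-exact ties go to the lower edge id.
A segment is called **regressing** when both stated criteria hold:

1. *linear TUNEL cluster*: at least `min_cluster_puncta` (3) assigned
   puncta whose projections span at least twice the corridor half-width
   (20 µm) along the path — a span requirement, because three puncta
   piled at one point mark a single dying cell, not a regressing
   segment;
2. *discontinuous CD31*: the fraction of path samples with
   supra-threshold CD31 is at most `max_continuity_for_regressing`
   (0.8). CD31 is sampled at every path pixel after disc maximum-pooling
   (radius 3 px) so that a skeleton that does not run exactly
   mid-vessel still reads the vessel's intensity, and the continuity
   threshold defaults to the Otsu level of the CD31 intensities *within
   the mask* — staining loss is judged relative to stained vessel, not
   relative to tissue background, which would make almost any pixel
   count as continuous.

The original study applied these two criteria visually; the numeric
defaults here were fixed on the package's synthetic fixtures and make no
claim to reproduce any individual annotator. All of them are exposed in
`topology_params()`.

## Retina metrics

The oval that "fully encompasses" the plexus is formalized as the
minimum-area enclosing ellipse of the collagen IV-positive pixels,
computed with Khachiyan's algorithm on the convex hull (rescaled to the
farthest point after convergence so containment is exact). Radial
expansion is half the mean axis length, density is
`area / (expansion² · π)`. Densities above 1 are possible when positive
area extends beyond the fitted disc and are flagged with a warning. The
four radial incisions made when flatmounting a retina are ignored — the
mask is used as-is.

## SORT-seq pipeline

Processing follows the stated order: plate normalization → QC → marker
typing → log-normalization → differential expression → enrichment.

* **Plate scaling** multiplies every cell by
  `max(plate medians) / own plate median`, medians taken over wells with
  at least one count. After scaling, all plate medians agree to
  numerical precision.
* **QC** keeps cells with scaled total UMI in `[1000, 8000]` — read as
  inclusive on both ends, the conventional reading of an en-dash range;
  the boundary behaviour is pinned by tests either way — and
  mitochondrial percentage strictly below 10%, mitochondrial genes
  identified by the case-insensitive symbol prefix `mt-` (mouse
  convention, configurable).
* **Typing** is the pure marker rule: `Cldn5 > 0` and `Pdgfrb = 0` →
  endothelial; converse → pericyte; both or neither → excluded.
* **Differential expression** regresses group membership on the
  log-normalized expression of one gene at a time (logistic regression,
  IRLS with at most 25 iterations and tolerance 1e-8; the convergence
  flag is kept per gene because perfect separation is common at these
  cell numbers) and tests the expression term with a χ²(1) likelihood
  ratio. Fold changes compare de-logged group means with a pseudo-count
  of 1 (`fc_pseudo`, configurable since no published value exists),
  which keeps log₂FC finite for all-zero groups. Significance is raw
  p < 0.05 with |log₂FC| > 1 — no multiple-testing correction, matching
  the published criteria; the seurat-style `min.pct`/log-FC prefilters
  exist as options but default to off, since their use in the original
  run is not documented.
* **Enrichment** is the hypergeometric upper tail over a user-supplied
  universe, reported at overlap ≥ 5 and raw p < 0.01. Gene sets come in
  as GMT; term databases themselves are inputs, not package contents,
  because GO/PanglaoDB snapshots are version-dependent.

Gene and cell order are canonicalized with locale-independent radix
sorting, so results cannot depend on input file ordering or on the
session's collation settings.

## What the generators emulate — and what they do not

`generate_flatmount()` draws seed points with a minimum separation,
takes their exact Delaunay edges (brute-force empty-circumcircle test —
the point counts are small), prunes overlong hull edges while keeping
the graph connected, and enforces three geometric guards (≥ 30° between
edges at a node, ≥ 120° interior angle at pass-through points, a
clearance between non-adjacent edges) so that the rendered tube union
has exactly the topology of the abstract graph. Regressing segments are
planted on branch-to-branch edges and carry an evenly spaced TUNEL
cluster plus CD31 gap windows at 60% residual signal — reduced but
present staining, as collapsed vessels retain some CD31, which keeps the
solid mask connected while the continuity criterion reads the segment as
discontinuous. Nuclei are rendered as ellipses: axis ratio 5 for
pericytes (spindle-shaped, circularity ≈ 0.45–0.55, safely below the
0.6 cutoff), 1.8 for endothelial, 1.15 for the rounder other class,
with an equivalent radius of 4.5 µm typical of perinatal nuclei. Noise
is additive Gaussian with σ expressed as a fraction of the signal level.

The generator deliberately does **not** model optics (PSF, vignetting,
depth attenuation), staining heterogeneity along a vessel, nuclear
texture, or densely packed nuclei beyond the watershed's reach. Passing
the recovery tests therefore demonstrates that the *rules* are
implemented correctly and are robust to pixel noise — not that the
pipeline segments arbitrary real micrographs perfectly; on real data the
thresholds and minimum sizes remain the user's responsibility to review.

`generate_counts()` samples negative-binomial counts (dispersion
`size = 2`, `Inf` for the Poisson limit) around cell-type and
genotype-dependent means, scaled by plate depth factors and per-cell
depth. Mitochondrial counts are added on top, sized so planted
fractions land strictly on their side of the 10% criterion; depth
outliers are planted far outside the UMI window so the intended QC
outcome is unambiguous after plate scaling. DE genes get symmetric
half-shifts of ±log₂FC/2 per genotype and a floor on their baseline
mean (≈ 3 counts per cell at nominal depth) so that a planted fold
change is identifiable at all — a gene sampled at mean 0.01 carries no
signal at 30 cells per group, which is a fact about the design, not
about the estimator. Ambient RNA, doublets and batch effects beyond
plate depth are not modelled.

## Numerical choices and degenerate inputs

* Thresholding a constant raster returns a threshold at or above the
  single value: no positive pixels, empty results rather than errors.
* The watershed tolerance (1, on EBImage's scale) is applied to the
  distance transform for nuclei (shape-based splitting) and to a
  10-unit-normalized masked intensity for puncta (peak-based
  splitting).
* Khachiyan iterations stop at a relative step of 1e-4 and the ellipse
  is then rescaled to the farthest hull point, so containment is exact
  and the area is within a fraction of a percent of optimal.
* LRT p-values are floored at the smallest positive double so the
  contract `p ∈ (0, 1]` holds even for astronomically large statistics.
* All generators run under a locally-seeded RNG and restore the
  caller's `.Random.seed`, so library code never perturbs a user's
  random stream.

## Problem sizes used in the tests

The test suite and the acceptance script run on 512×512 px scenes at
1 µm/px with ~10-seed networks (≈ 38 nuclei, 19 puncta, 3 regressing
segments) and on 4-plate × 48-cell count matrices with 1000 genes —
sizes at which a full imaging pipeline takes a few seconds and the
whole suite well under two minutes, while every rule still faces the
geometry it was designed for (junctions, way-points, gaps, boundary QC
cells, planted fold changes at the study's cell numbers). The
permutation-null calibration uses ≥ 2000 gene-permutation draws.

## Known limitations

* The skeleton is 2-D; crossing vessels in a projected flatmount merge
  into a single junction.
* Circularity at the 0.6 cutoff is sensitive to segmentation detail for
  nuclei only a few pixels wide; at 1 µm/px the measured index of a
  spindle nucleus sits ≈ 0.1 below its analytic value, which is
  acceptable here but means the cutoff should not be re-tuned on
  differently sampled images without re-checking.
* The accession-scale validation of the SORT-seq stage (retained-cell
  and DEG counts of the deposited experiment) requires the deposited
  matrices, which are not redistributable inside the package; the
  corresponding test states exactly what it would check and fails
  informatively when the data are absent.
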