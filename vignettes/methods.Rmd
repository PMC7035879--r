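---
title: "Surface-based tetrahedral meshing of segmented head volumes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based tetrahedral meshing of segmented head volumes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(headmesher)
```

## The problem

Quantitative neuroimaging models — optical (fNIRS), electrical (EEG/tDCS)
and mechanical alike — need anatomically faithful volumetric meshes of the
head.  Their input is almost always a *segmentation*: per-voxel tissue
probabilities or labels for white matter (WM), gray matter (GM),
cerebrospinal fluid (CSF), skull and scalp, possibly with enclosed air
cavities.  Turning that voxel data into a tetrahedral mesh that (i)
represents each tissue boundary smoothly, (ii) respects the anatomical
nesting scalp ⊃ skull ⊃ CSF ⊃ GM ⊃ WM, (iii) keeps every element's shape
quality and size under control, and (iv) conserves each tissue's volume, is
the job of this package.

The pipeline is *surface-based*: tissue boundaries are extracted as closed
triangle surfaces first, and the volume mesh is built to conform to them.
This yields smooth boundaries and far fewer elements than voxel-conforming
approaches, at the cost of one genuine difficulty — adjacent tissues that
*share* a boundary (GM touching the outer CSF boundary where the CSF layer
pinches to zero thickness is the canonical case) would produce coincident,
intersecting surfaces.

## The layered tissue model and gap insertion

Let $P_{in}$ and $P_{out}$ be the probabilistic segmentations of an inner
tissue and its enclosing neighbor (values in $[0,1]$; binary masks are a
special case).  Two voxel-space operators insert a controlled gap wherever
the boundaries merge:

* **Thickening** grows the outer tissue over the dilated inner one:
  $$T^+(P_{out};P_{in}) : P_{out} \leftarrow
  \max\bigl[P_{in}+P_{out},\; D_\varepsilon(P_{in})\bigr],$$
  where $D_\varepsilon$ replaces each voxel by the maximum over the cubic
  (Chebyshev) neighborhood of half-edge $\varepsilon$ voxels.
* **Thinning** shrinks the inner tissue away from the union boundary:
  $$T^-(P_{in};P_{out}) : P_{in} \leftarrow
  \min\bigl[P_{in},\; E_\varepsilon(P_{in}+P_{out})\bigr],$$
  with $E_\varepsilon$ the dual min-filter (the sum is clamped to $[0,1]$
  first).

Both operators act only where the inner boundary merges with the outer one:
wherever $D_\varepsilon(P_{in}) \le P_{in}+P_{out}$, the thickened map
equals the plain cumulative sum, and similarly for $T^-$.  The altered
voxels are recorded, because the inserted gap is an *artifact* that the
post-meshing relabeling step undoes.

`buildLayeredModel()` applies one operator per adjacent pair, innermost
pair first.  The *extraction volume* of layer $i$ is the clamped cumulative
sum of layers $1..i$ (innermost first) with interior holes filled, so its
0.5-level set is the tissue's single outer boundary and successive level
sets are strictly nested.  Air-cavity masks are subtracted from the host
layer's extraction volume outward and their surfaces are extracted
separately.

Default choices (all user-overridable):

* $\varepsilon = 1$ voxel — the smallest value that guarantees
  non-intersecting level sets; the paper-level workflow never needs more.
* Neighborhood: the full $(2\varepsilon+1)^3$ cube, matching the index
  ranges in the operator definitions, with a shrinking window at grid
  borders (no padding artifacts).
* Strategy: `thin_inner` for the WM/GM pair, `thicken_outer` elsewhere,
  mirroring the two sample pathways of the layered-model workflow.
* Clamping the sums to $[0,1]$ preserves probability semantics and cannot
  move a 0.5-level set (values at the set are fixed points of the clamp).

## Surface extraction and processing

Surfaces are extracted by **marching tetrahedra** on a body-centered (BCC)
decomposition of the voxel grid: cell centers carry the 8-corner mean, each
pair of face-adjacent cells contributes four tetrahedra, and cut vertices
are welded by lattice-edge key.  This guarantees watertight, consistently
oriented, self-intersection-free output without the case-table subtleties
of marching cubes.  Two guards give the raw surface a minimum feature
size: the edge-interpolation parameter is clamped to $[0.12, 0.88]$, so no
facet degenerates where the level set grazes a lattice vertex (the
positional cost is sub-voxel, symmetric, and volume-neutral on average),
and a short-edge collapse removes the residual sub-voxel edge tail.
Without that floor, micro-facets fold over their neighbors under
smoothing and slim facets drive the density refinement into a subdivision
cascade.  The per-layer density bound `rmax` — the maximum circumradius of
any surface triangle, in mm — is then enforced by short rounds of
selective red/green subdivision (split triangles above the bound at edge
midpoints, bisect neighbors with hanging nodes) alternating with
short-edge collapses, because subdivision alone cannot reduce the
circumradius of a slim triangle.

Three standard smoothing filters are provided: plain Laplacian
($\alpha = 0.5$), Laplacian+HC (Vollmer's correction pushing vertices back
toward the originals, $\alpha = 0.1$, $\beta = 0.6$) and Taubin's low-pass
filter ($\lambda = 0.5$, $\mu = -0.53$), whose alternating
positive/negative steps avoid the volume shrinkage of pure Laplacian
smoothing — that shrink-resistance is asserted in the tests.  The pipeline
default is 10 low-pass iterations: enough to remove voxel-scale ripple,
mild enough that the enclosed volume moves by well under one percent.

Dense surfaces are then **decimated** by quadric-error-metric edge
collapse (candidate positions: endpoints, midpoint, quadric-optimal point;
link-condition and normal-flip guards preserve closed manifoldness) down to
the `rmax` density.  The error metric used to characterize decimation is
the per-node distance to the nearest node of the original surface; on a
dense sphere at a resampling ratio of 0.2 the mean error stays below
0.2 mm.  A rasterize-and-subtract path (`rasterizeSurface()`,
`subtractProbability()`) and an implicit Boolean union (`booleanUnion()`,
signed-distance minimum re-extracted at a fine pitch) support hybrid
workflows that combine precreated surfaces with volumetric segmentations.

## The tetrahedralization engine

No embeddable constrained-Delaunay refinement engine is available to this
package, so it ships its own conforming mesher, designed around the
contracts that matter downstream (boundary fidelity, quality bounds, exact
volume accounting) rather than around Delaunay optimality:

1. **Background lattice.**  A BCC lattice of near-regular tetrahedra
   (radius-edge ratios 0.65–0.87) tiles the bounding box at pitch $h$.
   By default $h = \min\{(12\,v_{max})^{1/3},\, \mathrm{extent}/48\}$, so
   lattice elements respect the element-volume bound with the whole-mesh
   extent resolved by ~50 cells; `cellSize` overrides it.
2. **Imprinting, outermost surface inward.**  For each surface the signed
   distance (negative inside) is evaluated at all mesh vertices.  A
   stuffing-style snap moves a vertex onto its closest surface point
   whenever a cut point on an incident edge would fall within 30% of the
   edge length from it — the cuts that would create degenerate slivers are
   exactly the ones removed.  Remaining sign-crossing elements are split
   along the linearly interpolated zero set (convex sub-polyhedra are coned
   from their minimum-index vertex; shared faces triangulate consistently
   by the minimum-index diagonal rule).  New interface vertices are finally
   projected onto the exact surface, eliminating the first-order chord
   bias of the interpolated cut.
3. **Mesh improvement.**  Rounds of (a) guarded Laplacian smoothing with
   tangential reprojection for surface-bound vertices, (b) short-edge
   collapse (global, shortest first) and targeted collapse of elements
   above the radius-edge bound, (c) edge removal (generalized 3–2 flips)
   for interior edges, and (d) long-edge splits for elements whose obtuse
   boundary faces bound their circumradius from below.  Every operation is
   accepted only if nothing inverts, no element exceeds the volume bound,
   and the local worst radius-edge ratio does not regress; a final pattern
   search polishes the last few stubborn clusters.  On the test phantoms
   the loop terminates with *every* element at or below the default bound
   $q = 1.414$.

Because the elements partition the meshed domain by construction, the sum
of element volumes equals the enclosed volume of the mesh's own outer
boundary to floating-point rounding — the conservation identity the QC
metrics verify at $10^{-6}$ relative and typically observe at $10^{-15}$.
The mesh conforms to a resampled implicit form of the input surfaces
(vertices exactly on the surface, facets chords of it) rather than to the
input triangles themselves; volume fidelity per tissue is the contract,
and is held to a fraction of a percent.

Region labels are assigned per connected region by the innermost surface
containing a representative interior point — the centroid of the region's
largest element, which is always strictly interior and needs no fallback
sampling.  Containment uses parity ray casting with a fixed perturbation
schedule, so points near faces resolve deterministically.

The sizing field is sampled over the domain and folded, with the per-label
bounds, into one effective global volume bound that sizes the lattice; a
constant field therefore reduces exactly to the global `vmax`.  This is
deliberately conservative — local grading is traded for simplicity and
guaranteed constraint satisfaction.

## Boundary recovery (relabeling)

Elements filling an inserted gap carry the adjacent tissue's label.
`relabelSharedBoundaries()` consults the *original* (pre-gap) segmentation
at element centroids (innermost tissue whose cumulative original map is ≥
0.5, with air masks checked first) in two steps:

1. every connected same-label region is retagged by majority vote —
   correcting wholesale mislabels such as swapped regions;
2. inside the altered-voxel record, elements are retagged *individually*.

The second step deviates from a pure per-region vote on purpose: a gap
shell is face-connected to genuine tissue of the same preliminary label,
so any connected-component vote bleeds across the very boundary being
recovered (we observed a component-level vote pulling thousands of skull
elements into GM on the merged-cap phantom).  Per-element retagging within
the recorded zone restores the tissue volumes to within the QC band while
leaving everything outside the zone untouched.  Ties resolve to the
innermost candidate tissue, since the gap was carved from the inner layer.

## Quality metrics

* **Joe–Liu quality** $q_{JL} = 12\,(3V)^{2/3} / \sum_{i<j} \ell_{ij}^2$ —
  scale-invariant, 1 for the regular tetrahedron, 0 when degenerate.  The
  normalization is asserted in closed form in the tests.
* **Radius-edge ratio** $R/\ell_{min}$ — circumsphere radius over shortest
  edge, minimized at $\sqrt6/4$ by the regular tetrahedron.  The meshing
  bound `q` is enforced as an *upper* bound on every element: a minimum of
  this ratio cannot bound quality (the regular tetrahedron minimizes it),
  and the conventional quality flag of Delaunay refinement engines is the
  same upper-bound reading.  Default `q = 1.414`.
* **Volume conservation** $V_{rel}$ — mesh-side tissue volume over the
  voxel count of the original per-tissue map at threshold 0.5.  Shells are
  measured per tissue via the label partition (equivalently, differences
  of cumulative boundary volumes), so the shells tile the head exactly.

## The phantom generator

`makeLayeredPhantom()` builds nested spherical (or ellipsoidal) layers
with analytically known volumes: probability maps are Gaussian CDFs of the
signed distance to each interface, so the 0.5-level set sits *exactly* on
the analytic sphere regardless of blur.  It emulates, in controlled form:

* shared boundaries (concentric shells partition the head exactly);
* *merged* boundaries — a layer offset until it is clipped against its
  neighbor, producing a cap of locally zero thickness (sphere–sphere
  intersection volumes in closed form);
* separated layers (a background gap carved from the inner layer);
* air cavities inside a host layer; and
* misclassified noise islands (deterministic under a seed).

Default blur is $\sigma = 0.5$ mm.  The choice matters: thresholding a
*difference* of CDFs at 0.5 under-counts any layer whose thickness is not
large against $\sigma$ (at $\sigma = 1$ mm the 2 mm CSF shell loses ~7% of
its voxels), which would contaminate the volume-conservation denominator
with a generator artifact.  Keeping $\sigma$ at or below a quarter of the
thinnest layer thickness keeps the thresholded volume faithful to the
analytic one; the cumulative (filled) maps used for surface extraction are
single CDFs and are insensitive to this.

What passing on phantoms does *not* show: real segmentations have
topological noise (handles, disconnected components), anisotropic voxels,
cortical folding at the resolution limit, and partial-volume profiles that
are not CDF-shaped.  The operators are defined for that generality and the
noise-island and keep-largest-component machinery addresses part of it,
but quantitative guarantees demonstrated here are for smooth nested
geometries at 1 mm resolution.

## Problem sizes and numerical choices

The validation suite runs the full pipeline on 96³-voxel, 1 mm phantoms
(~0.7 M elements at the default bounds, a few minutes each) and keeps unit
tests on 24³–64³ grids.  Tolerances asserted: morphology operators exact
against brute force; surface volumes within 3% of analytic; mesh region
volumes within 0.5% of their bounding surfaces; per-tissue $V_{rel}$
within $[0.98, 1.02]$; conservation within $10^{-6}$ relative; all
elements at or below `q` and `vmax`.  Degenerate inputs (empty level sets,
all-zero layers, cavities outside their host, non-nested inputs that the
operators cannot repair) raise errors naming the offending layer or pair.

## Known limitations

* The mesher's boundary is piecewise linear on surface chords: curvature
  error is $O(h^2)$ and shows up as the sub-percent negative volume bias
  visible in the QC numbers.
* Uniform lattice pitch: the sizing field does not yet grade the lattice
  locally.
* Oblique NIfTI affines are rejected rather than resampled (the operators
  are grid-axis-aligned by definition).
* The quality loop is heuristic; it has always terminated with zero
  violations on the suite's geometries, but no theoretical bound is
  claimed for arbitrary inputs.
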