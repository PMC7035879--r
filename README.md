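# headmesher

Surface-based tetrahedral meshing of segmented head MRI volumes, in R.

Model-based neuroimaging — optical (fNIRS), electrical (EEG/tDCS) and
mechanical alike — needs volumetric head models in which every tissue
boundary is smooth, anatomically nested (scalp ⊃ skull ⊃ CSF ⊃ gray matter
⊃ white matter), and volume-faithful to the segmentation it came from.
`headmesher` converts multi-label or probabilistic tissue segmentations
(NIfTI) into a nested multi-layer triangle-surface model and a labeled
tetrahedral mesh with per-element quality and size guarantees, for people
who build photon-transport, forward-EEG or FEA models of the head.

## Method in brief

Adjacent tissues that share a boundary would produce coincident, mutually
intersecting iso-surfaces.  The pipeline therefore first inserts a
controlled one-voxel gap wherever boundaries merge, using a morphological
**thickening** operator on the outer tissue

    T+(Pout; Pin):  Pout ← max[ Pin + Pout , D_ε(Pin) ]

or a **thinning** operator on the inner tissue

    T-(Pin; Pout):  Pin ← min[ Pin , E_ε(Pin + Pout) ]

where `D_ε`/`E_ε` are cubic max/min filters of half-edge ε voxels.  Closed
surfaces are then extracted per layer at probability threshold 0.5 under a
per-layer triangle-circumradius bound `Rmax` (1.7 mm for white/gray
matter, 2 mm for CSF, 2.5 mm for skull, 3.5 mm for scalp by default),
smoothed (Taubin low-pass, Laplacian, or Laplacian+HC), and optionally
decimated by quadric edge collapse.  A background-lattice tetrahedralizer
imprints the nested surfaces into a BCC lattice and drives every element
to the radius-edge bound `q = 1.414` and element-volume bound
`Vmax = 30 mm³`; elements in the inserted gaps are finally *relabeled*
against the original segmentation, recovering the shared boundaries.
Quality control reports the Joe–Liu shape metric

    q_JL = 12 (3V)^(2/3) / Σ ℓ_ij²   ∈ [0, 1]

the radius-edge ratio `R/ℓ_min`, and the per-tissue volume-conservation
ratio `Vrel` (mesh tissue volume over segmentation voxel volume).

A synthetic phantom generator (`makeLayeredPhantom()`) produces nested
spherical head phantoms with analytically known volumes — including
merged-boundary caps, separated layers, air cavities and noise islands —
so every stage of the pipeline is validated against closed-form oracles.

## Worked example

```r
library(headmesher)

# five-layer spherical head phantom: 96^3 voxels at 1 mm
stack <- makeLayeredPhantom(phantomPreset("five-layer"))
analyticVolumes(stack)
#>    scalp    skull      csf       gm       wm
#> 72650.38 44899.64 25744.30 42340.29 82447.96

res <- runPipeline(stack, pipelineConfig(), verbose = FALSE)
res$mesh
#> TetMesh: 123112 nodes, 701493 elements
#>   labels: csf=68288, gm=109705, scalp=191563, skull=117299, wm=214638

res$report
#> QualityReport
#>   elements: 701493   mean Joe-Liu 0.8970   min Joe-Liu 0.0027
#>   max radius-edge 1.4140   max volume 1.852 mm^3
#>   Vrel: wm=0.9948, gm=1.0041, csf=0.9851, skull=1.0084, scalp=0.9956
```

Every tissue's `Vrel` sits within 2% of unity — the mesh conserves each
layer's volume — while no element exceeds the radius-edge bound 1.414 or
the 30 mm³ volume bound, and the summed element volume equals the enclosed
volume of the mesh's outer boundary to rounding error.  Writing outputs:

```r
writeTetMesh(res$mesh, "head.vtk", "vtk")          # or "msh", "node_ele"
writeSurface(res$surfaces$gm, "gm.off", "off")     # or "ply", "stl"
writeQcReport(res$report, "qc.json")
```

The same pipeline is scriptable from a shell:

```sh
inst/exec/headmesher phantom --preset five-layer --out ph/
inst/exec/headmesher run --out mesh/ \
    --tissue wm=ph/wm.nii.gz --tissue gm=ph/gm.nii.gz \
    --tissue csf=ph/csf.nii.gz --tissue skull=ph/skull.nii.gz \
    --tissue scalp=ph/scalp.nii.gz
inst/exec/headmesher qc --mesh mesh/mesh.vtk --out qc.json
```

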