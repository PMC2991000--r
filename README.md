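# kneefusion

Fully automated, contrast-agent-free quantification of knee joint-effusion
volume from paired axial MRI acquisitions, for imaging scientists and
osteoarthritis researchers who need a reproducible alternative to manual
voxel selection or arthrocentesis. Joint effusion — excess synovial fluid in
the knee capsule — is a marker of osteoarthritis flare-up; on a T2-trueFISP
acquisition the fluid is markedly bright, but bright confounders (cartilage,
blood, fat), variable effusion topology and smooth intensity inhomogeneity
defeat any single fixed threshold.

The package implements a four-stage pipeline over a paired T1-weighted
(anatomy) and T2-trueFISP (fluid contrast) volume:

1. **Bone segmentation (T1).** The histogram of a fixed 18 × 36 × 18 mm
   femoral seed region yields a bone-marrow intensity interval
   [*T*<sub>lower</sub>, *T*<sub>upper</sub>] via optimal-point (triangle,
   maximum chord-deviation) thresholds on both sides of the marrow mode;
   after 2D contrast correction of each slice boundary and inter-slice
   repair, the femur and tibia become solid 3D reference objects,
   transported to the T2 frame through the stored voxel-to-world affines.
2. **Masking (T2).** Bones plus the patella/fat complex (bright tissue
   anterior to the femur) form the non-interest mask; the remaining body
   voxels are the analysis domain. Masking restricts the domain without
   overwriting intensities.
3. **Fluid segmentation.** A recursive two-pass histogram threshold — pass 1
   delimits the bright range above the dominant tissue mode, pass 2 locates
   the bright (fluid) mode and places the cut midway between the two modes —
   selects candidate objects, which are then filtered by anatomic position
   relative to the bones (centroid within 15 mm of a bone surface, bounding
   box meeting the synovial-pouch bands, not a cartilage-like shell).
4. **Subvoxel volumetry.** The final mask is meshed into watertight
   triangular surfaces (marching tetrahedra at the 0.5 level of the binary
   grid); interior voxels count fully and surface voxels contribute the
   sub-volume inside the mesh, so the reported millilitres have subvoxel
   precision: V = Σ V<sub>interior</sub> + Σ V<sub>partial</sub>.

A synthetic-data module generates the validation material: calibrated
digital phantoms (a 14.1 ml two-cylinder pair and a 247 ml sphere shell,
rendered at the protocol voxel of 0.5 × 0.5 × 3 mm with partial-volume
edges, pose jitter and noise) and knee-like paired T1/T2 scenes with ground
truth labels.

## Worked example

```r
library(kneefusion)

# a synthetic knee acquisition pair with known ground truth
sim <- renderKnee(kneeSpec(seed = 7))
res <- runSegment(sim$t1, sim$t2)

sprintf("bone thresholds [%.3f, %.3f]; fluid threshold %.3f",
        res$thresholds$bone["tLower"], res$thresholds$bone["tUpper"],
        res$thresholds$fluid)
#> "bone thresholds [0.924, 1.107]; fluid threshold 0.626"
res$volume
#> VolumeResult: 23.301 ml (SUBVOXEL_MESH; interior 6.009 + partial 17.292)
#>   components (ml):  1.171, 22.130
sim$truth$fluidVolumeMl
#> 23.38209
dice(res$bones@femur, sim$labels$t2$femur)
#> 0.9843525
head(res$candidates[, c("voxels", "boneDistMm", "retained", "rule")], 2)
#>   voxels boneDistMm retained     rule
#> 1   7413   5.579614     TRUE retained
#> 2    406   2.974963     TRUE retained
```

The recovered effusion volume (23.30 ml) lies within 0.4% of the generator's
analytic truth (23.38 ml); the two retained components are the femoral pouch
and the small posterodistal tibial recess, and the per-candidate audit table
records why every other bright object (cartilage slivers, the vessel decoy)
was discarded. Real acquisitions are loaded the same way from NIfTI files or
single-frame DICOM series directories:

```r
res <- runSegment("t1.nii.gz", "t2.nii.gz", outDir = "out/")
# writes effusion_mask.nii.gz, volume.json, candidates.csv, config.yaml
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/kneefusion segment --t1 t1.nii.gz --t2 t2.nii.gz --out out/
Rscript inst/cli/kneefusion phantom --kind cylinder --n 50 --seed 0 --out out/
Rscript inst/cli/kneefusion simulate --what knee --seed 7 --out sim/
```

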