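---
title: "Methods: automated knee joint-effusion volumetry"
author: "kneefusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated knee joint-effusion volumetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Joint effusion — excess synovial fluid in the knee capsule — is a marker of
osteoarthritis flare-up and a candidate outcome measure for treatment
studies. Its volume can be measured from MRI without contrast agents because
fluid is markedly bright on a T2-trueFISP acquisition, but a fixed global
intensity threshold fails in practice: other fluid-like tissues (blood,
hyaline cartilage, bone-marrow lesions) are also bright, the effusion's
topology varies between patients, and smooth intensity inhomogeneity (IIH)
shifts each tissue's intensities across the volume. `kneefusion` implements
a fully automated four-stage pipeline that addresses these confounds and
reports the fluid volume with subvoxel precision.

The inputs are two co-registered axial acquisitions of the same knee without
patient repositioning: a T1-weighted gradient-echo volume (bone marrow and
fat bright; used as the anatomic reference) and a T2-trueFISP volume (fluid
bright; used for fluid detection). Each volume carries its own voxel-index
to world-millimetre affine; all reasoning across sequences happens in world
space. The package convention is RAS (+x right, +y anterior, +z superior)
with 0-based voxel indices in the affine; DICOM's LPS axes are converted on
load.

# The four stages

**Stage 1 — bone segmentation (T1).** The femur lies at the image center of
axial knee acquisitions, so a fixed 18 × 36 × 18 mm box (long side
anterior–posterior) samples pure femoral marrow. Because bone marrow
occupies the mid-range of T1 intensities, two thresholds are needed: the
histogram of the seed box is bracketed by an *optimal point* on each side of
its dominant mode (see below), defining the marrow intensity interval
`[T_lower, T_upper]`. Voxels in this interval are selected in 3D, each
slice's boundary is refined by a 2D contrast correction (boundary points may
move up to 3 px along the local normal to the maximum intensity-gradient
position, sharpening the marrow-to-subchondral interface), and an
inter-slice repair replaces slices whose cross-section collapsed (area below
half the mean of both non-empty neighbours, or empty between non-empty
neighbours) with the morphological interpolation of the neighbours — the
zero level of the mean of their signed distance transforms. After
26-connected labelling, the femur is the component containing the seed box
and the tibia is the largest remaining component centered inferior to it;
both are hole-filled into solid objects and transported to the T2 grid by
nearest-neighbour resampling through the affines (binary masks stay binary).

**Stage 2 — masking objects of non-interest (T2).** Bright structures other
than fluid are removed from consideration so they cannot contaminate the
stage-3 histogram: the transported bones, plus the patella/fat complex,
which is segmented per slice (optimal-point threshold of the body-region
histogram, bone voxels excluded) and identified by position — 3D components
reaching anterior of the femur's anterior extent. Masking is by *domain
restriction*: intensities are never overwritten, so no artificial zero peak
enters later histograms. The analysis domain is the complement of the
non-interest mask within an automatically extracted body region (everything
above the optimal point over the air mode, hole-filled); without the body
restriction the air mode would dominate the stage-3 histogram.

**Stage 3 — fluid segmentation.** The histogram of analysis-domain
intensities is thresholded recursively: pass 1 computes the optimal point
above the dominant (soft-tissue) mode, delimiting the bright range; pass 2
locates the dominant bright mode within that range and places the final
threshold midway between the two mode intensities (never below the pass-1
value). Voxels at or above the threshold form 26-connected candidate
objects (minimum 5 voxels). Candidates are then filtered *anatomically*
against the bones: an object is retained only if its centroid lies within
15 mm of a bone surface, its bounding box intersects the peri-articular
pouch bands (the synovial pouch extends anteroproximally along one third of
the femur and posterodistally along one fourth of the tibia, measured from
the joint), and it is not a thin shell apposed to subchondral bone (≥ 80% of
its voxels within 2 in-plane voxels of a bone surface — the hyaline
cartilage signature). Filtering includes or excludes whole objects; masks
are never edited. The union of retained objects passes once more through
the inter-slice repair.

**Stage 4 — subvoxel volumetry.** The final mask is converted to one
watertight, outward-oriented triangular mesh per component (marching
tetrahedra over the translation-consistent Kuhn decomposition of each grid
cell). Fully interior voxels (all 26 neighbours foreground) contribute their
full voxel volume; voxels intersected by the surface contribute the
sub-volume inside the mesh, evaluated on a fixed 5×5×5 sub-voxel lattice
against the same piecewise-linear field whose level set defines the mesh, so
the sampled region is exactly the mesh interior. The total is reported in
millilitres, and the divergence-theorem (signed-volume) evaluation of the
mesh provides an independent estimate of the same model volume, which the
test suite requires to agree with the sampled total.

# The optimal-point threshold and the recursive variant

The *optimal point* of a histogram curve is computed by the triangle
(maximum chord-deviation) method: normalize the bin axis and the count axis,
draw the chord from the dominant mode's peak to the last (searching above
the mode) or first (below) non-empty bin, and return the bin center that
maximizes the perpendicular distance from the curve to the chord. It is
parameter-free, deterministic, and exactly reproducible by an exhaustive
per-bin search (the test suite checks bit-identical agreement on 1000 random
histograms). Ties break toward the higher intensity — a slightly higher but
more stable threshold. Otsu's criterion is available as a configuration
alternative (`thresholdMethod = "otsu"`).

The stage-3 threshold must sit at the *midpoint of the partial-volume ramp*
between background and fluid: a boundary voxel containing a fraction `f` of
fluid has intensity `bg + f·(fluid − bg)`, and the downstream mesh passes
midway between the last included and first excluded voxel center, so the
volume bias of the whole chain is proportional to (0.5 − cut fraction).
A threshold near the base of the fluid mode (where a knee-of-the-curve
search on the restricted histogram lands) would under-segment a 14 ml
cylinder at 0.5 × 0.5 × 3 mm voxels by 15–20%. The recursive rule
implemented here — bright range from pass 1, dominant bright mode from
pass 2, threshold at the mode midpoint — places the cut at ramp fraction
~0.5 by construction, is invariant to noise level (modes do not move with
noise width), and degrades gracefully: when the restricted curve has no
separable bright mode the pass-1 value is returned with a fallback flag.
One guard matters in knees: the decaying tail of the soft-tissue mode
reaches past the pass-1 value, so the bright-mode search skips the initial
non-increasing run of the (lightly smoothed) restricted curve; otherwise the
muscle tail masquerades as the bright mode.

# Mesh conventions

Two vertex placements are supported. The default, `"interpolated"`, is the
0.5-level iso-surface of the binary mask: vertices midway between foreground
and background voxel centers. It is the placement consistent with
partial-volume physics (the midway surface is an unbiased estimate of the
true boundary when the selection cut sits at ramp fraction 0.5) and is used
for all volumetry. The alternative, `"centers"`, realizes the literal
surface through the peripheral-voxel centers themselves; it inscribes the
surface half a voxel deeper (for a solid a×b×c cuboid at unit spacing its
enclosed volume is exactly (a−1)(b−1)(c−1)) and correspondingly biases small
objects low, so it is provided for comparison rather than measurement.
Components thinner than 2 voxels along any axis cannot carry a surface and
fall back to voxel-count volume, flagged `VOXEL_COUNT_FALLBACK`.

Partial-voxel integration uses 5³ sub-samples per intersected voxel
(config-adjustable), bounding the per-voxel error by voxelvolume/125 against
the per-tetrahedron linear interpolant.

# The synthetic-data module

No acquisitions ship with the package, so a generator supplies the study
material.

**Calibrated phantoms.** `cylinderPhantomSpec()` renders two disjoint
perpendicular cylinders (radius 7.5 mm; total length set so the analytic
volume is exactly the 14.1 ml calibration; one axis along the acquisition
direction, one in-plane — the pose with minimal partial volume) filled with
bright solution in a water bath; `spherePhantomSpec()` renders a dark solid
sphere (radius 20 mm) surrounded by bright solution inside a container
sphere whose radius is derived from the 247 ml fluid calibration. Phantom
grids use the T2 protocol voxel of 0.5 × 0.5 × 3 mm. Ground truths are
closed forms recomputed from the geometry. Per-scan variability is modelled
as uniform orientation jitter (± 5°), uniform sub-voxel translation (± half
a voxel per axis: the placement of a phantom relative to the slice grid is
effectively uniform modulo one slice), and additive Gaussian noise with SD
0.04 of the fluid intensity (SNR ≈ 25, typical of 1.5 T trueFISP). These
defaults were fixed once, from acquisition realism.

Voxel occupancies are computed by sub-voxel sampling whose per-axis rate
scales with the voxel spacing (base 5 → 5 × 5 × 31 samples for 0.5 × 0.5 ×
3 mm voxels, capped at 49 per axis, odd counts so occupancy fractions never
tie at exactly 0.5). Isotropic 5³ sampling leaves a 0.6 mm z-pitch that
visibly quantizes flat axis-aligned surfaces (≈ −1% on the cylinder
phantom); equalizing the physical pitch removes both that bias and the
spurious scan-to-scan variance it adds.

**Synthetic knees.** `kneeSpec()` renders a paired T1/T2 acquisition of a
knee-like scene in a shared world frame: femoral and tibial capsules with
bright marrow and a thin (0.8 mm) dark cortical shell, 1.5 mm hyaline
cartilage shells on the joint-facing surfaces, a C-shaped synovial fluid
pouch wrapping the distal femur (clipped so it never passes anterior of the
femur, as the suprapatellar capsule does not) plus a posterodistal tibial
recess, an anterior patella/fat complex, a posterior popliteal-vessel decoy
~28 mm from both bones, an elliptical muscle cross-section, and air. Per
sequence, tissues take tabulated relative intensities (marrow/fat bright on
T1, fluid bright on T2 with every other tissue below half its intensity); a
smooth multiplicative bias field (amplitude 0.05, shared between sequences)
emulates IIH, and independent Gaussian noise (SD 0.04) is added. Grids are
scaled-down analogues of the acquisition protocol — T2 160 × 160 × 30 at
1 × 1 × 3 mm, T1 240 × 240 × 30 at 0.6 × 0.6 × 3 mm — chosen once as the
package's test geometry. The bone ground-truth labels are the marrow
compartments (the bone object the thresholds delineate is bounded by the
marrow-to-subchondral interface); the fluid ground-truth volume is computed
by fine fixed-resolution quadrature (1 mm grid, 4³ sub-samples) of the
analytic pouch geometry, since the pouch region has no closed form.

**What the generator does and does not emulate.** It reproduces the features
the pipeline's design responds to: tissue contrast of the two sequences,
partial-volume mixing at 3 mm slices, IIH, noise, anatomically positioned
confounders (cartilage shells, a bright vessel, the patella/fat complex).
It does not model MR physics (no TR/TE/flip-angle signal equations, no
Rician noise floor, no truncation artefacts), osteophytes or irregular bone
shapes, synovial-membrane thickening, bone-marrow lesions, popliteal-cyst
subcompartments, or inter-scanner calibration drift. Passing tests
demonstrate that the implementation realizes the method faithfully under
these controlled conditions — not that the method generalizes to arbitrary
clinical images.

# Numerical choices and degenerate inputs

- Histograms: 256 equal-width bins over the observed range; a constant
  region degenerates to a single occupied bin and threshold operations on it
  raise errors (the candidate segmenter maps this to "no bright content").
- All thresholds are invariant to uniform intensity scaling up to bin
  quantization.
- Connectivity is 26-neighbour in 3D and 8-neighbour in 2D throughout; the
  3 mm slice gap makes maximal connectivity the safe choice.
- The inter-slice repair only fires for slices flanked by two non-empty
  neighbours: the natural taper at an object's ends (sphere poles, bone
  ends) is shape, not missing data.
- The contrast correction resolves gradient ties toward the smallest move
  (an exact step edge is a fixed point) and clamps every boundary move to
  the configured depth; stray components created by a moved boundary are
  dropped and holes refilled.
- The anterior patella/fat rule uses a 4 mm margin over the femur's
  per-slice anterior extent, floors that extent at the global femur extent
  minus 2 mm, and leaves femur-free slices unqualified: near the rounded
  femoral end the per-slice extent shrinks to zero and would otherwise
  declare the joint fluid itself "anterior tissue".
- Empty masks, empty candidate lists and empty analysis domains propagate
  as empty results (with a warning where the spec of the operation calls
  for one), never as crashes.

# Problem sizes used by the validation suite

The test suite and the acceptance script run: 50 simulated cylinder-phantom
acquisitions and 5 sphere-phantom acquisitions at full protocol resolution
(the reproducibility study sizes of the validation design), one default
synthetic knee plus one bright-vessel variant through the complete
four-stage pipeline, digitized balls of radius 5–20 voxels and cuboids for
the analytic mesh oracles, and 1000 random histograms for the threshold
oracle. These sizes were chosen as the package's standard validation
configuration.

# Known limitations

- The bone separation rule (seed containment for the femur, largest distal
  component for the tibia) presumes an axial stack covering the joint with
  the femur centered; acquisitions centered elsewhere need a different seed.
- The anatomic filter's constants (15 mm bone margin, band fractions, the
  80%/2-voxel shell rule) operationalize qualitative anatomy and were fixed
  against the synthetic scenes only.
- DICOM support is read-only, single-frame, uncompressed little-endian.
- No inter-sequence motion correction is applied; the two acquisitions are
  trusted to share a world frame, as they are acquired without patient
  repositioning.
- The subvoxel integrator is exact only with respect to the mesh's
  piecewise-linear model; both it and the divergence-theorem value measure
  the model, not the unknown continuous object.
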