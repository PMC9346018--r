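---
title: "Methods: synthetic patellofemoral FE analysis of sulcus-deepening trochleoplasty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic patellofemoral FE analysis of sulcus-deepening trochleoplasty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

`patellofem` implements a quasi-static finite-element analysis of
patellofemoral cartilage contact before and after virtual sulcus-deepening
trochleoplasty. The clinical study this workflow mirrors used two private
MRI segmentations (one healthy knee, one severe type-D trochleodysplastic
knee); since those geometries are not available, the package generates
*synthetic* parametric knees that reproduce the published clinical indices
of the two study knees, and reproduces the study's statistical layer
exactly from its printed per-angle tables. Absolute stresses on the
synthetic pair are therefore *not* expected to match the published
patient-specific values; the qualitative orderings (dysplastic above
healthy, further increase and contact-area loss after surgery, lateral
facet concentration) are pinned as fixture regressions.

All modules share one frame: origin at the deepest mid-trochlear sulcus
point, +x lateral along the posterior condylar baseline (BL), +y anterior,
+z proximal; units mm, N, MPa. Models are right knees; left knees are
mirror images.

## Synthetic geometry

The distal femur is lofted from axial profiles. Each profile's
articulating arc between the condylar peaks (MC, LC) is an asymmetric
parabolic channel: the groove floor S sits `sulcus_depth` posterior to the
MC-LC chord, giving a valley radius `halfwidth^2 / (2 depth)` (about 16 mm
at the healthy default depth of 6 mm). The non-articulating edges and the
posterior bone contour close each profile into a watertight shell. Groove
depth varies along the shaft (deepest mid-trochlea), the groove dives into
the intercondylar notch distally, and the dysplastic preset adds a
supratrochlear spur ramp that makes the proximal trochlea flat to convex
(depth at the proximal station is negative), a hypoplastic medial facet
(prominence scale 0.75) and a medial drift of the groove track.

The patella is a closed shell built from an elliptic-paraboloid articular
disc (facet radius 15.7 mm transverse, 88 mm sagittal; the medial facet 8%
steeper) and an anterior bone dome. The transverse *bony* axis carries the
clinical tilt obliquity (`axis_tilt`), so a patella measured at 12 or 18
degrees of tilt still articulates congruently - as real patellae do.
Cartilage thickness maps peak centrally (femur 3.3 mm, patella 4.2 mm)
and thin toward the margins.

Calibration, not ground truth: the facet radii, thickness maps and loading
geometry were chosen once so that the healthy knee's contact area is of
order 600 mm^2 across flexion (the scale the study reports); they are not
patient measurements. The dysplastic preset's quantitative targets are
only the published clinical indices: TT-TG 17 mm, patellar tilt 18
degrees, bisect offset 76% (healthy: 12 degrees, 48.5%, TT-TG 9 mm as a
normal value); its remaining shape parameters are design choices.

What the generator does *not* emulate: real osteochondral surface noise,
subject-specific thickness distributions, menisci/tibiofemoral cartilage,
and patellar rotations (see Loading). Passing tests on the synthetic pair
therefore validate the machinery and the reported orderings, not
patient-specific magnitudes.

## Virtual trochleoplasty

The surgery operator relocates the sulcus of every axial profile between
two correction planes: `S1 = S + f L_mean x (lateral) - f D_mean x
(anterior)`. The proximal plane is the most proximal station whose
articulating arc is fully cartilage-covered; the distal plane the most
distal station before the groove turns into the notch (tangent threshold
45 degrees). The published reduction of the TT-TG fixes `L_mean = 6.1 mm`
(3.05 mm at half correction, 9.15 mm at 1.5x); the mean deepening is not
printed in the source study and defaults to `D_mean = 4 mm`
(configurable). Both planes carry the full corrected values, matching the
two marked axial images of the surgical protocol; a cosine taper of width
`blend = 3 mm` outside the band avoids slope discontinuities. The new
anterior contour through MC-S1-LC uses the same parabolic-channel
construction as generation (a literal straight-segment mode is available),
clamped so bone is only removed. The osteochondral flap is re-draped by
construction: vertex thickness values ride along unchanged, which realizes
the surgical principle that the flap is moved, not thinned. A zero
correction factor reproduces the input mesh bitwise.

## Discretization and materials

Cartilage layers are extruded from the articular shells along inward
vertex normals through the per-vertex thickness, in two element layers by
default, each prism split into three tetrahedra with globally consistent
diagonals. Cartilage is homogeneous isotropic linear-elastic (E = 5.0 MPa,
nu = 0.47, friction coefficient 0.02); bones are rigid: the femoral
bone-cartilage interface is fixed, the patellar one moves with the
patellar rigid body. Four-node constant-strain tetrahedra with exact
integration pass the affine patch test to machine precision and reproduce
the constrained modulus `E(1-nu)/((1+nu)(1-2nu)) = 30.045 MPa` in confined
compression. Near-incompressible CST elements can lock; with two layers
through the thickness and the compression-dominated loading here the
benchmark errors stay in the few-percent range (see the verification
script), which is adequate for the comparative questions the study asks.
At the reference mesh density the two cartilage bodies together have a few
tens of thousands of elements, the scale of the source models; studies and
tests run at half density (about 6,000 elements), where the mesh-refinement
drift of peak pressure is below 5%.

## Loading

Per flexion angle (30, 45, 60, 75 degrees): the femur is fixed; the
patella has three translational degrees of freedom with rotations held at
the preset tilt; three patellar-tendon fan springs (total 4334 N/mm,
split equally, tension-only) run from the flexion-rotated tibial
tuberosity to the inferior pole; MPFL (6.45 N/mm) and LPFL (5.42 N/mm)
springs carry a 2% default prestrain (the source protocol states prestrain
without a value). The quadriceps applies 276 N split 111/67/98 N
(RF+VI/VM/VL) along per-angle unit directions from an editable table; the
posterior lean grows with flexion (18-46 degrees for RF/VI), standing in
for the experimentally derived directions of the cited loading protocol,
with VL leaning 22 degrees lateral and VM 28 degrees medial.
Tibiofemoral kinematics enter only through the tendon origin, which
rotates about the posterior condylar axis with the tibia. The start pose
places the patella at the preset bisect-offset target, a
flexion-dependent engagement station, and an anterior offset such that
the unloaded minimum cartilage gap equals 0.3 mm.

## Contact and solver

Node-to-surface penalty contact couples the patellar articular nodes to
the femoral articular triangles: deterministic spatial-hash candidate
search on the (x, z) plane, exact closest-point projection, and contact
normals interpolated from master vertex normals so the force field is
continuous across facet edges. The penalty (100 MPa/mm) is C1-regularized
over a 0.01 mm gap window - both smoothings exist purely to give Newton a
differentiable residual; solutions are penalty-insensitive (doubling the
stiffness moves peak pressure by under 2%). Friction is regularized
Coulomb with mu = 0.02 on the incremental slip per load step, capped at
mu times the normal traction; a frictionless fast path exists. An
augmented-Lagrange outer loop is available when near-zero residual
penetration is wanted; the penalty default keeps the 99th-percentile
penetration below 1% of local thickness.

The solver ramps the load by adaptive substepping (increments halve when
a level fails, a snap-through-tolerant continuation) and runs Newton
iterations on the coupled unknowns (patellar translation + nodal
displacements) with a backtracking line search, a 1 mm trust-region
clamp, and the three patellar rigid-DOF Jacobian columns replaced by
finite differences of the full residual - this captures the geometric
stiffness of the rigid glide along the curved groove that the
frozen-geometry penalty linearization misses. A rigid-body pre-settle
(elastic-foundation approximation, 3-DOF Newton) chooses the starting
contact basin, and when the iteration stagnates at a fold between contact
basins a frictionless energy-descent fallback (L-BFGS on the total
potential) carries the iterate through. Convergence requires the residual
below 1e-6 of the applied load, at which point the patellar force balance
(muscle + springs + contact) holds to the same tolerance; a secondary,
explicitly flagged acceptance class exists for states whose patellar
rigid-body balance meets the full tolerance while the nodal residual
stalls below 0.5% of load (single-projection flicker of nodes wedged in a
valley narrower than the mesh spacing). Non-convergence is always
flagged, never silently accepted; the study driver retries once with a
finer ramp and a groove-seeking start. Everything is deterministic:
direct sparse factorizations, no randomized algorithms, so reruns are
bitwise identical.

## Output measures

Contact pressure is reported from the nodal penalty tractions averaged
onto patellar faces: the peak over faces and the area-weighted mean over
faces above the 271 kPa inclusion threshold (without the threshold the
mean would be diluted by the low-stress periphery; if nothing passes, the
mean is reported absent, not zero). Contact area sums undeformed patellar
face areas with pressure above a 1e-6 MPa numeric floor - the threshold
rule is deliberately *not* applied to area, though a thresholded variant
is exposed. Von Mises equivalent stress (`sqrt(3 J2)`) is computed per
element and summarized over elements adjacent to either the articular
(chondro-chondral) or the bone (chondro-osseous) interface of either
body - the source study's text and figure captions disagree on which
interface is meant, so both are first-class outputs. Alignment indices
follow the clinical conventions: tilt is the axial angle between the bony
transverse axis and BL; bisect offset the percentage of patellar width
lateral to the sagittal plane through the deepest sulcus point; TT-TG the
lateral offset of the tibial tuberosity from that point, so the
postoperative TT-TG drops by exactly the applied lateralization.

## Statistics

The statistical layer reproduces the published workflow: per-angle
tables, pooled mean and sample SD (n-1), percent changes versus
preoperative, two-sided Student or Welch t-tests (raw samples or summary
statistics, the latter for the literature comparison), significance at
p < 0.05, no multiplicity correction (none was applied in the source).
Values print with half-away-from-zero rounding (two decimals for MPa,
integer percents), which is the convention that reproduces the published
rows from the published per-angle values - including the postoperative
"all angles" rows, which pool all 12 values (4 angles x 3 factors).
Computed this way, the healthy mean-pressure row pools to 0.78 while the
published table prints 0.79 (SD agrees), and the two headline p-values
compute to 0.048 and 0.008 against printed 0.047 and 0.007 - the
published versions evidently used unrounded inputs; the recomputed values
are reported as computed.

## Numerical choices and limitations

* Penalty 100 MPa/mm, smoothing 0.01 mm, slip regularization 0.05 mm,
  Newton tolerance 1e-6, ramp 5 steps: chosen for the penalty-insensitive,
  deterministic regime; all configurable.
* The elastic-foundation (Winkler) closed form is used as a contact oracle
  only in its validity regime (thin bonded layer, compressible material,
  contact radius well above thickness): there the FE matches it to a few
  percent, and it matches Hertz on a thick slab within 10%. At the
  cartilage parameter set (nu = 0.47, 3 mm layer, 10 N) the contact radius
  is about 0.6x the thickness and the constrained-to-shear modulus ratio
  is 18, so neither asymptote applies; the FE peak falls between the two
  limits, as mechanics requires.
* Patellar rotations are fixed at the preset tilt (as in the source
  protocol); tilt changes after surgery reported by the source (which
  re-ran its transient positioning) are therefore outside this model's
  reach. The solved postoperative bisect offsets at 30 degrees (67% at
  half and 59% at nominal correction) nevertheless land on the published
  postoperative values (65% and 58%), because the groove, not the
  patella, moves.
* The static protocol has no reachable postoperative equilibrium at 45
  degrees flexion and beyond at default conditions: on the freshly carved
  spur-region groove the load path folds (the patella must pop between
  contact basins), which the omitted transient repositioning phase of the
  source protocol would traverse. Postoperative cells there are reported
  as failed, with per-cell status; postoperative comparisons use the
  fully converged 30-degree solves.
* Linear elasticity, small strain, no biphasic behavior, no menisci, no
  fixation hardware, single synthetic subject pair: inferences are
  comparative, not predictive of absolute patient stresses.
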