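---
title: "Parametric solid models of the pediatric lumbar spine: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric solid models of the pediatric lumbar spine: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

pedspine generates solid-state, tissue-labelled 3D models of pediatric
lumbar vertebrae, intervertebral discs and whole lumbar spines for five
age groups — newborn, infant (0–1 yrs), toddler (1–3 yrs), middle
childhood (4–7 yrs) and preadolescent (8–12 yrs) — from a packaged table
of mean osteometric dimensions (7 linear measurements of the vertebral
body per age group and lumbar level, in mm) and a registry of
linear-elastic tissue properties. This vignette explains the geometric
model, the tunable parameters, the numerical machinery and the design
choices that were genuinely open.

## The solid representation

All solids are closed, consistently oriented triangle surfaces
(`tri_solid`) in mm. We deliberately use triangulated boundary
representations rather than an exact CAD B-rep: booleans are computed on
a sampled signed field of the input surfaces (sign by scanline ray
parity with a three-axis majority vote, magnitude by exact
point-to-triangle distance through a bounding-volume hierarchy) and the
result is re-triangulated by marching tetrahedra on a Kuhn-subdivided
grid. This yields watertight output by construction and exports directly
to STL/OBJ/PLY. The price is a faceting error controlled by two
resolutions:

* `kernel$segments` (default 64 facets per full revolution; chord error
  at vertebral radii is well below 0.05 mm), and
* the boolean field pitch `kernel$voxel` (default 0.3 mm; 0.4 mm for the
  large fused unions of groups 4–5, `kernel$fused_voxel`). Because exact
  distances are stored at the grid nodes, planar and smoothly curved
  faces are reproduced to interpolation error (micrometres), not to the
  voxel size.

Edge rounding ("smoothing of sharp edges") is a morphological opening:
the surface field is eroded and re-dilated by the fillet radius, which
rounds convex edges and corners. A volume-drift guard rejects radii that
would remove more than 15% of the volume. This is not a constant-radius
CAD fillet; the contract is reduced convex sharpness at bounded volume
change, which the tests verify against the closed-form volume of an
opened cube.

## The vertebral body

The body is a loft of planar cross-sections. Each section is a
normalised profile — an oval for newborns, a "sector of a disc" for
infants/toddlers, a "sector of a cylinder" for the older groups, each
with a flat posterior chord where the arch attaches — scaled
anisotropically to the width and depth of its station. The width blend
holds the inferior width (IVBW) over a bottom plateau (15% of the
height), passes exactly through the middle width (MVBW) at mid-height
and reaches the superior width (SVBW) over a top plateau; transitions
are cosine-smooth. Whenever MVBW is the smallest of the three widths
(the middle-childhood and preadolescent records) this automatically
produces the "waist". Depths blend the same way between IVBL and SVBL.

The inferior face is flat; the superior face is a plane calibrated so
that the posterior height station reads PVBH and the anterior station
reads AVBH exactly. The measurement protocol *is* the inverse of the
construction: widths and depths are measured on planes parallel to the
endplates, 0.6 mm inside them (below the rounded rim, still within the
blend plateaus); heights are vertical extents on frontal planes at the
calibrated stations. This is why a correct build reproduces the packaged
table to well within max(0.2 mm, 2%) and why a perturbed input flips the
corresponding report entry.

Endplate detail: central fossae are spherical-cap cutouts (depth
0.05 PVBH, configurable) centred along the endplate normal; rim notches
(groups 3–5, count and depth configurable) are placed away from the
anterior apex and the lateral-most points so they never touch a
measurement station; the preadolescent "step" (ring-apophysis rebate) is
a marginal rebate of depth 0.05 PVBH and inset 5% of the width on both
endplates. For group 5 the width stations shift just deep to the step,
where the rim is interrupted.

## Posterior elements and the foramen

The arch is an extruded ring: an inner canal boundary (an ellipse with
frontal diameter 0.60 MVBW and sagittal diameter 0.80 IVBL; tapered
posteriorly into a triangle-like section for groups 4–5), offset
outward by the pedicle width at the limbs and the plate thickness
posteriorly. The pedicle limbs reach into the body and are trimmed
against it by a boolean, giving a conforming junction. Transverse and
spinous processes are parallelepipeds, scaled per group (rudimentary in
infancy, prominent later); the spinous process slants 15 degrees
caudally in middle childhood and is a short horizontal plate in
preadolescents.

Articular facets are cylindrical: the inferior processes are vertical
ridges (radius 0.45 pedicle width), the superior processes carry a
concave groove whose diameter is not defaulted but solved by bisection
on the measured mesh-to-mesh gap of the mated pair, targeting a nominal
0.3 mm clearance — 60% of the 0.5 mm joint-gap cap, leaving headroom for
the rigid tilts the assembly introduces. Facet geometry is uniform
within an age group (anchored on the L3 record) so that facets of
adjacent levels mate coaxially; with level-wise facet sizes the mating
clearance would drift across a segment by more than the cap.

Component architecture by age:

* group 1 (newborn): the body plus two semi-arches in bone; the bony
  ring is kept 0.4 mm clear of the body and the two cartilaginous
  pedicles (neurocentral junctions) bridge the gap exactly, with a
  midline cartilage strip between the semi-arches — 6 components,
  3 bone + 3 cartilage. Following the anatomy, the *entire* pedicle
  bridge is cartilage rather than a thin interposed film; the midline
  strip uses the configurable thickness (0.15 pedicle width).
* groups 2–3: body + one arch (the midline has ossified) + two
  cartilaginous pedicles — 4 components. The stated L5 exception for
  infants is available as a config flag
  (`arch$group2_l5_midline_cartilage`), off by default so the
  four-component count holds.
* groups 4–5: a single fused bony solid (one n-ary union of all parts
  minus foramen, fossae, notches and, for group 5, the step rebates),
  then edge-rounded.

## The disc and the S1 endplate

A disc is a wedge prism over the mean footprint of its two adjacent
endplates (for L5/S1, the L5 inferior endplate), with a 7-degree
sagittal wedge opening anteriorly (lordotic; the source states the angle
but not the direction) and a posterior height equal to the group's
disc-to-body height ratio times the mean adjacent PVBH. The ratios are
1.0 for newborns (stated: discs as tall as the bodies) and 0.8, 0.6,
0.4, 0.3 for the older groups — a monotone gradient chosen to realise
the qualitative "shorter" to "relatively small" progression; all are
configurable.

The internal cavity (anterior cavity plus posterior recess) must hold
about half the disc volume. Rather than fixing a wall thickness, the
wall is solved by bisection on the measured volume fraction to
0.50 ± 0.005. Because the cavity lies strictly inside the envelope, the
annulus is built exactly as a two-shell solid (outer shell plus inverted
cavity shell) with no re-meshing; its faces are therefore exactly planar
and the wedge angle exact. The nucleus pulposus is built separately from
the cavity shape with a uniform 0.05 mm clearance and inserted; it never
touches the annulus.

The S1 superior endplate is a flat plate matching the L5/S1 footprint,
0.3 L5-PVBH thick, labelled cortical bone.

## Spine assembly

Elements are stacked caudally to cranially: S1 plate, disc L5/S1, L5,
…, L1. The configured total lordosis (0, 0, 15, 25, 30 degrees by
default — the source states only absence in the first two groups and
visible presence later) is distributed equally over the five segments as
rigid rotations about the frontal axis at the disc planes. Two choices
keep the column geometrically consistent:

* each in-spine disc is built so its inferior face conforms to the
  superior endplate below (same slope) and its superior face carries
  exactly the segment rotation, so adjacent faces are parallel; the
  stand-alone disc default (7 degrees) is unchanged and is what the
  disc-level acceptance measures;
* every interface is contact-solved: the new element slides along the
  local axis until its mesh clears the previous one by 0.02 mm
  (`spine$contact_gap_mm`), which satisfies the sub-0.1 mm contact
  invariant without interpenetration for any wedge/tilt combination.

With a straight stack this makes the posterior stack height equal the
arithmetic sum of posterior body heights and disc heights to within half
a millimetre, which the tests verify for the newborn group.

## Validation surface and what it shows

`full_validation()` rebuilds all 25 vertebrae, 25 discs and the
per-group spine and re-measures everything: dimension round-trips,
component counts and tissue labels, watertightness, wedge angle and
cavity fraction, contacts, interpenetration and facet gaps. Perturbation
controls (scaling a model, corrupting one packaged value) flip the
corresponding entries to fail, so the suite is sensitive, not vacuous.

These models are schematic by intention: geometric primitives with
population-mean dimensions, built for finite-element preprocessing,
teaching and morphometric reasoning. Passing the validation shows the
construction is internally consistent and faithful to the packaged
means; it does not make the models patient-specific, and no imaging,
statistical shape variation, ligaments or kinematics are represented.
Problem sizes are kept at desk scale: the default resolutions build a
vertebra in seconds and a full spine in about a minute on one core.

## Known limitations

* Mesh booleans are sampled-field booleans: coincident-face unions are
  robust, but tool surfaces should overlap their targets by a margin
  rather than touch them exactly.
* The arch, process and foramen measurements of the underlying
  osteometric study are not published; their defaults here are
  documented fractions of printed body dimensions and should be treated
  as stand-ins (all are overridable per call).
* The fillet is an opening, not a constant-radius fillet; at the default
  fused-model resolution the rounding radius is only marginally
  resolved.
* Disc wedge angles inside an assembly follow the lordosis model, not
  the stand-alone 7-degree default; the two coincide only when the
  per-segment rotation equals 7 degrees.
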