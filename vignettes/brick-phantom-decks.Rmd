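---
title: "Generating MCNP decks for brick phantom layouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating MCNP decks for brick phantom layouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brickphantom)
```

## The problem

Whole-body counters — shielded gamma-spectrometry facilities that measure
radionuclides inside a person's body — are calibrated with the Saint
Petersburg brick phantom (also known as UPh, or Igor/Olga/Irina): stackable
high-density-polyethylene bricks that are assembled into human-like layouts
and loaded with rod-shaped sealed radionuclide sources through drill holes
in their front faces.  Reproducing such a calibration in a Monte-Carlo
radiation transport code requires (a) the analytical geometry of every brick
in the user's layout and (b) a volumetric source definition that samples the
rod sources with the correct relative probabilities.  Writing that input
deck by hand is error-prone for anything beyond a couple of bricks; this
package generates it from a layout drawn in any LDraw-capable brick editor.

Two brick types exist: **full** bricks of 16.5 cm x 11 cm x 5.5 cm and
**half** bricks of 16.5 cm x 11 cm x 2.75 cm.  Their edges stand in ratios
6:4:2 and 6:4:1 of 2.75 cm, the half-brick thickness.  That length is the
smallest dimension in any layout and therefore serves as the unit of the
placement lattice: every brick pose is an integer lattice index plus one of
the 24 proper cube rotations.

## Segmentation model

Each brick is decomposed into cubic segments of (2.75 cm)^3: 6 x 4 x 2 = 48
segments for the full brick and 6 x 4 x 1 = 24 for the half brick.  In the
MCNP deck each brick type is written once, as a *template universe* built
from `rpp` (box) and `rcc` (cylinder) macro-bodies: the polyethylene body,
the four source drill holes, the rod active sections (and inactive plugs
when configured), and the connector blind holes on the side faces.  Each
segment is its own universe containing a single (2.75 cm)^3 window cell
filled with the template universe under a per-segment translation, so a
segment shows exactly its part of the brick geometry.  The layout then
becomes one `LAT=1` lattice cell with a fully specified `FILL` array over
the bounding box of the occupied cells: occupied elements reference the
segment universe that belongs there (with a shared `TR` card when the brick
is rotated — at most 23 of them, one per non-identity orientation), empty
elements reference a background air universe.  Compared with a voxel
phantom this keeps the exact cylindrical surfaces of holes and sources and
uses orders of magnitude fewer volume elements.

## Source model

Every rod source sits flush with the front face of its brick and extends
along the brick thickness.  The sampling rules implemented are:

* **Between sources**: all rod sources in full bricks are sampled with equal
  probability; a rod source in a half brick gets exactly half that
  probability.  Implemented as weight = brick thickness / full-brick
  thickness, normalized over all sources, which reduces to the 1 : 0.5 type
  rule for the default bricks and stays a type rule under reconfiguration.
* **Within a source**: spatially uniform.  Each source is split over the
  lattice segments its active section traverses; a segment's share is the
  active length contained in it divided by the total active length.

The emitted `SDEF` block uses a discrete cell distribution (`SI1 L` with
path-form references `rod cell < segment cell < lattice[i j k] < container`,
`SP1` with probability = source weight x segment share) and, per entry,
dependent `X`/`Y`/`Z` distributions that sample uniformly over the
segment-clipped bounding box of the rod cylinder.  MCNP's cell rejection
discards candidates outside the rod cell; because each bounding box is
clipped to its own segment, the acceptance rate is the cylinder-in-box
ratio pi/4 or better.  Rod active sections are air-filled cells: they exist
as sampling targets, so the transport geometry is identical whether or not
a hole holds a source (capsule and active-matrix attenuation are neglected
by default; a custom material can be assigned via the template emitter if
needed).

## Conventions where the hardware leaves choices open

The published description of the phantom fixes brick dimensions, segment
counts, the number of drill holes and the sampling rules, but not the
drill-hole coordinates or rod dimensions of the real bricks.  The following
defaults are package conventions, all overridable from the YAML
configuration:

* **Frames.**  Phantom frame: right-handed, z = stacking axis.  Brick-local
  frame: x spans 16.5 cm, y spans 11 cm, z the thickness; the front face is
  z = 0.  LDraw's y-down frame is mapped via (x, y, z) -> (x, z, -y).
  Lattice cells are half-open `[i*u, (i+1)*u)`, 0-based; a placement's index
  is the minimum-corner cell of its rotated footprint.
* **Source holes** (4 per brick, perpendicular to the front face): radius
  0.4 cm, depth = brick thickness, centres offset (±4.125, ±4.125) cm from
  the face centre.  These offsets put every hole at the centre of a lattice
  column (x in {4.125, 12.375}, y in {1.375, 9.625} cm), so a rod cylinder
  never crosses a transverse column boundary and the axial length-share
  rule is exact.  A configuration that makes a hole straddle a column is
  rejected with a geometry error rather than silently mis-weighted.
* **Rod sources**: radius 0.35 cm, plug length 0, active length = brick
  thickness - plug.  With these defaults the half-brick active length is
  exactly half the full-brick one, so the 1 : 0.5 probability rule coincides
  with length-proportional weighting.
* **Connector blind holes**: one per side face, radius 0.3 cm, depth 1 cm,
  air-filled.  They exist on the real bricks; their dimensions here are
  conventions.
* **Materials**: polyethylene as CH2 at 0.95 g/cm3, air at 1.205e-3 g/cm3.
* **Deck skeleton**: MODE P, a placeholder photon energy of 0.662 MeV
  (Cs-137, a typical whole-body-counting calibration line) and an NPS
  placeholder; users adapt both, as well as tallies and detector models,
  which are deliberately out of scope.
* **Numbering plan** (deterministic): surfaces from 1000, template cells
  from 100 (50-id block per type), segment universes 200 (full) / 400
  (half), segment-universe cells at 5000 + universe, lattice cell 10, world
  container/graveyard/buffer cells 2/3/4, background cell 50, TR cards from
  900, materials 1-2.
* **LDraw scale**: 25 LDU per cm (the standard 0.4 mm LDU), so one lattice
  unit is 68.75 LDU.  Positions are snapped to the lattice; residuals over
  0.01 cm and rotation matrices that do not round to a proper signed
  permutation are errors, because a misaligned layout cannot be meant.

## The canonical fixtures

`generate_canonical_layout()` ships four deterministic layouts.  The
`p70_stretcher` fixture realises the documented 70 kg configuration — 68
full and 4 half bricks — as a lying figure (two six-brick legs, a hip
block, a 3 x 3 torso, two arms, a two-brick-wide head, half bricks as hands
and feet), with a rod source in hole 1 of every brick for a homogeneous
calibration distribution.  The historical record fixes only the brick
counts, not the arrangement, so this arrangement is an invented but frozen
convention; its solid mass at density 1 g/cm3 is 69.8775 kg, and at the
default 0.95 g/cm3 polyethylene density 66.38 kg.  `mini_torso` is a
six-brick smoke test with one rotated brick and two sources; `single_full`
and `single_half` are one-brick layouts.

```{r}
lay <- parse_ldraw(generate_canonical_layout("mini_torso"))
summarize_layout(lay)[1]
```

## The oracle: testing without MCNP

Because running MCNP is out of scope, the package carries an
implementation-independent oracle:

* `voxelize()` rasterizes the analytical layout at a resolution that
  divides 2.75 cm, labelling each voxel by evaluating the constructive
  geometry at its centre (air / polyethylene / hole void / source active /
  plug).  Centre-point labelling has a first-order error bound: the volume
  error of a region is at most its surface area times the resolution, which
  the tests check at two resolutions (0.275 and 0.1375 cm) to confirm the
  convergence order.  Grid-aligned solid boxes are exact by construction.
* `sample_source_points()` draws seeded source positions by the same
  scheme the SDEF cards describe (entry selection from the discrete
  probabilities, uniform box sampling, cylinder rejection).  Tests compare
  per-entry counts against the SP probabilities within 3-sigma binomial
  bounds at n = 1e5 and the axial distribution against uniformity with a
  Kolmogorov-Smirnov test at alpha = 0.01.  Sampling uses R's default
  Mersenne-Twister generator; the default seed is 20210828.

What the oracle does *not* show: agreement with measured counting
efficiencies, detector response, or the behaviour of the deck inside MCNP
itself (syntax acceptance is ensured structurally — three blank-line-
separated blocks, 78-character wrapped cards with 5-blank continuations,
and a reference-closure linter that verifies every referenced surface,
cell, universe, transform and material id is defined exactly once).

## Numerical and design choices

* Orientations are validated as signed permutation matrices with
  determinant +1; reflections are rejected (a physical brick cannot be
  mirrored).  Composition stays inside the 24-element group, which the
  tests enumerate.
* Collision detection works on exact integer cell sets, so "adjacent" never
  becomes "overlapping" through floating-point drift; segmentation itself is
  validated against brute-force rasterization of the rotated brick box.
* `layout_mass()` deliberately ignores the drill-hole voids (solid-brick
  approximation) because hole dimensions are conventions; the summary
  report says so explicitly.
* Layouts with several sources per brick are unrepresentable by
  construction: the part catalog encodes at most one source hole per part.
  The documented workaround for multi-source bricks is one deck per source
  with results combined afterwards.
* Property-style suites run on seeded generated layouts: 200 random
  collision-free layouts of 5 bricks for occupancy/round-trip/FILL checks,
  30-seed segmentation-vs-rasterization comparisons, and 1e5-point sampling
  checks.  These sizes keep the default test run around twenty seconds while
  leaving the binomial bounds tight enough to be meaningful.

## Limitations

* Placement is lattice-only: positions snap to 2.75 cm and angles to 90
  degrees.  Inclined assemblies (e.g. a phantom on a reclined chair) are
  composed manually from several generated decks, as with the original
  workflow; this is documented, not automated.
* One rod source per brick.
* The generated deck is a calibration-phantom skeleton: no tallies,
  detectors, variance reduction or physics options beyond MODE P.
* MPD (multi-model) LDraw documents are rejected; export flat `.ldr` files.
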