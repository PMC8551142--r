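# brickphantom

Generate ready-to-run MCNP6 input decks for user-defined layouts of the
Saint Petersburg brick phantom — the stackable high-density-polyethylene
calibration phantom (UPh, also known as Igor/Olga/Irina) used at whole-body
counting facilities, whose bricks carry drill holes for rod-shaped sealed
radionuclide sources.

## What it does

A layout is drawn in any LDraw-capable brick editor (e.g. Bricklink
Studio, exporting a flat `.ldr` file) using this package's part catalog:
`uph_full.dat` / `uph_half.dat` for source-free bricks and
`uph_full_s1..s4.dat` / `uph_half_s1..s4.dat` for bricks with a rod source
in drill hole 1–4.  The two brick types measure 16.5 × 11 × 5.5 cm (full)
and 16.5 × 11 × 2.75 cm (half); their edges stand in ratios 6:4:2 and 6:4:1
of the 2.75 cm lattice unit, the smallest length in any layout.

From the parsed layout the package builds:

* **Geometry** — each brick type is written once as a template universe of
  `rpp`/`rcc` macro-bodies (body, four source drill holes, rod active
  sections, connector blind holes) and decomposed into 6 × 4 × 2 = 48
  (full) or 6 × 4 × 1 = 24 (half) cubic segment universes of (2.75 cm)³.
  The layout becomes one `LAT=1` lattice cell with a fully specified `FILL`
  array; rotated bricks share per-orientation `TR` cards.
* **Source definition** — an `SDEF` block with a discrete cell distribution
  over all rod-source segments.  Sources in full bricks are equally
  probable and a half-brick source gets exactly half that probability;
  within a source, sampling is spatially uniform (per-segment share =
  contained active length / total active length), realised with uniform
  bounding-box position distributions plus MCNP cell rejection.

A voxelization and Monte-Carlo sampling oracle validates volumes, overlaps
and sampling probabilities without running MCNP, and an internal linter
proves that every referenced surface/cell/universe/transform/material id in
a generated deck is defined.

## Worked example

```r
library(brickphantom)

lay <- parse_ldraw(generate_canonical_layout("mini_torso"))
lay
#> <brick_layout> 6 placements (5 full, 1 half), 2 with rod sources

cat(summarize_layout(lay), sep = "\n")
#> 5 full, 1 half, 2 sources, extents 12x8x4
#> bricks: 5 full, 1 half
#> rod sources: 1 in full bricks, 1 in half bricks
#> lattice extents: 12 x 8 x 4 cells (33 x 22 x 11 cm)
#> solid mass at 0.95 g/cm3: 5.21585625 kg (drill holes ignored)
#> collisions: none

deck <- build_deck(lay)
deck
#> <mcnp_deck> 'brick phantom: 5 full + 1 half bricks on a 2.75 cm lattice':
#>   111 cell, 30 surface, 31 data cards
writeLines(serialize_deck(deck), "mini_torso.i")   # the MCNP input file

dist <- build_source_distribution(lay)
dist$entries[, c("pid", "brick", "hole", "ci", "cj", "ck", "share", "prob")]
#>    pid brick hole ci cj ck share      prob
#> 1 p001  full    1  1  0  0   0.5 0.3333333
#> 2 p001  full    1  1  0  1   0.5 0.3333333
#> 3 p006  half    2 10  0  2   1.0 0.3333333
```

The full-brick rod spans two lattice segments (half its 5.5 cm active
length in each), the half-brick rod one segment; the half-brick source's
total probability (1/3) is exactly half the full-brick source's (2/3).
Cross-check by sampling:

```r
s <- sample_source_points(dist, n = 1e5, seed = 20210828)
s$counts
#> [1] 33312 33354 33334
```

The deck's `SP1` card carries the same 1/3 probabilities, and the sampled
counts reproduce them within statistical noise.

Parameters such as the photon energy (placeholder 0.662 MeV) and the number
of histories, as well as detector geometry and tallies, are adapted in the
generated file by the user.

## Command line

```sh
Rscript inst/cli/brickphantom.R fixture -i p70_stretcher -o p70.ldr
Rscript inst/cli/brickphantom.R build -i p70.ldr -o p70.i -s p70_summary.txt
Rscript inst/cli/brickphantom.R check -i p70.ldr
Rscript inst/cli/brickphantom.R summarize -i p70.ldr
```

Exit codes distinguish parse (2), collision (3), orientation (4),
configuration (5), I/O (6) and geometry (7) failures.  All dimensions,
materials and id-numbering bases are overridable from a YAML file passed
with `--config`; see `?default_config`.

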