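Package: brickphantom
Title: MCNP Input Decks for Saint Petersburg Brick Phantom Layouts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts LDraw-format layouts of the Saint Petersburg brick
    phantom (the stackable high-density-polyethylene calibration phantom used
    at whole-body counting facilities, with drill holes for rod-shaped sealed
    radionuclide sources) into ready-to-run MCNP6 input decks.  Bricks are
    decomposed onto a 2.75 cm lattice into cubic segments realised as MCNP
    universe/fill combinations over a fully-specified lattice, and the rod
    sources become a volumetric SDEF definition with per-segment sampling
    probabilities and cell rejection.  A voxelization and sampling oracle
    allows the generated geometry and source distribution to be validated
    without running MCNP.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
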