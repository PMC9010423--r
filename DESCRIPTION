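Package: gasbind
Title: Noble-Gas Binding-Site Analysis for Membrane Proteins
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how noble gases (argon, krypton, xenon) bind
    to membrane proteins embedded in a crystal lattice or a lipid bilayer.
    Classifies crystallographic gas sites into internal-cavity, lipid-facing
    surface and crystal-contact groups using an exterior flood-fill burial
    test and crystal-symmetry expansion; accumulates time-averaged gas
    occupancy grids from aligned trajectory frames; detects density peaks
    above a mean + k*sigma threshold, matches them to crystallographic
    sites, clusters them hierarchically and converts peak densities into
    binding free energies via the Boltzmann relation; and quantifies the
    damping of protein dynamics by bound gas through anisotropic
    elastic-network (ANM) normal-mode analysis with gas atoms included as
    network beads. Ships synthetic generators (helical bundles, planted gas
    sites, Gaussian-blob density grids, dwell/hop trajectories) with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
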