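Package: mfepath
Title: Minimum Free Energy Paths by the On-the-Fly String Method with
    MBAR Reweighting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Engine-agnostic machinery for locating minimum free energy
    paths (MFEPs) in a linear collective-variable space and for computing
    free energies and observables along them.  Provides analytic model
    potentials with a seeded overdamped Brownian sampler, linear
    collective-variable maps built from Kabsch superposition and combined
    principal component analysis of structure ensembles, the on-the-fly
    string method with equal-arc-length reparametrization, umbrella
    sampling around string images, a multistate Bennett acceptance ratio
    (MBAR) solver with asymptotic uncertainties, Voronoi-tessellated
    potentials of mean force with ellipsoidal cell-volume correction,
    per-cell average structures, fluctuations and reweighted densities,
    and committor-style transition-state diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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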