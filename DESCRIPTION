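Package: dhpmd
Title: Diphasic High-Pressure Molecular Dynamics Screening of Enzyme Mutants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening stabilizing enzyme mutants from molecular
    dynamics snapshots collected over a pressure by cosolvent condition grid.
    Computes per-region isothermal compressibility from Voronoi volume
    fluctuations under periodic boundary conditions, ranks "sensitive
    fluctuation" regions across conditions, enumerates virtual saturation
    mutants and applies a dual-predictor consensus folding free-energy filter.
    Also provides trajectory flexibility analysis (RMSD/RMSF after Kabsch
    superposition), cosolvent hydration-shell counting, polar/apolar
    solvent-accessible surface area, geometric hydrogen-bond detection, and
    Michaelis-Menten enzyme kinetics arithmetic, together with seeded
    synthetic-data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
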