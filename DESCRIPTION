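Package: mcdock
Title: Massively Parallel Monte-Carlo Molecular Docking with BFGS Pose Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A portable, testable implementation of a massively parallel,
    reduced-depth Monte-Carlo iterated local search for protein-ligand docking.
    Ligand conformations are parameterized by position, orientation (unit
    quaternion) and rotatable-bond torsions; poses are scored with an
    AutoDock-Vina-style empirical potential evaluated through a precomputed
    receptor energy grid with trilinear interpolation, and locally optimized
    with a BFGS quasi-Newton minimizer.  Includes a PDBQT torsion-tree
    reader/writer, a Vina-style config parser, deterministic synthetic
    receptor/ligand fixtures with a planted minimum-energy pose, host-side
    clustering and grid-free refinement of top poses, virtual-screening
    rank-comparison utilities, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
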