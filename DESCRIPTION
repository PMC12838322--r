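Package: StabScan
Title: Structure-Based Thermostabilization Candidate Scanning for Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Structure-based screening of candidate stabilizing mutations for
    proteins, modelled on the design workflow used for thermostable
    subtilisin-like proteases. Implements a fixed-width PDB reader/writer with
    an explicit altloc and metal-ion policy, exact 3-D geometry primitives,
    a deterministic sphere-point (Shrake-Rupley style) solvent-accessible
    surface area engine with Gly-X-Gly relative solvent accessibility,
    salt-bridge and long-range ion-pair detection with ionic-network assembly,
    beta-turn detection and typing from backbone dihedrals with Type I turn
    i+1 proline candidate proposal, calcium-site coordination analysis and
    graft verification, a surface Asp/Glu substitution scan, multi-predictor
    consensus mutation selection, and a synthetic-structure builder that
    plants ground-truth features (salt bridges, turns, burial, coordination
    shells) for end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
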