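Package: abkit
Title: Antibody Fv Template Curation, Constraints, Fold-Tree Kinematics
    and Benchmark Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for antibody variable-fragment (Fv) homology-modeling
    infrastructure. Curates a per-region, per-length structural template
    database from Chothia-numbered antibody crystal structures with explicit
    quality filters (resolution, backbone geometry, occupancy, conserved
    anchor residues, chainbreak detection, sequence non-redundancy); selects
    templates per structural region by local alignment with BLOSUM62/PAM30
    conventions and exclusion/proline filters; builds automatic
    glutamine-glutamine flat-harmonic distance constraints and K-of-N
    composite constraints with Rosetta-compatible serialization; models
    multi-chain complexes with linear and hierarchical fold trees using
    virtual residues at centers of mass; and evaluates models with
    per-region backbone RMSD and the backbone-dihedral chord-distance
    fragment-similarity metric. Includes a deterministic synthetic-fixture
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
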