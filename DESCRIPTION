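Package: ploopkit
Title: Walker-A P-Loop Detection, Grafting and Nucleotide-Site Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for engineering nucleotide-binding sites at pseudo-active
    sites of P-loop NTPases. Detects Walker-A P-loop motifs in protein
    structures by three conserved features (amino-acid sequence
    G-X1-X2-X3-X4-G-K-[T/S], ABEGO backbone-torsion pattern EBBGAGAA, and the
    orientation of the conserved lysine relative to the preceding strand
    residue), surveys motif statistics over structure sets, grafts a donor
    P-loop backbone onto an acceptor pseudo-loop by rigid superposition,
    evaluates nucleotide phosphate placements against flat-bottom distance
    constraints, and filters design candidates by torsion-pattern retention
    and a binding-score threshold. Includes a seeded synthetic-backbone
    generator (internal-coordinate construction from dihedral specifications)
    so the full pipeline runs without structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
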