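Package: polbind
Title: Design and Quantitative Evaluation of DNA-Binding-Enhanced Y-Family
    DNA Polymerase Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end desk-scale workflow for engineering tighter
    DNA binding into a Y-family DNA polymerase (Dbh-like translesion
    polymerases). Identifies protein residues in the DNA contact shell of a
    polymerase-DNA complex, classifies conserved versus non-conserved
    positions from a multiple sequence alignment and ranks substitutions by
    homolog frequency, scores wild-type and mutant complexes with a
    deterministic per-DNA-chain molecular-mechanics binding-energy surrogate
    and aggregates mutant-minus-wild-type differences, and analyses the
    downstream quantitative assays: hyperbolic equilibrium titrations
    (dissociation constants), single-nucleotide-insertion Michaelis-Menten
    kinetics (catalytic efficiencies, fold changes, misinsertion fidelity),
    and gel-densitometry processivity percentiles under single-hit trap
    conditions. Seeded synthetic-data generators emulate every input so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
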