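Package: negcon
Title: Negative Constraints on Interaction Specificity in Paralog Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies "negative constraints" -- interfacial residues that
    selectively destabilize non-cognate complexes -- in paralog protein
    families partitioned into interaction-specificity subgroups (such as the
    Drosophila DIP/Dpr adhesion receptors). Combines an energy filter over
    externally computed mutational binding free-energy changes (ddG tables,
    e.g. from a FoldX scan) with an evolutionary filter over subfamily
    multiple sequence alignments (base-21 Shannon entropy conservation,
    biophysical-property and size-class percent differences), enumerates
    non-cognate subgroup pairs, and intersects both filters into per-position
    constraint calls. Includes a seeded synthetic-data generator that plants
    ground-truth constraints in subfamily alignments and ddG tables so the
    full pipeline can be validated by precision/recall recovery, plus
    conversion of dissociation-constant ratios to binding free-energy
    differences for comparison with surface plasmon resonance measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
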