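Package: famHotspot
Title: Mutation Hotspot Discovery on Protein-Family Consensus Alignments
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pools somatic mutations from members of a protein family onto the
    consensus of a multiple sequence alignment and statistically detects
    mutational hotspots shared across the family, including members mutated at
    low frequency. The global mutational profile is tested for departure from
    randomness via Shannon entropy against a coverage-weighted multinomial
    bootstrap null with a fitted Gamma distribution; per-position hotspot
    p-values come from per-column Gamma nulls and are gated by a Trident
    conservation score before Benjamini-Hochberg correction. Mutual exclusivity
    and co-occurrence of mutated genes or consensus positions across tumor
    samples is assessed with an exact hypergeometric co-occurrence model.
    Includes a synthetic family and cohort generator with planted ground truth.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    MASS,
    knitr
Config/testthat/edition: 3
biocViews: SomaticMutation, Alignment, MultipleSequenceAlignment,
    StatisticalMethod, Software
RoxygenNote: 7.3.3
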