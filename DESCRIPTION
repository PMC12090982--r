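Package: glycomine
Title: Compositional Classification and Ontology Enrichment of Released N-Glycans
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mining released N-glycan compositional annotations from
    MALDI mass spectrometry imaging experiments. Parses compositional strings
    such as "Hex:5 HexNAc:4 dHex:1", computes neutral monoisotopic masses and
    singly charged adduct m/z values for annotation and lock-mass checks,
    classifies each composition into structural classes (pauci-mannose,
    high-mannose, hybrid, complex, and decorations such as fucosylated,
    sialylated, bisecting, tetra-antennary, polylactosamine) through an
    explicit numeric rule system, and performs ontology-style term enrichment
    (Fisher exact, EASE-adjusted Fisher, binomial, rank-based
    Kolmogorov-Smirnov) with multiple-testing adjustment. Includes region-level
    class-frequency summaries for anatomically annotated glycan sets, a toy
    ion-image co-localization path, synthetic fixture generators, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
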