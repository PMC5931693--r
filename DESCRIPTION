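Package: gainloss
Title: Regional DNA Gain and Loss Between Diverged Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and maps lineage-specific DNA gain and loss events between two
    diverged genomes from UCSC-style pairwise alignment nets. Parses nets into
    chain-blocks and chain-gaps, builds outgroup-supported ancestral elements,
    classifies transposon families as recent or ancestral with a two-feature linear
    discriminant, annotates chain-gaps as gain or loss by two complementary methods,
    places annotated gaps into the partner genome to build a synthetic coordinate
    system, calls gain/loss hotspots with the Getis-Ord local statistic under FDR
    control, tests feature enrichment by permutation and hotspot overlap by Fisher's
    exact test, and dates events against ordered ingroup panels. A forward simulator
    of two-lineage turnover histories supplies alignments, repeat tables and ground
    truth so the full pipeline can be exercised and scored without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
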