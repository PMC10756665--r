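Package: ysrna
Title: Split-Half Quantification and Terminal-Chemistry Inference for
    YRNA-Derived Small RNAs
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for profiling YRNA-derived small RNAs (YsRNAs) in
    small-RNA sequencing libraries. Loads YRNA homolog references, splits
    each into a 5' and a 3' half to neutralise the stem complementarity of
    the source RNA, quantifies reads by exact full-read containment in the
    halves, and normalises counts to reads per million alignable sequences.
    Infers 5' (monophosphate vs triphosphate) and 3' (2'-O-methyl
    protection) terminal chemistry of fragment classes from differential
    representation across periodate-oxidation/beta-elimination, PNK, and
    RppH treated libraries. Ships a seeded synthetic-library generator that
    models fragment origin, terminal chemistry, the four treatment
    operators, adapter-ligation eligibility and 50-nt size selection, so
    the whole pipeline is testable end to end with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
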