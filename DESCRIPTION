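Package: myzaphid
Title: Interval-Based Identification Engine for the Rose Aphids of the
    Genus Myzaphis and Relatives
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A taxonomic knowledge base and identification engine for the
    rose-feeding aphid genus Myzaphis (Hemiptera: Aphididae) and the related
    genera Ericaphis and Richardsaphis.  Bundles per-species, per-morph
    morphometric interval profiles (linear measurements in mm, morphometric
    ratios, setal and sensorial counts, categorical states) in two layers
    (verbatim transcription and a curated layer with documented corrections),
    executable dichotomous keys with explicit ambiguity semantics, a
    multi-access interval identifier, a pairwise diagnosability analyzer,
    a consistency audit, and a seedable synthetic-specimen generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
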