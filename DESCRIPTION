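Package: scaffeval
Title: Evaluation of Mate-Pair Scaffolding for Highly Repetitive Chromosome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate the effect of mate-pair scaffolding on fragmented
    shotgun assemblies of repeat-rich chromosomes, such as flow-sorted wheat
    chromosome arms amplified by multiple displacement amplification (MDA).
    Provides mate-pair orientation and insert-size classification, assembly
    contiguity statistics (N50, length filtering, coverage arithmetic), a
    reference-protein hit-filtering pipeline with total and adjusted gene
    coverage and a Gene Fragmentation Index, a synteny-based scaffold
    reliability bootstrap test, a BAC-concordance Scaffold Reliability Index,
    and a ground-truthed synthetic data generator that emulates repeat-driven
    assembly fragmentation and MDA chimera artifacts in mate-pair libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
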