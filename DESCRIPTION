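Package: tailend
Title: Resolving 3'-End Distributions of Ultrashort RNAs from Tailed RNA-Seq Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the 3'-end length distributions of
    ultrashort RNAs (such as bacterial 6S RNA-derived pRNAs) from small
    RNA-Seq libraries built by 3'-homonucleotide tailing or 3'-adapter
    ligation. Provides tail-signature trimming, exact anchored 3'-end
    profiling against target sequences, a deterministic four-case merge of
    two differently tailed libraries that resolves homopolymer-induced
    ambiguities, simulation of the profile a tailed library would report
    from a reference distribution, and a seedable synthetic read generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stringr,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
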