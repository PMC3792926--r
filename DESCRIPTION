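Package: dnafuse
Title: DNA-Based Semantic Annotation Fusion and Archival Encoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An in-silico toolkit for DNA-computing approaches to merging
    multi-source semantic annotations. Property annotations of data objects
    are encoded as 48-nt oligonucleotides over a degenerate two-bases-per-bit
    alphabet, assembled into a layered property network whose Start-to-End
    paths are candidate complete records, and fused by a simulated
    splinted-ligation reaction followed by Adleman-style screening
    (prefix/suffix/length/substring separation on a multiset "tube" of
    strands). Also provides an address-tagged archival block codec for
    arbitrary byte streams (128 data bits plus a 32-bit address per 200-nt
    oligo) and closed-form DNA storage-density calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
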