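Package: teloatlas
Title: Telomeric Repeat Variant Atlas from HiFi-Like Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling the hypervariable composition of plant
    telomeric repeat arrays from accurate long reads. Simulates chromosome-end
    truth structures and HiFi-like reads with quality-dependent homopolymer
    indel errors; anchors reads to chromosome ends by unique flank sequence;
    detects the repeat-array start and tokenizes tracts into repeat units with
    a dynamic-programming segmentation against the canonical TTTAGGG unit;
    models per-read indel density in the terminal canonical region via
    hill-climbing over ideal canonical arrays; builds per-end consensus unit
    arrays, unit catalogs and saturation curves; annotates higher-order
    repeats and monomer homogenization; and derives repeat-compression
    haplotype distance matrices, neighbor-joining trees of non-coding flanks
    and the associated statistical comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    vegan,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
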