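Package: ctcfscreen
Title: Screening CTCF Co-Binding and Loop-Promoting Factors from Peak and
    Loop Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for screening protein factors that
    co-localize with CTCF and promote CTCF-mediated chromatin loops.
    Builds conserved CTCF binding-site references from multi-cell-type
    ChIA-PET peak sets and a ChIP-seq compendium, screens factors by
    stringent summit-resized overlap ratios, merges peaks into candidate
    regulatory modules and clusters them by co-binding density, computes
    anchor-level loop strength from ChIA-PET/HiChIP loops with Wilcoxon
    and stratified-correlation screens, aggregates factor pairs at paired
    loop anchors into a weighted network, calls differential loops
    between two conditions, and classifies CTCF loops against
    enhancer-promoter loops into five positional categories. Includes a
    fully parameterized synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
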