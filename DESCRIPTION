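Package: introcov
Title: Mapping Alien Chromatin Introgressions from Low-Pass GBS Read Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterises the chromosome constitution of interspecific
    introgression lines (e.g. wheat-barley centric fusion lines) from
    low-pass genotyping-by-sequencing read coverage. Reads mapped to a
    concatenated "in silico hybrid" reference of the two parental genomes
    are counted in 1-Mb bins, normalized so euploid bins centre near 1,
    classified present/absent with threshold-plus-smoothing segmentation,
    and interpreted into compensating Robertsonian translocation calls,
    deletion calls, introgression summaries and pericentric-inversion
    inference from complementary carrier lines. A seeded gamma-Poisson
    coverage simulator with packaged translocation-line scenarios
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
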