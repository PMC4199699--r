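Package: introgramap
Title: Marker-Based Analysis of Interspecific Wheat Introgression Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the molecular-marker analysis of wide crosses between the
    diploid wheats Triticum monococcum (genome Am) and T. urartu (genome Au):
    reconstruction of Am/Au mosaic chromosomes from dominant (AFLP-type) marker
    segregation anchored to a backbone linkage map, two-point recombination
    estimation for codominant and dominant markers with LOD-gated grouping and
    the Kosambi mapping function, donor-segment calling and nonredundant
    introgression-line panel selection with map coverage reports, AFLP diversity
    analysis (pairwise distances, principal coordinates, species-specific locus
    counts), macrocolinearity comparison of two genetic maps, fertility
    arithmetic and transgressive-trait tests, and a forward cross simulator with
    known ground-truth chromosome paintings for validating every inference step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
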