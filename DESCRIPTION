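Package: hypermutr
Title: Germline Hypermutation Analysis in Parent-Offspring Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying germline de novo mutation (DNM) rates in
    sequenced parent-offspring trios: filtering candidate DNM calls with
    cohort-style read-depth and allele-balance rules, read-backed
    parent-of-origin phasing, identity-link negative-binomial modelling of
    DNM counts against parental age, detection and characterization of
    hypermutated individuals, 96-channel mutational-spectrum construction
    with non-negative least-squares signature refitting and small-scale NMF
    extraction, decomposition of count variance into parental-age, data
    quality and hypermutation components, and analysis of parental
    pre-conception cancer/chemotherapy exposure. A synthetic trio-cohort
    generator with known ground truth makes every stage testable without
    access to managed clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
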