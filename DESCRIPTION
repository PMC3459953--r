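Package: famexome
Title: Familial Exome Candidate Gene Discovery with Pedigree
    Co-Segregation and Carrier Burden Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rare-variant candidate gene discovery in multiplex
    cancer pedigrees from germline exome variant calls. Implements a
    confidence and annotation filtering cascade for post-GATK calls
    (call quality, read depth, variant allele fraction, bidirectional
    strand support, database membership, cohort recurrence, deleterious
    consequence classes), intra-family shared-variant and cross-family
    recurrent-gene prioritization, HGVS coding-DNA parsing with protein
    consequence classification on transcript sequences, a
    retrospective-likelihood co-segregation Bayes factor computed by
    pedigree peeling under a two-point penetrance model, and exact
    case-control carrier burden statistics. A seeded simulator generates
    multi-generational pedigrees with a rare causal allele segregating
    under incomplete penetrance and phenocopies, emitted as VCF/PED so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    stats,
    utils,
    vcfR,
    Biostrings,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
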