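Package: bcrcsf
Title: Clonal and Maturation Analysis of Cerebrospinal-Fluid B Cell Receptor Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-cell B cell receptor (BCR) repertoires
    from cerebrospinal fluid in antibody-mediated encephalitis. Implements
    clonal inference by junction Hamming-distance clustering, founder
    identification, unmutated-common-ancestor (UCA) reconstruction by germline
    reversion, peripheral-versus-intrathecal maturation contrasts, clone-size
    stratified autoantigen-specificity enrichment with exact contingency
    testing, intrathecal antibody index and IgG subclass summaries,
    reference-correlation cell-state classification, and a V(D)J
    recombination simulator with somatic hypermutation that provides full
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    seqinr,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
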