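Package: cnasig
Title: Consensus Copy-Number Alteration Signatures from Targeted Panel Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction, consensus merging, and refitting of somatic
    copy-number alteration (CNA) signatures from sparse targeted-panel
    segment data. Segments are encoded into a 28-category feature space
    (copy-number state by segment length), candidate signatures are
    extracted with four complementary deconvolution backends (NMF,
    non-negative ICA, graph-Laplacian-regularized NMF, and a truncated
    hierarchical Dirichlet process sampler), merged by validated
    consensus clustering with bootstrap stability diagnostics, and
    refit into new samples by non-negative least squares with
    per-sample quality control. Includes downstream association
    statistics (fraction of genome altered, alteration-activity tests,
    enrichment, progression odds ratios) and a synthetic cohort
    generator with planted signature structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    cluster,
    pracma,
    glmnet,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
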