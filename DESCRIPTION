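Package: cernet
Title: Inference of Cancer-Associated Competing Endogenous RNA Networks
Version: 0.1.0
Authors@R: person("cernet", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Infers cancer-associated competing endogenous RNA (ceRNA)
    interaction networks from matched multi-omics matrices (miRNA, mRNA and
    lncRNA expression, gene-level copy number, promoter methylation and
    transcription-factor expression). Candidate miRNA regulators of each
    differentially expressed RNA are selected by repeated LASSO regression with
    a one-standard-error rule, stability-selection frequency filtering and a
    bootstrap confidence-interval filter; RNA pairs sharing selected miRNA
    regulators are then screened by Pearson correlation, a hypergeometric
    shared-regulator test and a sensitivity (partial) correlation filter with
    an empirical resampling null. Includes degree-distribution, modularity and
    gene-set-enrichment characterization of the inferred network, a
    knockdown-based evaluation metric (ratio fold change and network accuracy),
    and a synthetic multi-omics generator with planted regulatory and ceRNA
    structure so that the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
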