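Package: csdnet
Title: Conserved, Specific and Differentiated Gene Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential gene co-expression analysis across two conditions.
    Computes full-sample Spearman correlations per gene pair together with a
    subsampling-based standard error from pair-unique sample subsets, scores
    every pair as conserved (C), specific (S) or differentiated (D), selects
    per-score cutoffs at a common importance level by sampled maxima, and
    assembles a unified typed co-expression network. Includes node-homogeneity
    and hub reporting, topology diagnostics against degree-preserving null
    models, reference-network comparison utilities, hypergeometric gene-set
    enrichment, and a synthetic signed-regulatory-network benchmark that
    evaluates score rankings by ROC/AUC against known perturbations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
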