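Package: sizeScaling
Title: Cell-Size Scaling Analysis of Transcriptomes and Metabolomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Correlates every transcript and metabolite with a continuous
    cell-size gradient (relative nuclear radius) across a two-genotype,
    two-timepoint liver regeneration design, and summarises the resulting
    size-scaling behaviour at the gene-set level. Provides per-feature
    Pearson correlations with Fisher-z confidence intervals and
    Benjamini-Hochberg adjustment, largest-versus-smallest-cell fold
    changes, binned gene-set scaling profiles compared to a size-normalised
    whole-cell background by two-sample Kolmogorov-Smirnov tests, lipid-class
    summaries, connectivity enrichment of size-correlated genes on a protein
    interaction network against a random-gene-set null, and an overlap
    analysis separating genotype effects from size effects. A synthetic-data
    generator with planted size-coupled signal makes the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
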