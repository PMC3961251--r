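Package: biclustbench
Title: Benchmarking Framework for Biclustering of Gene Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluation framework for biclustering and one-way clustering
    methods on gene expression matrices. Implements Dice/Sorensen overlap
    scores, a greedy-matching sample-differentiation benchmark (SampleDif),
    resampling-based tissue-specific gene-set significance (TiGER-Sig), and
    Gene Ontology style enrichment significance via Fisher's exact test with
    Westfall-Young minP adjustment (GO-Sig). Ships reference implementations
    of the Cheng-Church mean-squared-residue algorithm, Bimax inclusion-maximal
    binary bicluster enumeration, an xMOTIF-style constant-interval search,
    k-means and hierarchical clustering adapters, the standard result filters,
    a versioned exchange format for importing results from external tools, and
    a synthetic multi-tissue expression simulator with planted ground truth so
    every benchmark is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
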