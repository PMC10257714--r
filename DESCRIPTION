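Package: proteoFR
Title: Proteome-Level Functional Redundancy of Microbiome Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies within-sample functional redundancy of microbiome
    samples at the proteome level. Builds weighted bipartite taxon-function
    networks from metaproteomic protein-group and peptide tables (proteomic
    content networks, PCNs) and from metagenomic gene tables (genomic content
    networks, GCNs), computes weighted Jaccard functional distances, Gini-Simpson
    taxonomic diversity, Rao quadratic-entropy functional diversity and the
    derived functional-redundancy indices FR and nFR, characterises network
    topology (connectance, degree distributions, NODF nestedness), generates
    GCN-constrained degree-preserving null networks, compares distance
    distributions across sample groups (Jensen-Shannon divergence, rank-sum
    tests), and simulates community assembly under a MacArthur consumer-resource
    model with cross-feeding. A synthetic-data generator with controllable
    nestedness and weight structure makes the full pipeline testable without
    mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
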