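Package: pathdiffcorr
Title: Differential Gene-Pair Correlation Analysis Within KEGG Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovers condition-specific (differential) correlations of gene
    expression within biological pathways. For every interacting gene pair a
    least-squares line is fitted per condition and gross outlier samples are
    discarded (squared residual above mean + 3 SD, retaining at least 80% of
    samples), Pearson correlation is computed on the retained samples and
    classified against a +/-0.45 threshold, and pairs whose between-condition
    correlation difference falls outside AVG +/- 3 SD of all pair differences
    are selected as differentially correlated. Interacting pairs are parsed
    from KEGG KGML pathway XML files and mapped to probes through an
    annotation table. The pairwise computation runs as independent chunks on
    a local worker pool with a deterministic combine. Includes readers for
    tab-delimited and GEO series-matrix expression data and a synthetic
    two-condition data generator with planted correlations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    parallel,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
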