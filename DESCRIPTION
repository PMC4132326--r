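Package: pcopnet
Title: Nonlinear Coexpression Networks from Principal Curves of Oriented Points
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects complex (nonlinear) expression dependences between sets of
    coexpressed genes from a genes-by-samples expression matrix. Every gene pair
    is summarised by a principal curve of oriented points (PCOP) with an
    uncorrelation factor f; curvature points on the curve separate linear
    (coexpressed) from nonlinear pairs, and each nonlinear pair is classified
    into a shape-based curve-type taxonomy (exponential, logarithmic, parabolic,
    cubic, closed, ...) that maps to activation/deactivation semantics. Gene
    cliques of pairwise nonlinear relationships are matched into isomorphic and
    linear clique pairs and assembled into skeleton networks: complete graphs
    over sets of coexpressed genes in which every pair of sets carries one curve
    type. Includes a synthetic-data generator with planted coexpressed modules
    and known intergroup curve types, plus command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
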