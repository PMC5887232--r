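Package: pckernel
Title: Phenotype Control Kernel Identification for Boolean Network Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Target control of Boolean network models of molecular regulatory
    networks. Builds the layered network of direct and indirect regulators of
    one or more phenotype nodes, enumerates the minimal partial input
    assignments (prime implicants) that force each update rule to a desired
    value, and constructs the converging tree whose surviving control sets
    form the phenotype control kernel: the collection of all minimal sets of
    node clamps that drive every initial state to an attractor with the
    desired phenotype values. Supports logic rules in a BoolNet-style plain
    text format and signed-threshold rules from edge tables, synchronous
    attractor analysis (exhaustive and sampled), constant-propagation model
    reduction, exhaustive any-to-multiple verification oracles, a seeded
    random network generator, and a command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
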