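Package: pathdc
Title: Decision Analysis of Pathway Impact Hierarchies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ranks the members of a pathway hierarchy (KEGG category,
    subcategory, secondary pathway) by a decision coefficient computed from a
    standardized path-analysis model of pathway impact values observed over
    time points or treatment contrasts. The decision coefficient of a child
    pathway combines its direct determination factor with the indirect
    determination contributed by correlated sibling pathways, so pathways are
    scored with their dependence structure instead of one at a time. Includes
    the determination-coefficient decomposition into direct and indirect
    parts, a t-based significance cutoff for decision coefficients, impact
    direction calls from the coefficient sign, decision-percentage annotated
    tree export (Graphviz DOT and JSON), gene-level impact scoring from
    differential-expression tables, method-comparison metrics, and a
    synthetic-data generator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
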