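Package: crossgrm
Title: Genomic Relationship Matrices for Multi-Line Intercross Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds observed and expected genomic relationship matrices for
    pedigreed intercross populations founded by a small number of genotyped
    individuals from two or more lines, for autosomes and the X chromosome
    (hemizygous males). Founder allele frequencies per line yield gamete
    moments from which expected founder relationships are derived; a modified
    tabular method propagates them through the pedigree into the expected
    genomic relationship matrix.  Observed founder matrices are blended with
    their expectation when singular and combined with the pedigree expectation
    into a single-step inverse suitable for mixed-model software.  Includes a
    gene-drop Monte-Carlo simulator used as an oracle for the analytic
    expectations, a segregation-variance summary for two-line crosses, the
    founder-relatedness variance correction factor, and a deterministic
    generator of synthetic founder lines and advanced-intercross pedigrees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
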