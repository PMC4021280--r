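Package: foldcons
Title: Structural Sensitivity and Evolutionary Conservation of Synonymous Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tests whether synonymous (4-fold degenerate) coding sites whose
    mutations disrupt local mRNA secondary structure are more evolutionarily
    conserved than structurally insensitive sites. Provides phylogenetically
    weighted column entropy for per-site conservation, an exact McCaskill
    partition-function folding engine with a mutation-scan structural
    sensitivity score (mean maximum structural distance over the three
    possible point mutations), per-gene 2x2 contingency tables combined by
    the Mantel-Haenszel procedure, expression and codon-bias (ENC')
    stratification, 5' sliding-window scans, a constrained-permutation test
    on continuous scores, and a synthetic ortholog-alignment generator with
    an optional planted coupling between structural sensitivity and
    synonymous substitution rate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    Biostrings,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
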