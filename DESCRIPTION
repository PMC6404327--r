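Package: ambicode
Title: Evolution of Ambiguous Genetic Codes Under Mistranslation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the emergence of genetic code structure from
    ambiguous codon-to-label assignments. A population of row-stochastic
    64x21 code matrices evolves under an evolutionary algorithm whose
    stochastic fitness rewards codes that encode all 20 amino acids and
    the stop signal unambiguously, with mistranslation modelled by codon
    neighbourhoods affecting one, two or three codon positions (M1, M2,
    M3). Ships the measurement suite used to characterise the evolved
    codes: genetic code entropy, maximum-likelihood graph partition,
    coding strength, and conductance of codon groups on the 64-node
    point-mutation graph, together with the standard genetic code and
    the best simulated codes as built-in partitions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
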