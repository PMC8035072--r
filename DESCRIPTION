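Package: ryescan
Title: Detection of Rye Introgressions and Reticulate Evolution in Triticeae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Read-depth karyotyping of wheat-rye introgressions on a combined
    reference genome with SVM classification; Hi-C link-asymmetry scanning for
    large structural variants with a permutation enrichment test; windowed
    population-genetic statistics (identity-by-state, Weir-Hill Fst, Pn/Ps with
    outgroup polarization, Patterson's D with block jackknife); reciprocal-best-hit
    percent-identity profiles along chromosomes; and flow-cytometric genome-size
    estimation. Includes seeded synthetic-data generators that emulate the
    statistical structure of each input, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    kernlab,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
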