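Package: foundertrace
Title: Founder-Haplotype Evidence Analysis for Rare Variants from Phased Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing whether a rare variant observed in apparently
    unrelated individuals descends from a single founder. Detects the shared
    haplotype core around a focal variant from phased genotypes, estimates its
    background frequency, tests rare tagging variants for carrier enrichment
    with a log-space exact 2x2 test, unifies equivalent representations of
    complex delins calls, and provides the accompanying clinical comparison
    statistics (Welch t from summaries, chi-square, CKD-EPI 2009 eGFR, KDIGO
    staging, Kaplan-Meier and log-rank). Includes a founder-descent simulator
    with recombination under the Haldane model for validation against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
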