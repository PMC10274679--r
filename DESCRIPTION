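Package: fpopseek
Title: Hybrid Variable-Modification and Mass-Offset Search for FPOP Proteomics
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale peptide-spectrum search engine for hydroxyl radical
    protein footprinting (FPOP) data. Implements hybrid candidate generation
    that enumerates common modifications as variable modifications while
    admitting at most one rare modification per peptide as a precursor mass
    offset, fragment-indexed scoring with shifted-ion delta-mass localization,
    and group-based target-decoy false discovery rate control that filters
    unmodified, assigned-modification and other-modification peptide-spectrum
    matches at separate score thresholds. Includes a ground-truthed synthetic
    FPOP data generator (proteome, spectra, truth table) so every stage of the
    workflow is testable without external raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
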