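Package: parentsim
Title: In-Silico Parentage Testing with STR Panels: False Inclusion of Relatives
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates three-generation families from short tandem repeat (STR)
    allele frequencies under Hardy-Weinberg founder sampling and Mendelian
    transmission, and quantifies the risk that a close relative of the true
    father (sibling, paternal grandfather, paternal uncle, half sibling,
    cousin) or a random man is falsely included as the father in duo
    (motherless) and trio paternity testing. Reports non-conformity
    (mismatching-locus) distributions, accumulative non-exclusion rates with
    modified-Wald (Agresti-Coull) intervals, and paternity-index likelihood
    ratio summaries with probability-of-paternity conversions. Includes a
    synthetic allele-frequency generator emulating forensic identification
    panels and CSV import/export of user-supplied population frequency tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
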