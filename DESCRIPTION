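Package: bigsmilesr
Title: Bidirectional Conversion Between Repeat-Unit SMILES and BigSMILES for Homopolymers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated conversion of homopolymer repeating-unit SMILES strings
    (carrying two asterisk polymerization points) into BigSMILES stochastic
    objects, and back. Implements asterisk relocation to the string ends via
    permutative branch swapping, AA/AB polymerization-type classification from
    the backbone composition, the ring-opening (epoxide) two-unit exception for
    *CCO* backbones, detection of reactive end-group pairs by single-character
    parallel displacement of the repeat unit, and a three-stage validation
    harness (ground-truth agreement, round-trip fidelity, permutation
    invariance). Batch table readers/writers and a command-line script mirror
    the published dataset layout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    readxl,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
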