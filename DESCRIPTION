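Package: fabkit
Title: Annotation, Geometry and Search for Antibody V and C Region Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and querying collections of antibody
    structures that carry both variable (V) and constant (C) regions.
    Detects V and C domains in amino-acid sequences by alignment against
    IMGT-gapped germline references and transfers IMGT-style position
    labels to both regions; consolidates per-domain species calls with a
    percentage-identity override rule, flags engineered formats, and
    assigns isotype or light-chain type from the best constant-region
    hit; classifies structural coverage (Fab versus full antibody) from
    the residues with resolved coordinates; computes Fab packing angles
    (elbow and CH1-CL) from pseudo-twofold superposition axes, C-alpha
    contact matrices, solvent-accessibility-based heavy-light interfaces,
    and disulfide bonds; searches an annotated collection by sequence
    similarity (V or V+C, paired or unpaired chains, repertoire file
    dialects) and by CH1-CL interface similarity; and post-processes
    in-silico mutational-scanning score tables, including wild-type
    scaling, additive multi-mutant scores, and a per-position isotype
    sensitivity comparison. Deterministic synthetic fixture generators
    make the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
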