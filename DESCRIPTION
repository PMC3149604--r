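Package: codonharmony
Title: Codon-Usage Harmonization and Constraint-Aware Coding-Sequence Design
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds codon-usage tables from sets of highly expressed host
    coding sequences, diagnoses a heterologous coding sequence for
    translation-hostile features (rare codons, tandem codon repeats,
    inverted-repeat hairpins, AT/GC-rich runs, cryptic splice sites,
    restriction sites, GC-content windows), and redesigns its synonymous
    codons so that within-family codon frequencies match those of the host's
    highly expressed genes. Redesign excludes low-frequency codons, keeps
    every 40 bp window near a GC target, can introduce unique restriction
    sites purely by synonymous substitution, and preserves the encoded
    protein exactly. Allocation uses largest-remainder apportionment;
    placement is repaired by seeded simulated annealing, so runs are
    reproducible bit-for-bit under a fixed seed.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
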