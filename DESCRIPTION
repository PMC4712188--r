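Package: g4flux
Title: Fluctuation Analysis of G-Quadruplex-Driven Epigenetic Instability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying replication-coupled epigenetic instability
    at G-quadruplex (G4) bearing loci. Provides a G4 motif scanner with
    tract/loop geometry and replication-fork orientation classification, a
    stochastic branching-process simulator of sequential irreversible
    expression-state transitions during clonal expansion, Luria-Delbruck-style
    fluctuation analysis with Monte-Carlo inversion to estimate the
    per-division probability of expression loss from per-clone percent-loss
    distributions, binned Fisher exact comparison of genotypes, and small
    utilities for ChIP-qPCR double normalization, Welch's t test and
    bisulphite CpG methylation percentages. A synthetic-data generator with
    ground-truth sidecars makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
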