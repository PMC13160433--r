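Package: vus3d
Title: Structural Triage of Missense Variants of Uncertain Significance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps missense variants of uncertain significance (VUS) from genomic
    or protein coordinates onto automatically selected 3D protein structures and
    scores their spatial clustering with known pathogenic versus benign sites.
    Provides a desk-scale pipeline: VCF or case-CSV ingest with a toy-transcriptome
    consequence caller, transcript-to-curated-protein cross-reference
    reconciliation with isoform expansion, multi-criteria structure selection over
    local structure catalogs with SIFTS-style residue maps, a native
    proximity-kernel clustering statistic with a permutation null, precomputed
    per-residue score ingestion, architecture-independent work planning with a
    file-based job status protocol and pluggable executors, and case-wide report
    aggregation with per-variant value ranges. A synthetic-fixture module
    generates every input (transcriptomes, structures, planted spatial clusters,
    score tables) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    vcfR,
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
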