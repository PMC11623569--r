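Package: psiscan
Title: Pseudouridine Site Calling from Bisulfite-Induced Deletion Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls pseudouridine (Psi) sites in bacterial transcriptomes from
    paired bisulfite-treated and untreated per-base pileup count tables, where
    the bisulfite-Psi adduct leaves a uridine-specific single-base deletion in
    cDNA. Provides the per-base deletion-ratio diagnostic, isolate-mode and
    microbiome-mode site callers, high-confidence aggregation across samples,
    Psi stoichiometry and transcript-level Psi-strength quantification, TPM
    normalisation, pseudouridine-synthase assignment from knockout contrasts,
    stress-differential pseudouridylation, sequence-motif analysis, antisense
    RNA and small-RNA candidate discovery, and a synthetic pileup generator
    with ground truth for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
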