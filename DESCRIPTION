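Package: trfm1a
Title: Mapping N1-Methyladenosine in tRNA-Derived Fragments from RT
    Misincorporation Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and quantifies N1-methyladenosine (m1A) in small RNAs,
    in particular 22-nucleotide 3' tRNA fragments (tRF-3b), from the
    misincorporation signature that m1A leaves in reverse-transcribed
    sequencing reads, combined with m1A antibody (RIP) enrichment.
    Provides mismatch-tolerant hierarchical mapping of trimmed small-RNA
    reads with fractional multi-mapping, tRF classification (tRF-5, tRF-3,
    tRF-1, halves, 18-nt/22-nt size isoforms), per-position mismatch
    pileups and mismatch indices, spike-in-normalized cloning frequencies,
    zero-intercept mismatch-vs-stoichiometry calibration with bootstrap
    stoichiometry estimates, RIP-vs-input enrichment testing with
    two-antibody candidate calls, and seed-based (8mer-A1, 7mer-m8,
    7mer-A1, 6mer) 3' UTR target prediction with centered-CDF one-sided
    Kolmogorov-Smirnov repression analysis. A synthetic-data module
    simulates fragment pools, RT-specific error models, RIP fractions,
    spike-in mixtures, and expression tables with planted seed-target
    effects so every stage is testable against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
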