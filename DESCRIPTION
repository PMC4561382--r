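Package: rg4scan
Title: RNA G-Quadruplexes in mRNA Coding Regions: Discovery, Scoring,
    Peptide Context, Mutant Design and In-Line Probing Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers potential G-quadruplex (PG4) motifs in mRNA coding
    sequences with the four-G-tract pattern Gx-N1-7-Gx-N1-7-Gx-N1-7-Gx
    (x >= 3), merges overlapping matches into countable loci, scores loci
    with the consecutive-G/consecutive-C (cG/cC) ratio against the >2
    G4-propensity threshold, translates loci in an annotated reading frame
    to characterize the encoded peptide and its RGG/RG motifs, designs
    G4-disrupting mutants (tract ablation, G-run breaking, glycine-to-
    alanine codon rewriting), and quantifies in-line probing band
    intensities as per-nucleotide K+/Li+ cleavage ratios with replicate
    statistics and the strict twofold G4-formation call. A synthetic-data
    module generates ground-truthed coding sequences with embedded G4
    cassettes, guaranteed-negative controls, and simulated probing
    profiles so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    withr,
    optparse,
    stats,
    utils
Suggests:
    seqinr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
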