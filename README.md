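# rg4scan

RNA G-quadruplexes (G4s) are four-stranded structures of stacked guanine
tetrads, stabilized by K⁺ but not Li⁺. G4 motifs inside mRNA **coding
regions** are of particular interest because the G-rich codons that encode
glycine- and arginine-glycine-rich protein segments (GGN, CGN, AGA/G) are
exactly the codons that can fold into G4s — so the mRNAs of RGG/RG-motif
proteins and of the MLL (mixed lineage leukemia) histone methyltransferase
family carry potential G4s (PG4s) a few hundred nucleotides into their open
reading frames, where they act as translational control elements.

`rg4scan` is an R package for the computational side of studying such
elements. It is aimed at RNA biologists who have transcript sequences,
CDS annotations and (optionally) in-line probing gel quantifications, and
want to:

1. **Discover PG4s** with the four-tract pattern
   G*ₓ*–N₁₋₇–G*ₓ*–N₁₋₇–G*ₓ*–N₁₋₇–G*ₓ* (x ≥ 3, N any nucleotide), merging
   overlapping matches into countable loci (`scan_transcript()`).
2. **Score G4 propensity** with the cG/cC ratio — run-weighted consecutive-G
   content over consecutive-C content in the locus plus flanking window,
   where cG/cC > 2 predicts G4 folding over Watson–Crick pairing with the
   neighbourhood (`score_locus()`).
3. **Characterize the encoded peptide**: frame-anchored translation of the
   locus codon span, pooled amino-acid composition, and RGG/RG-motif
   detection (`codon_span_and_translate()`, `find_rgg_motifs()`).
4. **Design G4-disrupting mutants** three ways: G-tract ablation (G→A over
   selected tracts, the classic "G4m" probe design), minimal G-run breaking,
   and glycine-to-alanine codon rewriting for reporter fusions — every
   emitted design is re-scanned and guaranteed G4-free (`tract_ablation()`,
   `run_break()`, `gly_to_ala()`).
5. **Quantify in-line probing**: per-nucleotide K⁺/Li⁺ band-intensity
   ratios with replicate mean ± SD and the strict twofold G4-formation
   call, aggregated over the scanner-predicted loop positions
   (`ratio_profile()`, `call_region()`).
6. **Generate ground-truthed synthetic data** — coding sequences with
   embedded G4 cassettes, guaranteed-negative controls, simulated probing
   profiles — so every stage is testable without downloads
   (`make_pg4_cassette()`, `make_negative_cds()`, `embed_in_cds()`,
   `simulate_probing()`).

Coordinates are 1-based inclusive transcript coordinates throughout; BED
import/export is the single 0-based surface. Sequences are handled in the
RNA alphabet internally (T accepted on input, restored on request).

The published probe sequences used to validate the pipeline (sc1, the
MLL1/MLL4 binding probes and their G4m mutants, the in-line probing
wild-type/G-A-mutant pairs, and the MLL4 luciferase-reporter insert) ship
as fixtures: `probe_fixtures()` / `inst/extdata/printed_probes.fasta`.

## Worked example

```r
library(rg4scan)

fx <- probe_fixtures()
mll4 <- fx$sequence[fx$name == "mll4_probe"]   # MLL4 probe, transcript 267-310

loci <- scan_transcript(transcript_record("MLL4_probe", mll4))
loci[, c("locus_id", "start", "end", "n_tracts", "loop_lengths")]
#>           locus_id start end n_tracts loop_lengths
#> 1 MLL4_probe_PG4_1     6  39        6    2;2;2;2;2
```

Six tracts of four guanines with 2-nt loops chain into a single locus —
locus count, not raw four-tract-match count, is the "PG4s per gene"
statistic. Scoring it (here over the bare probe, no flanks):

```r
score_loci(transcript_record("MLL4_probe", mll4), loci,
           cgcc_config(flank_up = 0, flank_down = 0))[, c("cG", "cC", "ratio", "classification")]
#>   cG cC ratio classification
#> 1 74 25  2.96    G4_favoured
```

cG/cC = 2.96 > 2: the guanine runs dominate the competing cytosines, so G4
folding is favoured over a Watson–Crick hairpin. Translating the reporter
insert (MLL4 262–318 fused to luciferase; codons begin at 262):

```r
ins <- fx$sequence[fx$name == "pgl3_mll4_insert"]
rec <- transcript_record("pGL3_MLL4",
                         paste0("AUG", substr(strrep("ACU", 86), 1, 258), ins),
                         cds_start = 1)
cc <- codon_span_and_translate(rec, scan_transcript(rec)[1, ])
cc
#> <coding_context> pGL3_MLL4 263-305 | codons 262-306 | +262 nt from AUG
#>   RVQRGRGRGRGRGWG
find_rgg_motifs(cc$peptide)
#>   start end unit_count          units      class
#> 1     4  13          5 RG+RG+RG+RG+RG TriRG-like
```

The locus encodes the RGG/RG motif RVQRGRGRG… — a G4 whose codons spell an
RG-repeat protein motif. Finally, the G4m mutant probe regenerates from the
wild type by ablating tracts 1 and 4:

```r
d <- tract_ablation(mll4, loci[1, ], tract_indices = c(1, 4))
d
#> <mutant_design> tract_ablation: 8 change(s), verified G4-free
d$mutant
#> "CCAGCAAAACCGGGGACGGGGUCAAAACCGGGGCUGGGGCCCGA"
```

A command-line entry point with `scan`, `score`, `context`, `mutate`,
`probing`, `simulate` and `pipeline` subcommands ships at
`inst/scripts/rg4.R` (`Rscript rg4.R scan --fasta seqs.fasta --out-prefix out`);
every output embeds a provenance block that can be replayed as a config
file.

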