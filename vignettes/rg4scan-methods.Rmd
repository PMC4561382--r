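---
title: "Methods: PG4 discovery, cG/cC scoring, mutant design and probing quantification"
author: "rg4scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PG4 discovery, cG/cC scoring, mutant design and probing quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rg4scan)
```

This vignette is the package's own account of its models and of the design
decisions that were genuinely open. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The PG4 pattern and what a "locus" is

A potential G-quadruplex (PG4) is a match to

$$G_x\,N_{1\text{-}7}\,G_x\,N_{1\text{-}7}\,G_x\,N_{1\text{-}7}\,G_x,\qquad x \ge 3,$$

four tracts of at least three guanines separated by loops of one to seven
nucleotides of any base. `g4_pattern()` exposes all four constants
(`tract_count = 4`, `min_tract = 3`, `loop_min = 1`, `loop_max = 7`); the
defaults are the pattern the analysis was built around and are frozen in
the CLI.

Three decisions shape the scanner:

* **Tract candidates are maximal G-runs only.** A run of five guanines is
  one five-G tract, never a three-G tract plus leftovers. This reproduces
  the way tracts are boxed in probing figures, keeps enumeration
  polynomial, and reproduces every wild-type/mutant match outcome of the
  printed probe fixtures. Because loops formally admit any base, a chain
  may *skip* a maximal run (the skipped run then sits inside a loop,
  subject to the 7-nt bound); the brute-force oracle in the tests
  enumerates all $\binom{n}{4}$ run combinations and the scanner must agree
  with it exactly.
* **Loops are measured between maximal runs**, so a loop of length zero is
  impossible by construction, and the ambiguity code N terminates any run
  (an uncertain base is never claimed as tetrad-forming).
* **Overlapping matches merge into loci** (transitive closure of interval
  overlap, via `IRanges::reduce`). Dense tract clusters — six four-G
  tracts in the MLL4 probe — produce many four-tract chains but one
  folding region; the locus count is the per-gene statistic, and the
  merged span is reported with its member tracts. Where more than four
  tracts chain, published locus boundaries chosen by eye may be narrower
  than the maximal merged span; the package reports the maximal span and
  leaves sub-selection to the user.

Scanning is single-stranded (mRNA sense); there is no reverse-complement
scan, and U/T are interchangeable on input.

## cG/cC scoring

The cG/cC score of a locus is the ratio of run-weighted consecutive-G
content to consecutive-C content over the locus plus flanking context.
The shipped weighting is the consecutive-count scheme in which an isolated
base scores 1, each base of a run of two scores 2, and each base of a run
of three or more scores 3 — per run: $1 \to 1$, $2 \to 4$, $L \ge 3 \to
3L$ (`run_weights = c(1, 4, 9)` with `tail_per_extra = 3`). A score
strictly above 2 classifies the locus `G4_favoured`: the guanine runs
outweigh the cytosines that could sequester them into Watson–Crick pairs.
The strictness matters and is tested: a ratio exactly at the threshold is
`undetermined`.

Open design points, and how they were resolved:

* **Window convention.** The original description of the score does not
  travel with the locus table, so the window is explicit configuration:
  `flank_up = flank_down = 15` nt by default, clipped silently (but
  recorded) at transcript ends. The five published per-locus anchor scores
  for the MLL-family transcripts (2.975, 2.796, 1.887, 2.468, 2.029) ship
  in `cgcc_anchors()`; users who supply the transcript sequences can run
  `calibrate_cgcc()` to check any weight/window configuration against
  them. The shipped defaults are a documented baseline, not a fidelity
  claim for any particular isoform.
* **Zero competing C.** A C-free window has no Watson–Crick competition at
  all. The default policy divides by a pseudocount of 1, keeping ratios
  finite and rankable; `zero_cc_policy = "infinite"` flags the ratio
  infinite for strict "no competing C" reporting. The pseudocount is used
  only when cC is exactly 0, so reciprocity
  ($\mathrm{ratio}(\bar s) = 1/\mathrm{ratio}(s)$ under G↔C
  complementation) holds exactly whenever both counts are positive.

## Reading-frame anchoring and the encoded peptide

Transcript coordinates are never assumed CDS-relative: the published locus
coordinates for the MLL genes are transcript coordinates with
gene-specific frame phase (codons begin at position 222 for the MLL1 probe
region but 262 for the MLL4 reporter insert). Every translation is
therefore anchored by an explicit `cds_start` — the position of the
initiator AUG — supplied per transcript. The codon span of a locus is the
smallest frame-aligned whole-codon interval covering it; translation uses
the standard genetic code (stops rendered `*`, no selenocysteine).

The RGG/RG motif grammar is a documented heuristic: greedy left-to-right
RG/RGG unit detection (RGG preferred), units grouped when separated by at
most `max_spacer = 4` non-unit residues, motifs needing at least two
units. Classes: `TriRG-like` (≥ 3 units), `DiRGG-like` (exactly two
adjacent RGG units), else `RG-rich`. The defaults recover the canonical
printed examples (RVQRGRGRG; the TriRG peptide QAERGARGGRGRRPGRGRPGGDRHS)
and are tunable because no formal grammar exists in the literature for
these motifs. Amino-acid composition is reported as ranked counts with
alphabetical tie-breaks; the package deliberately makes no significance
claim about composition preferences.

## Mutant design

Three strategies, each length-preserving, each re-scanned before a design
is emitted (a still-folding "mutant" is an error, never a silent return):

* `tract_ablation()` replaces every G of selected tracts with A. The
  published G4m probes correspond to tracts {1,3} (MLL1) and {1,4} (MLL4),
  which the tests regenerate character-for-character; the default
  selection is every other tract, which always breaks a four-tract chain.
* `run_break()` makes the minimal number of G→A substitutions that caps
  every G-run in the locus at `max_run` (default 2, below `min_tract`): a
  run of length $L$ receives $\lfloor L/(max\_run+1)\rfloor$ breaks,
  placed so the surviving fragments are as even as possible with the
  larger fragments central — substitutions land on the most central
  guanines consistent with minimality, deterministically.
* `gly_to_ala()` rewrites every glycine codon (GGN) in the locus codon
  span to alanine (GCN, second-position G→C), the reporter-construct
  design. GGN→GCN alone cannot always disrupt: an arginine CGG abutting a
  glycine codon leaves a GGG junction run, and in the MLL4 reporter insert
  six such junctions chain into a surviving locus. The package therefore
  follows with synonymous, protein-preserving codon edits applied 5′→3′
  over codons that overlap residual tracts (choosing the synonymous codon
  with fewest guanines; ties by similarity to the original, then
  alphabetically) until the scanner reports no locus — mirroring how the
  published reporter mutant silently recodes its arginines. Protein
  changes remain limited to Gly→Ala; if disruption is still unreachable,
  the error lists the residual tracts. Nucleotide-level identity with any
  particular plasmid is not claimed.

The published in-line probing G/A mutants follow no stated positional
rule, so they are kept as fixtures rather than regenerated; the tests
check instead that both they and `run_break()`'s output scan clean.

## In-line probing quantification

Input is a table of per-band intensities (sequence, position, condition
K/Li, replicate) — gel image processing and band calling are upstream of
this package. Per position, the K⁺ intensity is divided by the paired Li⁺
intensity (pairing strictly by replicate index; unpaired lanes are
rejected), and the mean ± SD across replicates is reported with the
G4-formation call **mean > 2**, strict, per band. A zero Li⁺ intensity
makes that replicate's ratio undefined; the position is flagged and the
undefined value excluded from the mean rather than propagated as
infinity, keeping means finite.

The region-level call is this package's addition: a G4 that folds exposes
its loop nucleotides, so elevated cleavage should appear at the
scanner-predicted loop positions specifically. `call_region()` calls the
region formed when at least `min_support` (default 1) predicted-loop
positions are individually called, always recording the supporting
positions so stricter rules can be applied downstream. How many loop
bands the original analyses required before declaring folding is not
stated anywhere; that is exactly why it is a parameter and not a
constant.

## The synthetic-data generator

The generator emulates what the analysis assumes, with exact ground truth:

* **Cassettes** (`make_pg4_cassette()`): four tracts of three G with loops
  drawn from {A, C, U} (G excluded by default so the constructed tracts
  stay maximal and the truth coordinates are exact). Defaults mirror the
  minimal pattern; loop lengths are per-call parameters.
* **Negatives** (`make_negative_cds()`): i.i.d. sequence at the requested
  GC content with every third consecutive G substituted by C — capping
  runs below `min_tract` while preserving GC exactly. Capping is used
  instead of shuffling because shuffling G-rich sequence can recreate
  PG4s and poison the negative label.
* **Embedding** (`embed_in_cds()`): the cassette is inserted at the
  requested position with `cds_start` recorded; backbone guanines
  touching the junctions are substituted with C so the terminal tracts
  are not extended, then the generator re-scans and errors if the
  recorded truth is ever violated. Defaults place the cassette at
  position 223 of a 1-kb backbone — the 200–300-nt post-AUG window where
  the MLL-family loci sit.
* **Probing** (`simulate_probing()`): baseline intensity 1.0 per position
  under multiplicative lognormal noise parameterized by its coefficient
  of variation ($\sigma^2 = \log(1+\mathrm{CV}^2)$, mean-corrected so the
  expected intensity is 1), with K⁺ loop positions multiplied by the
  effect size. Defaults — effect 4, CV 5%, 2 replicates — represent a
  clear folding signal quantified over two independent experiments, the
  replication level of the assays being emulated. Lognormal noise keeps
  intensities strictly positive, as band quantifications are.

All randomness flows from one explicit seed per call through a scoped RNG
(`withr::with_seed`); the global generator state is never touched, and
identical parameters plus seed give identical output.

What the generator does **not** emulate: codon-usage structure,
transcriptome-scale base composition, gel artifacts (band compression,
smiling), position-dependent cleavage chemistry, or partially folded
populations. Passing tests on synthetic data therefore demonstrate
algorithmic correctness against the stated signal model, not performance
on real gels or real transcriptomes.

## Numerical and degenerate-input conventions

* Coordinates: 1-based inclusive everywhere in R; BED files are the only
  0-based half-open surface, converted through GenomicRanges/rtracklayer.
* Empty inputs are values, not errors: empty FASTA → empty list; G-free
  sequence → zero tracts; zero hits → zero loci; empty locus table →
  header-only TSV, empty BED.
* TSV output rounds floating point to 4 significant digits; tests that
  round-trip through disk compare at that precision.
* Ranking ties (amino-acid composition) break alphabetically; mutant
  tie-breaks are specified above; all iteration orders are deterministic.

## Test-suite problem sizes

The property suites run at sizes chosen to exercise the combinatorics
while keeping the default test run fast: scanner-vs-oracle agreement on
500 random sequences of 20–200 nt at G densities 0.25–0.5 (in the
acceptance checks; 80 in the unit suite), label fidelity over 200
generator draws, probing power and null calibration over 100 simulated
two-replicate experiments, and 15–50 draws for the smaller invariants.
`scripts/acceptance.R` re-runs the headline quantities at these same
sizes from a single `--seed`.

## Known limitations

* The scanner models the canonical four-tract, 1–7-nt-loop pattern;
  bulged tetrads, two-tetrad G4s and thermodynamic stability are out of
  scope (the configurable `min_tract` is the only knob in that
  direction).
* The cG/cC window and weight defaults are a documented baseline; per
  isoform anchor reproduction requires the user's transcript sequences
  via `calibrate_cgcc()`.
* Locus boundaries for dense tract clusters are maximal merged spans and
  may be wider than hand-curated boundaries.
* Wet-lab observables around these elements — polysome association,
  reporter activity, proliferation — are outside what sequence analysis
  can reproduce; they are represented here only by the printed
  wild-type/mutant fixture pairs and the probing simulation model.
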