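#' Printed probe and construct sequences
#'
#' The published probe, in-line probing and reporter-insert sequences used
#' throughout the package's tests and examples, with the transcript
#' coordinates reported for the MLL probes. `sc1` is the high-affinity
#' G4-forming RNA binding standard (two-guanine tracts, below the default
#' x >= 3 pattern); `*_g4m` are the guanine-to-adenine mutant versions
#' predicted not to fold; `pgl3_mll4_insert` is the MLL4 262--318 region
#' fused to luciferase in the reporter construct, and
#' `pgl3_mll4_mutant` its glycine-to-alanine disrupted version. The same
#' sequences ship as `extdata/printed_probes.fasta`.
#'
#' @return data.frame: name, gene, variant ("wt"/"g4m"), role
#'   ("binding_probe", "probing", "reporter", "standard"),
#'   transcript_start, transcript_end (NA where not reported), sequence
#'   (RNA alphabet).
#' @export
probe_fixtures <- function() {
  df <- data.frame(
    name = c("sc1", "sc1_g4m",
             "mll1_probe", "mll1_probe_g4m",
             "mll4_probe", "mll4_probe_g4m",
             "mll1_inline", "mll1_inline_g4m",
             "mll4_inline", "mll4_inline_g4m",
             "pgl3_mll4_insert", "pgl3_mll4_mutant"),
    gene = c("sc1", "sc1", "MLL1", "MLL1", "MLL4", "MLL4",
             "MLL1", "MLL1", "MLL4", "MLL4", "MLL4", "MLL4"),
    variant = rep(c("wt", "g4m"), 6),
    role = c("standard", "standard",
             "binding_probe", "binding_probe",
             "binding_probe", "binding_probe",
             "probing", "probing", "probing", "probing",
             "reporter", "reporter"),
    transcript_start = c(NA, NA, 220L, 220L, 267L, 267L,
                         NA, NA, NA, NA, 262L, 262L),
    transcript_end = c(NA, NA, 258L, 258L, 310L, 310L,
                       NA, NA, NA, NA, 318L, 318L),
    sequence = c(
      "GCUGCGGUGUGGAAGGAGUGGUCGGGUUGCGCAGCG",
      "GCUGCAAUGUGGAAAAAGUGGUCGGGUUGCGCAGCG",
      "CGGCGGGAAGCAGCGGGGCUGGGGUUCCAGGGGGAGCGG",
      "CGGCAAAAAGCAGCGGGGCUAAAAUUCCAGGGGGAGCGG",
      "CCAGCGGGGCCGGGGACGGGGUCGGGGCCGGGGCUGGGGCCCGA",
      "CCAGCAAAACCGGGGACGGGGUCAAAACCGGGGCUGGGGCCCGA",
      "GGCCGCGGCGGCGGCGGCGGGAAGCAGCGGGGCUGGGGUUCCAGGGGGAGCGGCCGCCGCCUC",
      "GGCCGCGGCGGCGGCGGCGAGAAGCAGCGAAGCUGAAGUUCCAGAAAGAGCGGCCGCCGCCUC",
      "GGCCCGCGGGUCCAGCGGGGCCGGGGACGGGGUCGGGGCCGGGGCUGGGGCCCGAGUCGAGGCUG",
      "GGCCCGCGGGUCCAGCGAAGCCGAAGACGAAGUCGAAGCCGAAGCUGAAGCCCGAGUCGAGGCUG",
      "CGGGUCCAGCGGGGCCGGGGACGGGGUCGGGGCCGGGGCUGGGGCCCGAGUCGAGGC",
      "CGCGUCCAGCGCGCCCGCGCCCGCGCCCGCGCCCGCGCCUGGGCCCCGAGUCGAGGC"),
    stringsAsFactors = FALSE
  )
  df
}

#' Expected default-pattern locus counts for the printed fixtures
#'
#' The fixture truth table: under the default pattern (four tracts of
#' x >= 3 G, 1--7 nt loops) each wild-type MLL probe, probing sequence and
#' the reporter insert contains exactly one PG4 locus, each G/A mutant
#' none, and sc1 none (its tracts are two-guanine; it matches only at
#' `min_tract = 2`).
#'
#' @return named integer vector of locus counts, names as in
#'   [probe_fixtures()].
#' @export
fixture_locus_counts <- function() {
  c(sc1 = 0L, sc1_g4m = 0L,
    mll1_probe = 1L, mll1_probe_g4m = 0L,
    mll4_probe = 1L, mll4_probe_g4m = 0L,
    mll1_inline = 1L, mll1_inline_g4m = 0L,
    mll4_inline = 1L, mll4_inline_g4m = 0L,
    pgl3_mll4_insert = 1L, pgl3_mll4_mutant = 0L)
}

#' Printed fixtures as transcript records
#'
#' @param names optional subset of fixture names.
#' @return list of [transcript_record()]s.
#' @export
fixture_records <- function(names = NULL) {
  df <- probe_fixtures()
  if (!is.null(names)) df <- df[df$name %in% names, , drop = FALSE]
  lapply(seq_len(nrow(df)), function(i) {
    transcript_record(df$name[i], df$sequence[i],
                      description = sprintf("%s %s (%s)", df$gene[i],
                                            df$variant[i], df$role[i]))
  })
}

#' Path of the packaged fixture FASTA
#'
#' @return path to `extdata/printed_probes.fasta`.
#' @export
fixture_fasta_path <- function() {
  system.file("extdata", "printed_probes.fasta", package = "rg4scan",
              mustWork = TRUE)
}
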