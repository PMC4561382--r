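# loci of `sequence` overlapping [start, end]
loci_over_region <- function(sequence, start, end, pattern) {
  loci <- scan_transcript(transcript_record("mut", sequence), pattern)
  loci[loci$end >= start & loci$start <= end, , drop = FALSE]
}

new_mutant_design <- function(original, mutant, strategy, changed, verified,
                              residual = NULL) {
  structure(
    list(original = original, mutant = mutant, strategy = strategy,
         changed_positions = sort(unique(as.integer(changed))),
         verified = verified, residual_tracts = residual),
    class = "mutant_design"
  )
}

#' @export
print.mutant_design <- function(x, ...) {
  cat(sprintf("<mutant_design> %s: %d change(s), %s\n", x$strategy,
              length(x$changed_positions),
              if (x$verified) "verified G4-free" else "NOT disrupted"))
  invisible(x)
}

#' Ablate selected G-tracts of a locus (G -> A)
#'
#' Replaces every guanine of each selected tract with adenine -- the G4m
#' probe design. The default tract choice is every other tract (1, 3, 5,
#' ...), which disrupts any four-tract chain; the emitted design is always
#' re-scanned and an error is raised if the edited region still matches,
#' prompting a larger index set (selecting all tracts always verifies).
#'
#' @param sequence the transcript/probe sequence (or a
#'   [transcript_record()]).
#' @param locus one row of a `g4_loci` data.frame (its `tract_spans` column
#'   identifies the tracts).
#' @param tract_indices integer set of tracts to ablate (1-based within the
#'   locus); default every other tract.
#' @param pattern [g4_pattern()] used for the disruption re-scan.
#' @return a `mutant_design`.
#' @export
tract_ablation <- function(sequence, locus, tract_indices = NULL,
                           pattern = g4_pattern()) {
  if (inherits(sequence, "transcript_record")) sequence <- sequence$sequence
  sequence <- normalize_sequence(sequence)
  tracts <- parse_spans(locus$tract_spans)
  if (nrow(tracts) == 0L) stop("locus has no recorded tracts", call. = FALSE)
  if (is.null(tract_indices)) tract_indices <- seq(1L, nrow(tracts), by = 2L)
  tract_indices <- sort(unique(as.integer(tract_indices)))
  if (any(tract_indices < 1L | tract_indices > nrow(tracts))) {
    stop(sprintf("tract indices out of range 1..%d", nrow(tracts)),
         call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  changed <- integer()
  for (i in tract_indices) {
    pos <- seq.int(tracts$start[i], tracts$end[i])
    chars[pos] <- "A"
    changed <- c(changed, pos)
  }
  mutant <- paste(chars, collapse = "")
  residual <- loci_over_region(mutant, locus$start, locus$end, pattern)
  if (nrow(residual) > 0L) {
    stop(sprintf(
      "tracts {%s} do not disrupt the locus (%d matching locus/loci remain); select more tracts",
      paste(tract_indices, collapse = ","), nrow(residual)), call. = FALSE)
  }
  new_mutant_design(sequence, mutant, "tract_ablation", changed, TRUE)
}

#' Break G-runs within a locus (G -> A) down to a maximum run length
#'
#' Minimal deterministic disruption: every maximal G-run inside the locus
#' longer than `max_run` receives substitutions at its most central
#' guanines first (a run of length L needs floor(L / (max_run + 1))
#' breaks). With `max_run < min_tract` the edited region can no longer
#' contain any qualifying tract, so disruption is guaranteed.
#'
#' @param sequence the transcript/probe sequence (or record).
#' @param locus row/list with `start` and `end`.
#' @param max_run maximum surviving G-run length (default 2).
#' @param pattern [g4_pattern()] used for the verification re-scan;
#'   `max_run` must be < `pattern$min_tract`.
#' @return a `mutant_design`.
#' @export
run_break <- function(sequence, locus, max_run = 2L, pattern = g4_pattern()) {
  if (inherits(sequence, "transcript_record")) sequence <- sequence$sequence
  sequence <- normalize_sequence(sequence)
  if (max_run >= pattern$min_tract) {
    stop("max_run must be smaller than pattern$min_tract", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  changed <- integer()
  break_positions <- function(from, to) {
    # minimal break count k = floor(L / (max_run + 1)); the surviving
    # guanines are distributed over the k + 1 fragments as evenly as
    # possible, extra guanines going to the most central fragments, so the
    # substitutions land on the most central Gs consistent with minimality
    len <- to - from + 1L
    k <- len %/% (max_run + 1L)
    if (k == 0L) return(integer())
    nseg <- k + 1L
    sizes <- rep((len - k) %/% nseg, nseg)
    extra <- (len - k) %% nseg
    if (extra > 0L) {
      centrality <- order(abs(seq_len(nseg) - (nseg + 1) / 2), seq_len(nseg))
      sizes[centrality[seq_len(extra)]] <- sizes[centrality[seq_len(extra)]] + 1L
    }
    from - 1L + cumsum(sizes[seq_len(k)] + 1L)
  }
  runs <- find_tracts(substr(sequence, locus$start, locus$end),
                      min_tract = max_run + 1L)
  for (i in seq_len(nrow(runs))) {
    pos <- break_positions(locus$start + runs$start[i] - 1L,
                           locus$start + runs$end[i] - 1L)
    chars[pos] <- "A"
    changed <- c(changed, pos)
  }
  mutant <- paste(chars, collapse = "")
  residual <- loci_over_region(mutant, locus$start, locus$end, pattern)
  new_mutant_design(sequence, mutant, "run_break", changed,
                    nrow(residual) == 0L)
}

# synonymous codons of the standard genetic code, as RNA triplets
synonymous_codons <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  rna <- setNames(gc, chartr("T", "U", names(gc)))
  names(rna)[rna == rna[[codon]]]
}

#' Glycine-to-alanine G4 disruption within a locus codon span
#'
#' Rewrites every glycine codon (GGN) in the locus's codon span to alanine
#' (GCN, second-position G -> C), matching the reporter-construct design in
#' which glycine-to-alanine mutations disrupt the G4 while leaving the rest
#' of the peptide intact. Where arginine (CGG) or tryptophan-adjacent
#' codons still leave junction G-runs, additional synonymous
#' (protein-preserving) codon edits are applied 5' to 3' -- choosing, per
#' codon overlapping a residual tract, the synonymous codon with fewest
#' guanines (ties: most positions identical to the original, then
#' alphabetical) -- until the scanner reports no locus over the span.
#' Protein changes are therefore limited to G -> A residues. If disruption
#' is unreachable, an error lists the residual tracts.
#'
#' @param record a [transcript_record()] with `cds_start`.
#' @param locus one row of a `g4_loci` data.frame.
#' @param pattern [g4_pattern()] used for re-scanning.
#' @return a `mutant_design` (the full mutated transcript sequence).
#' @export
gly_to_ala <- function(record, locus, pattern = g4_pattern()) {
  cc <- codon_span_and_translate(record, locus)
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  codon_starts <- seq.int(cc$codon_start, cc$codon_end, by = 3L)
  changed <- integer()
  is_gly <- vapply(codon_starts, function(s) {
    chars[s] == "G" && chars[s + 1L] == "G"
  }, TRUE)
  if (!any(is_gly)) {
    stop(sprintf("no glycine codons in codon span %d-%d; gly_to_ala not applicable",
                 cc$codon_start, cc$codon_end), call. = FALSE)
  }
  for (s in codon_starts[is_gly]) {
    chars[s + 1L] <- "C"
    changed <- c(changed, s + 1L)
  }
  mutant <- paste(chars, collapse = "")
  residual <- loci_over_region(mutant, cc$codon_start, cc$codon_end, pattern)
  if (nrow(residual) > 0L) {
    # synonymous rescue pass, 5' -> 3'
    for (s in codon_starts) {
      residual <- loci_over_region(mutant, cc$codon_start, cc$codon_end,
                                   pattern)
      if (nrow(residual) == 0L) break
      tracts <- parse_spans(residual$tract_spans[1L])
      overlaps_tract <- any(tracts$start <= s + 2L & tracts$end >= s)
      if (!overlaps_tract) next
      codon <- paste(chars[s:(s + 2L)], collapse = "")
      syn <- synonymous_codons(codon)
      gcount <- vapply(strsplit(syn, ""), function(x) sum(x == "G"), 0L)
      ident <- vapply(strsplit(syn, ""), function(x)
        sum(x == chars[s:(s + 2L)]), 0L)
      best <- syn[order(gcount, -ident, syn)][1L]
      if (sum(strsplit(best, "")[[1]] == "G") >=
          sum(chars[s:(s + 2L)] == "G")) next
      new <- strsplit(best, "")[[1]]
      changed <- c(changed, (s:(s + 2L))[new != chars[s:(s + 2L)]])
      chars[s:(s + 2L)] <- new
      mutant <- paste(chars, collapse = "")
    }
    residual <- loci_over_region(mutant, cc$codon_start, cc$codon_end, pattern)
    if (nrow(residual) > 0L) {
      stop(sprintf(
        "G4 disruption unreachable by Gly->Ala plus synonymous edits; residual tracts: %s",
        paste(residual$tract_spans, collapse = " | ")), call. = FALSE)
    }
  }
  design <- new_mutant_design(record$sequence, mutant, "gly_to_ala",
                              changed, TRUE)
  design$codon_span <- c(cc$codon_start, cc$codon_end)
  design$original_peptide <- cc$peptide
  design$mutant_peptide <- translate_rna(substr(mutant, cc$codon_start,
                                                cc$codon_end))
  design
}

#' Summarize mutant designs as a table
#'
#' @param designs list of `mutant_design` objects (or one).
#' @return data.frame: strategy, n_changes, changed_positions, verified.
#' @export
mutant_report <- function(designs) {
  if (inherits(designs, "mutant_design")) designs <- list(designs)
  do.call(rbind, lapply(designs, function(d) {
    data.frame(strategy = d$strategy,
               n_changes = length(d$changed_positions),
               changed_positions = paste(d$changed_positions, collapse = ";"),
               verified = d$verified,
               mutant = d$mutant,
               stringsAsFactors = FALSE)
  }))
}
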