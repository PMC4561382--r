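#' cG/cC scoring configuration
#'
#' The cG/cC score is the ratio of run-weighted consecutive-G content to
#' run-weighted consecutive-C content over a PG4 locus plus flanking
#' context; a ratio above the threshold (default 2) predicts G4 folding
#' over Watson--Crick pairing with the neighbouring sequence.
#'
#' The default weight table implements the consecutive-count weighting in
#' which an isolated base scores 1, each base of a run of two scores 2, and
#' each base of a run of three or more scores 3 -- i.e. per run:
#' length 1 -> 1, length 2 -> 4, length L >= 3 -> 3L (the `tail_per_extra`
#' rule adds 3 per guanine beyond the longest configured run length).
#'
#' @param flank_up,flank_down nucleotides of context on each side of the
#'   locus (defaults 15).
#' @param run_weights named numeric vector: total contribution of one run of
#'   each length (names "1","2",... ).
#' @param tail_per_extra added per base beyond the longest configured run
#'   length.
#' @param threshold classification threshold (strict `>`; default 2).
#' @param zero_cc_policy "pseudocount" (divide by `pseudocount` when cC = 0;
#'   keeps ratios finite for ranking) or "infinite" (flag the ratio
#'   infinite, reproducing strict "no competing C" behaviour).
#' @param pseudocount denominator used when cC = 0 under the pseudocount
#'   policy.
#' @return object of class `cgcc_config`.
#' @export
cgcc_config <- function(flank_up = 15L, flank_down = 15L,
                        run_weights = c("1" = 1, "2" = 4, "3" = 9),
                        tail_per_extra = 3,
                        threshold = 2,
                        zero_cc_policy = c("pseudocount", "infinite"),
                        pseudocount = 1) {
  zero_cc_policy <- match.arg(zero_cc_policy)
  if (flank_up < 0 || flank_down < 0) stop("flanks must be >= 0", call. = FALSE)
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (is.null(names(run_weights)) ||
      !identical(names(run_weights), as.character(seq_along(run_weights)))) {
    stop("run_weights must be named \"1\", \"2\", ... consecutively",
         call. = FALSE)
  }
  structure(list(flank_up = as.integer(flank_up),
                 flank_down = as.integer(flank_down),
                 run_weights = run_weights,
                 tail_per_extra = tail_per_extra,
                 threshold = threshold,
                 zero_cc_policy = zero_cc_policy,
                 pseudocount = pseudocount),
            class = "cgcc_config")
}

#' Run-weighted count of consecutive G or C
#'
#' Sums, over every maximal run of `base` in the sequence, the configured
#' weight for that run length. Run lengths beyond the largest configured
#' key contribute the largest configured weight plus `tail_per_extra` per
#' extra base.
#'
#' @param sequence normalized nucleotide string.
#' @param base "G" or "C".
#' @param config a [cgcc_config()] (only the weight fields are used).
#' @return numeric scalar.
#' @export
run_weighted_count <- function(sequence, base = c("G", "C"),
                               config = cgcc_config()) {
  base <- match.arg(base)
  sequence <- normalize_sequence(sequence)
  if (nchar(sequence) == 0L) return(0)
  r <- rle(strsplit(sequence, "", fixed = TRUE)[[1]] == base)
  lens <- r$lengths[r$values]
  if (length(lens) == 0L) return(0)
  w <- config$run_weights
  kmax <- length(w)
  sum(ifelse(lens <= kmax, w[pmin(lens, kmax)],
             w[kmax] + config$tail_per_extra * (lens - kmax)))
}

#' Score one locus with the cG/cC ratio
#'
#' The scoring window is the locus extended by the configured flanks,
#' clipped at the transcript ends (clipping is recorded, not warned about).
#' Classification is strictly greater than the threshold: a ratio exactly
#' at the threshold is `undetermined`.
#'
#' @param record a [transcript_record()] or plain sequence.
#' @param locus one row of a `g4_loci` data.frame, or a list/row with
#'   `start` and `end`.
#' @param config a [cgcc_config()].
#' @return one-row data.frame: transcript_id, locus start/end, window
#'   start/end, clipped, cG, cC, ratio, infinite, classification.
#' @export
score_locus <- function(record, locus, config = cgcc_config()) {
  if (is.character(record)) record <- transcript_record("seq", record)
  L <- nchar(record$sequence)
  if (locus$start < 1L || locus$end > L || locus$end < locus$start) {
    stop(sprintf("locus %d-%d outside sequence 1..%d", locus$start,
                 locus$end, L), call. = FALSE)
  }
  ws <- locus$start - config$flank_up
  we <- locus$end + config$flank_down
  clipped <- ws < 1L || we > L
  ws <- max(1L, ws); we <- min(L, we)
  win <- substr(record$sequence, ws, we)
  cG <- run_weighted_count(win, "G", config)
  cC <- run_weighted_count(win, "C", config)
  infinite <- FALSE
  if (cC > 0) {
    ratio <- cG / cC
  } else if (config$zero_cc_policy == "infinite") {
    ratio <- Inf; infinite <- TRUE
  } else {
    ratio <- cG / config$pseudocount
  }
  data.frame(
    transcript_id = record$id,
    locus_id = if (!is.null(locus$locus_id)) locus$locus_id else NA_character_,
    start = locus$start, end = locus$end,
    window_start = ws, window_end = we, clipped = clipped,
    cG = cG, cC = cC, ratio = ratio, infinite = infinite,
    classification = if (ratio > config$threshold) "G4_favoured"
                     else "undetermined",
    stringsAsFactors = FALSE
  )
}

#' Score every locus of a scan
#'
#' @param record a [transcript_record()].
#' @param loci `g4_loci` data.frame from [scan_transcript()].
#' @param config a [cgcc_config()].
#' @return data.frame, one row per locus (zero rows for an empty scan).
#' @export
score_loci <- function(record, loci, config = cgcc_config()) {
  if (nrow(loci) == 0L) {
    return(score_locus(record, list(start = 1L, end = 1L), config)[0L, ])
  }
  do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
    score_locus(record, loci[i, ], config)
  }))
}

#' Complement an RNA sequence (G<->C, A<->U), without reversal
#'
#' Used by the cG/cC reciprocity property: complementing a window swaps the
#' roles of cG and cC exactly.
#'
#' @param sequence normalized nucleotide string.
#' @return complemented string.
#' @export
complement_rna <- function(sequence) {
  chartr("GCAU", "CGUA", normalize_sequence(sequence))
}

#' Published cG/cC anchor scores for the MLL-family PG4 loci
#'
#' The five printed anchor scores for the PG4 loci of the human KMT2A
#' (MLL1), KMT2B (MLL4) and KMT2D transcripts, with the transcript
#' coordinates reported for each locus. The transcript sequences themselves
#' are not redistributed (no accession is fixed; isoform choice is left to
#' the user), so these anchors serve as a calibration table: given the
#' transcript sequences, [calibrate_cgcc()] recomputes each score under a
#' configuration and reports the deviations.
#'
#' @return data.frame: gene, transcript, start, end, peptide, cgcc_score.
#' @export
cgcc_anchors <- function() {
  data.frame(
    gene = c("MLL1", "MLL4", "MLL4", "MLL4", "MLL2/KMT2D"),
    transcript = c("KMT2A", "KMT2B", "KMT2B", "KMT2B", "KMT2D"),
    start = c(223L, 262L, 3139L, 6274L, 961L),
    end = c(253L, 287L, 3166L, 6301L, 986L),
    peptide = c("AGSSGAGVPGG", "RVQRGRGRG", "RGAGAGGPRE", "RAGVLGAAGD",
                "RVCRACGAG"),
    cgcc_score = c(2.975, 2.796, 1.887, 2.468, 2.029),
    stringsAsFactors = FALSE
  )
}

#' Check a cG/cC configuration against the published anchor scores
#'
#' @param records named list of [transcript_record()]s keyed by transcript
#'   name ("KMT2A", "KMT2B", "KMT2D"), supplied by the user.
#' @param config a [cgcc_config()].
#' @return the [cgcc_anchors()] table with recomputed scores and deviations.
#' @export
calibrate_cgcc <- function(records, config = cgcc_config()) {
  anchors <- cgcc_anchors()
  anchors$computed <- NA_real_
  for (i in seq_len(nrow(anchors))) {
    rec <- records[[anchors$transcript[i]]]
    if (is.null(rec) || nchar(rec$sequence) < anchors$end[i]) next
    sc <- score_locus(rec, list(start = anchors$start[i],
                                end = anchors$end[i]), config)
    anchors$computed[i] <- sc$ratio
  }
  anchors$deviation <- anchors$computed - anchors$cgcc_score
  anchors
}
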