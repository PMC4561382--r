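#' Translate a frame-aligned RNA span
#'
#' Standard genetic code; stop codons are rendered `*`. The span length
#' must be a multiple of 3.
#'
#' @param sequence normalized RNA string of whole codons.
#' @return amino-acid string (one-letter codes).
#' @export
translate_rna <- function(sequence) {
  sequence <- normalize_sequence(sequence)
  if (nchar(sequence) %% 3L != 0L) {
    stop("sequence length is not a multiple of 3", call. = FALSE)
  }
  if (nchar(sequence) == 0L) return("")
  as.character(Biostrings::translate(Biostrings::RNAString(sequence),
                                     if.fuzzy.codon = "X"))
}

#' Codon span and encoded peptide of a locus
#'
#' Computes the smallest frame-aligned whole-codon interval covering the
#' locus (frame anchored at the record's `cds_start`, never at coordinate
#' 1) and translates it. The MLL-family loci sit 200--300 nt downstream of
#' the initiator AUG; `distance_from_cds_start` reports that offset.
#'
#' @param record a [transcript_record()] with `cds_start` set.
#' @param locus row/list with `start` and `end` (1-based inclusive).
#' @return object of class `coding_context`: list with locus start/end,
#'   codon_start, codon_end, peptide, distance_from_cds_start.
#' @export
codon_span_and_translate <- function(record, locus) {
  if (is.null(record$cds_start)) {
    stop(sprintf("record '%s' has no cds_start; frame cannot be anchored",
                 record$id), call. = FALSE)
  }
  cds <- record$cds_start
  if (locus$start < cds) {
    stop(sprintf("locus %d-%d upstream of cds_start %d", locus$start,
                 locus$end, cds), call. = FALSE)
  }
  codon_start <- cds + 3L * ((locus$start - cds) %/% 3L)
  codon_end <- cds + 3L * ((locus$end - cds) %/% 3L) + 2L
  if (codon_end > nchar(record$sequence)) {
    stop(sprintf("codon span %d-%d runs past sequence end (%d nt): truncated codon",
                 codon_start, codon_end, nchar(record$sequence)), call. = FALSE)
  }
  peptide <- translate_rna(substr(record$sequence, codon_start, codon_end))
  structure(
    list(transcript_id = record$id, start = locus$start, end = locus$end,
         codon_start = codon_start, codon_end = codon_end,
         peptide = peptide,
         distance_from_cds_start = locus$start - cds),
    class = "coding_context"
  )
}

#' @export
print.coding_context <- function(x, ...) {
  cat(sprintf("<coding_context> %s %d-%d | codons %d-%d | +%d nt from AUG\n  %s\n",
              x$transcript_id, x$start, x$end, x$codon_start, x$codon_end,
              x$distance_from_cds_start, x$peptide))
  invisible(x)
}

#' Coding contexts for every locus of a scan
#'
#' @param record a [transcript_record()] with `cds_start`.
#' @param loci `g4_loci` data.frame.
#' @return data.frame: transcript_id, locus_id, start, end, codon_start,
#'   codon_end, peptide, distance_from_cds_start.
#' @export
coding_contexts <- function(record, loci) {
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    cc <- codon_span_and_translate(record, loci[i, ])
    data.frame(transcript_id = cc$transcript_id,
               locus_id = loci$locus_id[i],
               start = cc$start, end = cc$end,
               codon_start = cc$codon_start, codon_end = cc$codon_end,
               peptide = cc$peptide,
               distance_from_cds_start = cc$distance_from_cds_start,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(transcript_id = character(), locus_id = character(),
                      start = integer(), end = integer(),
                      codon_start = integer(), codon_end = integer(),
                      peptide = character(),
                      distance_from_cds_start = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Pooled amino-acid composition of encoded peptides
#'
#' Counts residues over a set of coding contexts (or plain peptides) and
#' ranks amino acids by frequency, ties broken alphabetically. G-rich PG4
#' cassettes translate to glycine-dominated peptides (GGN codons), with
#' R/A/P next -- the composition signature of G4-encoding codons.
#'
#' @param contexts list of `coding_context` objects, a data.frame with a
#'   `peptide` column, or a character vector of peptides.
#' @return data.frame: residue, count, frequency, rank (frequency
#'   descending, alphabetical within ties).
#' @export
aggregate_composition <- function(contexts) {
  peptides <- if (is.character(contexts)) {
    contexts
  } else if (is.data.frame(contexts)) {
    contexts$peptide
  } else {
    vapply(contexts, `[[`, "", "peptide")
  }
  if (length(peptides) == 0L) stop("need at least one context", call. = FALSE)
  aa <- strsplit(paste(peptides, collapse = ""), "", fixed = TRUE)[[1]]
  tab <- table(aa)
  out <- data.frame(residue = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$frequency <- out$count / sum(out$count)
  out <- out[order(-out$count, out$residue), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Detect RGG/RG motifs in a peptide
#'
#' Greedy left-to-right detection of RG and RGG repeat units (RGG preferred
#' when both match), grouped into maximal regions in which consecutive
#' units are separated by at most `max_spacer` non-unit residues. Regions
#' with at least two units are motifs. Classes: `TriRG-like` (>= 3 units),
#' `DiRGG-like` (exactly two adjacent RGG units), else `RG-rich`. The unit
#' grammar is a documented heuristic chosen to recover the canonical
#' printed examples (e.g. RVQRGRGRG and the Aven TriRG peptide).
#'
#' @param peptide amino-acid string, one-letter codes.
#' @param max_spacer maximum residues between consecutive units (default 4).
#' @return data.frame: start, end, unit_count, units, class (zero rows if
#'   no motif).
#' @export
find_rgg_motifs <- function(peptide, max_spacer = 4L) {
  empty <- data.frame(start = integer(), end = integer(),
                      unit_count = integer(), units = character(),
                      class = character(), stringsAsFactors = FALSE)
  n <- nchar(peptide)
  if (n < 4L) return(empty)
  aa <- strsplit(toupper(peptide), "", fixed = TRUE)[[1]]
  # greedy unit scan
  units <- list()
  i <- 1L
  while (i <= n - 1L) {
    if (aa[i] == "R" && aa[i + 1L] == "G") {
      len <- if (i + 2L <= n && aa[i + 2L] == "G") 3L else 2L
      units[[length(units) + 1L]] <- c(start = i, end = i + len - 1L, len = len)
      i <- i + len
    } else {
      i <- i + 1L
    }
  }
  if (length(units) < 2L) return(empty)
  u <- as.data.frame(do.call(rbind, units))
  # group units separated by <= max_spacer residues
  grp <- cumsum(c(1L, as.integer(u$start[-1L] - u$end[-nrow(u)] - 1L > max_spacer)))
  rows <- lapply(split(seq_len(nrow(u)), grp), function(idx) {
    uu <- u[idx, , drop = FALSE]
    if (nrow(uu) < 2L) return(NULL)
    cls <- if (nrow(uu) >= 3L) {
      "TriRG-like"
    } else if (all(uu$len == 3L) && uu$start[2L] == uu$end[1L] + 1L) {
      "DiRGG-like"
    } else {
      "RG-rich"
    }
    data.frame(start = uu$start[1L], end = uu$end[nrow(uu)],
               unit_count = nrow(uu),
               units = paste(ifelse(uu$len == 3L, "RGG", "RG"), collapse = "+"),
               class = cls, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
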