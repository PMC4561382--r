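#' Normalize a nucleotide sequence to the internal RNA alphabet
#'
#' Uppercases and maps T to U. Only A, C, G, U and the ambiguity code N are
#' accepted; any other character is an error naming the first offending
#' position.
#'
#' @param sequence character scalar.
#' @param id optional sequence id used in error messages.
#' @return normalized character scalar.
#' @export
normalize_sequence <- function(sequence, id = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- chartr("T", "U", toupper(sequence))
  bad <- regexpr("[^ACGUN]", s)
  if (bad > 0L) {
    stop(sprintf("illegal character '%s' at position %d%s",
                 substr(s, bad, bad), bad,
                 if (is.null(id)) "" else sprintf(" in sequence '%s'", id)),
         call. = FALSE)
  }
  s
}

#' Create a transcript record
#'
#' A transcript record holds one mRNA (or probe) sequence with an optional
#' CDS start, the 1-based position of the first nucleotide of the initiator
#' AUG. The reading frame of every downstream translation is anchored at
#' `cds_start`; transcript coordinates are never assumed to be CDS-relative.
#'
#' @param id sequence identifier.
#' @param sequence nucleotide string (DNA or RNA alphabet; normalized to RNA).
#' @param description free-text description (defaults to "").
#' @param cds_start optional 1-based position of the initiator AUG.
#' @return an object of class `transcript_record`.
#' @export
transcript_record <- function(id, sequence, description = "", cds_start = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  raw <- toupper(sequence)
  alphabet <- if (grepl("U", raw, fixed = TRUE)) "RNA" else "DNA"
  seq <- normalize_sequence(sequence, id = id)
  if (!is.null(cds_start)) {
    cds_start <- as.integer(cds_start)
    if (is.na(cds_start) || cds_start < 1L || cds_start > nchar(seq)) {
      stop(sprintf("cds_start %s out of range 1..%d for '%s'",
                   cds_start, nchar(seq), id), call. = FALSE)
    }
  }
  structure(
    list(id = id, description = description, sequence = seq,
         source_alphabet = alphabet, cds_start = cds_start),
    class = "transcript_record"
  )
}

#' @export
print.transcript_record <- function(x, ...) {
  cat(sprintf("<transcript_record> %s (%d nt, %s input%s)\n", x$id,
              nchar(x$sequence), x$source_alphabet,
              if (is.null(x$cds_start)) ""
              else sprintf(", cds_start=%d", x$cds_start)))
  invisible(x)
}

#' Read transcript records from a FASTA file
#'
#' Sequences are uppercased and T is mapped to U; the original alphabet
#' (DNA/RNA) is recorded per record. Entry order is preserved. An empty file
#' yields an empty list.
#'
#' @param path FASTA file path.
#' @param cds_starts optional named integer vector (or data.frame as read by
#'   [read_cds_table()]) mapping transcript id to CDS start.
#' @return list of [transcript_record()] objects.
#' @export
read_fasta <- function(path, cds_starts = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (file.size(path) == 0L) return(list())
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    stop(sprintf("malformed FASTA in %s: %s", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  if (is.data.frame(cds_starts)) {
    cds_starts <- setNames(as.integer(cds_starts$cds_start),
                           cds_starts$transcript_id)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  lapply(seq_along(set), function(i) {
    transcript_record(ids[i], as.character(set[[i]]), description = descs[i],
                      cds_start = if (!is.null(cds_starts) && ids[i] %in% names(cds_starts))
                        cds_starts[[ids[i]]] else NULL)
  })
}

#' Write sequences to a FASTA file
#'
#' @param records list of [transcript_record()] objects, or a named character
#'   vector of sequences.
#' @param path output path.
#' @param alphabet "RNA" (default, U) or "DNA" (U restored to T).
#' @return invisibly, `path`.
#' @export
write_fasta <- function(records, path, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (is.character(records)) {
    seqs <- records
  } else {
    seqs <- setNames(vapply(records, `[[`, "", "sequence"),
                     vapply(records, `[[`, "", "id"))
  }
  if (alphabet == "DNA") seqs <- chartr("U", "T", seqs)
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a CDS-start annotation table
#'
#' Tab-separated file with columns `transcript_id` and `cds_start`.
#'
#' @param path TSV path.
#' @return data.frame with columns transcript_id (character), cds_start
#'   (integer).
#' @export
read_cds_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("transcript_id", "cds_start")
  if (!all(need %in% names(df))) {
    stop(sprintf("CDS table %s must have columns: %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  df$cds_start <- as.integer(df$cds_start)
  df[need]
}

#' Export loci to BED
#'
#' Loci use 1-based inclusive transcript coordinates internally; BED is
#' 0-based half-open, so a locus at 223--253 becomes `start=222, end=253`.
#' The name column is `<transcript_id>_PG4_<n>` (or the locus_id column if
#' present), the score column is the cG/cC ratio scaled by 100 and capped at
#' 1000 when a `ratio` column is present, else 0. Rows are ordered by
#' (transcript id, start).
#'
#' @param loci data.frame of loci as returned by [scan_transcript()] (columns
#'   transcript_id, start, end; optionally locus_id, ratio).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(loci, path) {
  if (nrow(loci) > 0 && any(loci$end < loci$start)) {
    stop("locus end < start", call. = FALSE)
  }
  if (nrow(loci) == 0) {
    file.create(path)
    return(invisible(path))
  }
  ord <- order(loci$transcript_id, loci$start)
  loci <- loci[ord, , drop = FALSE]
  nm <- if ("locus_id" %in% names(loci)) loci$locus_id
        else sprintf("%s_PG4_%d", loci$transcript_id,
                     stats::ave(loci$start, loci$transcript_id, FUN = seq_along))
  score <- if ("ratio" %in% names(loci)) {
    pmin(1000, round(100 * ifelse(is.finite(loci$ratio), loci$ratio, 10)))
  } else rep(0L, nrow(loci))
  gr <- GenomicRanges::GRanges(
    seqnames = loci$transcript_id,
    ranges = IRanges::IRanges(start = loci$start, end = loci$end),
    name = nm, score = score
  )
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Import loci from BED
#'
#' Converts the 0-based half-open BED interval back to 1-based inclusive
#' transcript coordinates.
#'
#' @param path BED path.
#' @return data.frame with columns transcript_id, locus_id, start, end.
#' @export
read_bed_loci <- function(path) {
  gr <- rtracklayer::import.bed(path)
  data.frame(
    transcript_id = as.character(GenomicRanges::seqnames(gr)),
    locus_id = if (!is.null(gr$name)) gr$name else NA_character_,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Write a results table as TSV
#'
#' Always writes the header row; floating-point columns are formatted with 4
#' significant digits. Optional provenance lines are written first as
#' `#`-prefixed comments so the file round-trips through
#' [read_results_tsv()].
#'
#' @param rows data.frame.
#' @param path output path.
#' @param provenance optional character vector of provenance lines.
#' @return invisibly, `path`.
#' @export
write_results_tsv <- function(rows, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(paste0("# ", provenance), con)
  }
  out <- rows
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 4))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results TSV written by [write_results_tsv()]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}
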