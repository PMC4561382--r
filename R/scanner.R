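#' PG4 search pattern
#'
#' The potential G-quadruplex pattern Gx-N(1-7)-Gx-N(1-7)-Gx-N(1-7)-Gx:
#' `tract_count` G-tracts of at least `min_tract` guanines separated by
#' loops of `loop_min`..`loop_max` nucleotides of any base.
#'
#' @param tract_count number of G-tracts (default 4).
#' @param min_tract minimum tract length x (default 3).
#' @param loop_min,loop_max loop length bounds in nucleotides (defaults 1, 7).
#' @return object of class `g4_pattern`.
#' @export
g4_pattern <- function(tract_count = 4L, min_tract = 3L,
                       loop_min = 1L, loop_max = 7L) {
  tract_count <- as.integer(tract_count); min_tract <- as.integer(min_tract)
  loop_min <- as.integer(loop_min); loop_max <- as.integer(loop_max)
  if (tract_count < 2L) stop("tract_count must be >= 2", call. = FALSE)
  if (min_tract < 2L) stop("min_tract must be >= 2", call. = FALSE)
  if (loop_min < 1L || loop_min > loop_max) {
    stop("need 0 < loop_min <= loop_max", call. = FALSE)
  }
  structure(list(tract_count = tract_count, min_tract = min_tract,
                 loop_min = loop_min, loop_max = loop_max),
            class = "g4_pattern")
}

#' @export
print.g4_pattern <- function(x, ...) {
  cat(sprintf("<g4_pattern> G(>=%d) x %d tracts, loops %d-%d nt\n",
              x$min_tract, x$tract_count, x$loop_min, x$loop_max))
  invisible(x)
}

#' Find maximal G-tracts
#'
#' Returns every maximal run of consecutive guanines of length at least
#' `min_tract`, left to right. Maximality means the flanking positions are
#' not G; N terminates a run (an ambiguous base is never part of a tract).
#'
#' @param sequence normalized nucleotide string (see [normalize_sequence()]).
#' @param min_tract minimum run length.
#' @return data.frame with columns start, end, length (1-based inclusive).
#' @export
find_tracts <- function(sequence, min_tract = 3L) {
  sequence <- normalize_sequence(sequence)
  empty <- data.frame(start = integer(), end = integer(), length = integer())
  if (nchar(sequence) == 0L) return(empty)
  r <- rle(strsplit(sequence, "", fixed = TRUE)[[1]] == "G")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_tract
  if (!any(keep)) return(empty)
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

#' Enumerate four-tract PG4 hits
#'
#' Every ordered selection of `pattern$tract_count` distinct maximal tracts
#' whose consecutive inter-tract gaps all lie in
#' `[loop_min, loop_max]` yields one hit. Selected tracts need not be
#' adjacent in the tract list: a skipped maximal run simply sits inside a
#' loop (loops admit any base, including G), subject to the loop length
#' bound. Hits are reported in (start, end) order.
#'
#' @param tracts data.frame from [find_tracts()].
#' @param pattern a [g4_pattern()].
#' @return list of hits; each a list with `tract_idx` (row indices into
#'   `tracts`), `start`, `end`, `tracts` (data.frame of the member tracts)
#'   and `loops` (data.frame of loop start/end/length).
#' @export
enumerate_hits <- function(tracts, pattern = g4_pattern()) {
  k <- pattern$tract_count
  n <- nrow(tracts)
  hits <- list()
  if (n < k) return(hits)
  # successors: tracts reachable through one loop
  succ <- lapply(seq_len(n), function(i) {
    j <- which(tracts$start > tracts$end[i])
    gap <- tracts$start[j] - tracts$end[i] - 1L
    j[gap >= pattern$loop_min & gap <= pattern$loop_max]
  })
  chain <- integer(k)
  descend <- function(i, depth) {
    chain[depth] <<- i
    if (depth == k) {
      hits[[length(hits) + 1L]] <<- chain
      return(invisible())
    }
    for (j in succ[[i]]) descend(j, depth + 1L)
  }
  for (i in seq_len(n)) descend(i, 1L)
  hits <- lapply(hits, function(idx) {
    mem <- tracts[idx, , drop = FALSE]
    loops <- data.frame(
      start = mem$end[-k] + 1L,
      end = mem$start[-1L] - 1L
    )
    loops$length <- loops$end - loops$start + 1L
    list(tract_idx = idx, start = mem$start[1L], end = mem$end[k],
         tracts = mem, loops = loops)
  })
  ord <- order(vapply(hits, `[[`, 0L, "start"), vapply(hits, `[[`, 0L, "end"))
  hits[ord]
}

#' Merge overlapping hits into loci
#'
#' Takes the transitive closure of interval overlap among hit spans; each
#' locus is the minimal covering span of its member hits. Locus count -- not
#' raw hit count -- is the per-gene "number of PG4 sequences" statistic:
#' dense tract clusters give many four-tract chains but one region.
#'
#' @param hits list from [enumerate_hits()].
#' @param transcript_id id recorded on each locus.
#' @param sequence optional sequence used to attach the locus subsequence.
#' @return data.frame of class `g4_loci` with columns transcript_id,
#'   locus_id, start, end, n_tracts, tract_spans, loop_lengths, sequence;
#'   member hits attached as attribute `hits` (a list parallel to rows).
#' @export
merge_loci <- function(hits, transcript_id = NA_character_, sequence = NULL) {
  empty <- data.frame(
    transcript_id = character(), locus_id = character(),
    start = integer(), end = integer(), n_tracts = integer(),
    tract_spans = character(), loop_lengths = character(),
    sequence = character(), stringsAsFactors = FALSE
  )
  class(empty) <- c("g4_loci", "data.frame")
  if (length(hits) == 0L) {
    attr(empty, "hits") <- list()
    return(empty)
  }
  spans <- IRanges::IRanges(
    start = vapply(hits, `[[`, 0L, "start"),
    end = vapply(hits, `[[`, 0L, "end")
  )
  merged <- IRanges::reduce(spans)
  ov <- IRanges::findOverlaps(spans, merged)
  member <- split(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))
  rows <- lapply(seq_along(merged), function(i) {
    hs <- hits[member[[as.character(i)]]]
    tr <- unique(do.call(rbind, lapply(hs, `[[`, "tracts")))
    tr <- tr[order(tr$start), , drop = FALSE]
    gaps <- if (nrow(tr) > 1L) tr$start[-1L] - tr$end[-nrow(tr)] - 1L else integer()
    data.frame(
      transcript_id = transcript_id,
      locus_id = sprintf("%s_PG4_%d", transcript_id, i),
      start = IRanges::start(merged)[i],
      end = IRanges::end(merged)[i],
      n_tracts = nrow(tr),
      tract_spans = paste(sprintf("%d-%d", tr$start, tr$end), collapse = ";"),
      loop_lengths = paste(gaps, collapse = ";"),
      sequence = if (is.null(sequence)) NA_character_ else
        substr(sequence, IRanges::start(merged)[i], IRanges::end(merged)[i]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("g4_loci", "data.frame")
  attr(out, "hits") <- lapply(seq_along(merged),
                              function(i) hits[member[[as.character(i)]]])
  out
}

#' Scan one transcript for PG4 loci
#'
#' Composition of [find_tracts()], [enumerate_hits()] and [merge_loci()].
#' Scans the given strand only (mRNA sense); no reverse complement.
#'
#' @param record a [transcript_record()] or a plain nucleotide string.
#' @param pattern a [g4_pattern()].
#' @return `g4_loci` data.frame (zero rows when nothing matches).
#' @export
scan_transcript <- function(record, pattern = g4_pattern()) {
  if (is.character(record)) record <- transcript_record("seq", record)
  tracts <- find_tracts(record$sequence, pattern$min_tract)
  hits <- enumerate_hits(tracts, pattern)
  merge_loci(hits, transcript_id = record$id, sequence = record$sequence)
}

#' Scan a set of transcripts
#'
#' @param records list of [transcript_record()]s (e.g. from [read_fasta()]).
#' @param pattern a [g4_pattern()].
#' @return one `g4_loci` data.frame with all loci, ordered by
#'   (transcript_id, start).
#' @export
scan_transcripts <- function(records, pattern = g4_pattern()) {
  res <- lapply(records, scan_transcript, pattern = pattern)
  out <- do.call(rbind, res)
  if (is.null(out)) out <- merge_loci(list())
  hits <- unlist(lapply(res, attr, "hits"), recursive = FALSE)
  class(out) <- c("g4_loci", "data.frame")
  attr(out, "hits") <- hits
  out
}

#' Loop positions of a locus
#'
#' Positions (transcript coordinates) falling in the loops between the
#' locus's G-tracts; these are the nucleotides expected to bulge out of a
#' folded G4 and show elevated in-line cleavage in K+.
#'
#' @param locus one row of a `g4_loci` data.frame.
#' @return integer vector of positions.
#' @export
locus_loop_positions <- function(locus) {
  tr <- parse_spans(locus$tract_spans)
  if (nrow(tr) < 2L) return(integer())
  unlist(lapply(seq_len(nrow(tr) - 1L), function(i) {
    seq.int(tr$end[i] + 1L, tr$start[i + 1L] - 1L)
  }))
}

# "5-7;15-18" -> data.frame(start, end)
parse_spans <- function(spans) {
  if (is.na(spans) || !nzchar(spans)) {
    return(data.frame(start = integer(), end = integer()))
  }
  parts <- strsplit(strsplit(spans, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  data.frame(start = as.integer(vapply(parts, `[`, "", 1L)),
             end = as.integer(vapply(parts, `[`, "", 2L)))
}
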