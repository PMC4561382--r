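# all generator randomness is scoped: one explicit seed per call, global
# RNG state untouched
with_local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Generate a PG4 cassette with known tract/loop structure
#'
#' Builds `n_tracts` G-tracts of `tract_len` guanines separated by loops of
#' the given lengths drawn from `loop_alphabet` (G excluded by default so
#' the constructed tracts stay maximal and the recorded truth is exact).
#' Deterministic for a seed.
#'
#' @param n_tracts number of tracts (default 4).
#' @param tract_len guanines per tract (default 3; must be >= the scanner's
#'   min_tract to be discoverable).
#' @param loop_lens integer vector of `n_tracts - 1` loop lengths, each in
#'   1..7 for a discoverable cassette.
#' @param loop_alphabet bases loops are drawn from (default A/C/U).
#' @param seed integer seed.
#' @return list with `sequence` and `truth` (class `synthetic_truth`:
#'   seed, tract spans, loop positions, label).
#' @export
make_pg4_cassette <- function(n_tracts = 4L, tract_len = 3L,
                              loop_lens = rep(2L, n_tracts - 1L),
                              loop_alphabet = c("A", "C", "U"),
                              seed = 1L) {
  stopifnot(n_tracts >= 2L, tract_len >= 2L,
            length(loop_lens) == n_tracts - 1L, all(loop_lens >= 1L))
  loops <- with_local_seed(seed, lapply(loop_lens, function(l) {
    paste(sample(loop_alphabet, l, replace = TRUE), collapse = "")
  }))
  tract <- strrep("G", tract_len)
  sequence <- paste0(paste0(tract, c(unlist(loops), "")), collapse = "")
  starts <- cumsum(c(1L, head(tract_len + loop_lens, n_tracts - 1L)))
  tracts <- data.frame(start = starts, end = starts + tract_len - 1L)
  loop_positions <- unlist(lapply(seq_len(n_tracts - 1L), function(i) {
    seq.int(tracts$end[i] + 1L, tracts$start[i + 1L] - 1L)
  }))
  truth <- structure(
    list(seed = seed, label = "positive", start = 1L,
         end = nchar(sequence), tracts = tracts,
         loop_positions = loop_positions),
    class = "synthetic_truth"
  )
  list(sequence = sequence, truth = truth)
}

#' Generate a guaranteed PG4-negative coding-like sequence
#'
#' Random sequence at the requested GC content, post-processed so no
#' maximal G-run reaches `min_tract`: every third consecutive guanine is
#' substituted with C (preserving GC content). Constructed capping is used
#' rather than shuffling because shuffled G-rich sequences can recreate
#' PG4s and poison the negative label.
#'
#' @param length sequence length.
#' @param gc_content target GC fraction in (0, 1); default 0.5.
#' @param min_tract the scanner tract threshold the negative must stay
#'   below (default 3).
#' @param seed integer seed.
#' @return list with `sequence` and `truth` (label "negative", realized gc).
#' @export
make_negative_cds <- function(length, gc_content = 0.5, min_tract = 3L,
                              seed = 1L) {
  stopifnot(length >= 1L, gc_content > 0, gc_content < 1)
  probs <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
             G = gc_content / 2, U = (1 - gc_content) / 2)
  chars <- with_local_seed(seed, sample(names(probs), length,
                                        replace = TRUE, prob = probs))
  run <- 0L
  for (i in seq_len(length)) {
    if (chars[i] == "G") {
      run <- run + 1L
      if (run == min_tract) {       # cap the run below min_tract
        chars[i] <- "C"
        run <- 0L
      }
    } else run <- 0L
  }
  sequence <- paste(chars, collapse = "")
  truth <- structure(
    list(seed = seed, label = "negative", length = length,
         gc_target = gc_content,
         gc_realized = mean(chars %in% c("G", "C"))),
    class = "synthetic_truth"
  )
  list(sequence = sequence, truth = truth)
}

#' Embed a PG4 cassette in a coding backbone
#'
#' Inserts the cassette at the requested transcript position (the cassette's
#' first base lands at `position`) of a PG4-negative backbone, sets
#' `cds_start`, and updates the truth to absolute coordinates. Backbone
#' guanines abutting either junction are substituted with C so the
#' cassette's terminal tracts are not extended: re-scanning then finds
#' exactly the recorded locus and never an unrecorded one (the backbone
#' itself carries no run of `min_tract` guanines). The generator re-checks
#' this invariant and errors if it ever fails.
#'
#' @param cassette result of [make_pg4_cassette()] (or a list with
#'   `sequence` and `truth`).
#' @param backbone PG4-negative backbone sequence (e.g. from
#'   [make_negative_cds()]), or NULL to generate one of `backbone_length`
#'   internally from `seed`.
#' @param position 1-based transcript position where the cassette starts.
#' @param cds_start CDS start recorded on the emitted record (default 1).
#' @param backbone_length backbone length when `backbone` is NULL
#'   (default 1000).
#' @param gc_content backbone GC when generated internally.
#' @param pattern [g4_pattern()] used for the fidelity re-check.
#' @param seed integer seed (backbone generation).
#' @param id record id.
#' @return list with `record` (a [transcript_record()]) and `truth`
#'   (absolute locus coordinates, loop positions, cds_start, seed).
#' @export
embed_in_cds <- function(cassette, backbone = NULL, position = 223L,
                         cds_start = 1L, backbone_length = 1000L,
                         gc_content = 0.5, pattern = g4_pattern(),
                         seed = 1L, id = "synthetic_tx") {
  if (is.null(backbone)) {
    backbone <- make_negative_cds(backbone_length, gc_content,
                                  pattern$min_tract, seed)$sequence
  }
  backbone <- normalize_sequence(backbone)
  cas <- cassette$sequence
  if (position < 1L || position > nchar(backbone) + 1L) {
    stop("position outside backbone", call. = FALSE)
  }
  left <- substr(backbone, 1L, position - 1L)
  right <- substr(backbone, position, nchar(backbone))
  # junction repair: backbone Gs touching the cassette would extend its
  # terminal tracts and shift the recorded coordinates
  left <- sub("G+$", "", left, perl = TRUE) |>
    (\(x) paste0(x, strrep("C", nchar(left) - nchar(x))))()
  ng <- attr(regexpr("^G+", right, perl = TRUE), "match.length")
  if (ng > 0L) right <- paste0(strrep("C", ng), substr(right, ng + 1L,
                                                       nchar(right)))
  sequence <- paste0(left, cas, right)
  record <- transcript_record(id, sequence, cds_start = cds_start)
  tr <- cassette$truth
  shift <- position - 1L
  truth <- structure(
    list(seed = seed, label = "positive",
         start = tr$start + shift, end = tr$end + shift,
         tracts = data.frame(start = tr$tracts$start + shift,
                             end = tr$tracts$end + shift),
         loop_positions = tr$loop_positions + shift,
         cds_start = cds_start,
         distance_from_cds_start = position - cds_start),
    class = "synthetic_truth"
  )
  loci <- scan_transcript(record, pattern)
  ok <- nrow(loci) == 1L && loci$start == truth$start && loci$end == truth$end
  if (!ok) {
    stop("synthetic truth violated after embedding; backbone is not PG4-negative",
         call. = FALSE)
  }
  list(record = record, truth = truth)
}

#' Simulate in-line probing lanes for a locus
#'
#' Baseline intensity 1.0 per position under multiplicative lognormal
#' noise with coefficient of variation `noise_cv` in both conditions;
#' loop positions in the K+ lanes are multiplied by `effect` (G4-dependent
#' loop exposure). Condition and replicate lanes are drawn independently;
#' deterministic per seed. `effect = 1` is the null; `noise_cv = 0` makes
#' every loop-position mean ratio exactly `effect`.
#'
#' @param loop_positions integer positions elevated in K+.
#' @param length profile length L (positions 1..L).
#' @param effect multiplicative K+ elevation at loop positions (default 4).
#' @param noise_cv lognormal coefficient of variation (default 0.05).
#' @param replicates replicate pairs (default 2, as in a two-experiment
#'   design).
#' @param seed integer seed.
#' @param seq_id id recorded on the lanes.
#' @return list with `k_lanes`, `li_lanes` and `truth` (loop positions,
#'   effect, noise_cv, replicates, seed).
#' @export
simulate_probing <- function(loop_positions, length, effect = 4,
                             noise_cv = 0.05, replicates = 2L, seed = 1L,
                             seq_id = "synthetic_probe") {
  stopifnot(length >= 1L, effect > 0, noise_cv >= 0, replicates >= 1L)
  loop_positions <- as.integer(loop_positions)
  if (length(loop_positions) > 0 &&
      (min(loop_positions) < 1L || max(loop_positions) > length)) {
    stop("loop positions outside 1..length", call. = FALSE)
  }
  sdlog <- sqrt(log(1 + noise_cv^2))
  draw <- function() exp(rnorm(length, mean = -sdlog^2 / 2, sd = sdlog))
  lanes <- with_local_seed(seed, {
    k <- lapply(seq_len(replicates), function(r) {
      x <- draw()
      x[loop_positions] <- x[loop_positions] * effect
      lane_profile(seq_id, "K", r, x)
    })
    li <- lapply(seq_len(replicates), function(r) {
      lane_profile(seq_id, "Li", r, draw())
    })
    list(k = k, li = li)
  })
  truth <- structure(
    list(seed = seed, loop_positions = loop_positions, effect = effect,
         noise_cv = noise_cv, replicates = as.integer(replicates),
         length = length),
    class = "synthetic_truth"
  )
  list(k_lanes = lanes$k, li_lanes = lanes$li, truth = truth)
}
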