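# Independent brute-force oracle for the PG4 scanner: enumerate every
# combination of tract_count maximal G-runs and test the gap constraint
# directly; merge loci by a plain sweep. Shares no code with the scanner.

oracle_runs <- function(sequence, min_tract) {
  m <- gregexpr("G+", sequence)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(), end = integer()))
  len <- attr(m, "match.length")
  keep <- len >= min_tract
  data.frame(start = as.integer(m[keep]), end = as.integer(m[keep] + len[keep] - 1L))
}

oracle_scan <- function(sequence, pattern = g4_pattern()) {
  sequence <- chartr("T", "U", toupper(sequence))
  tr <- oracle_runs(sequence, pattern$min_tract)
  k <- pattern$tract_count
  none <- list(hits = data.frame(start = integer(), end = integer()),
               loci = data.frame(start = integer(), end = integer()))
  if (nrow(tr) < k) return(none)
  cmb <- utils::combn(nrow(tr), k)
  ok <- apply(cmb, 2, function(idx) {
    gaps <- tr$start[idx[-1]] - tr$end[idx[-k]] - 1L
    all(gaps >= pattern$loop_min & gaps <= pattern$loop_max)
  })
  sel <- cmb[, ok, drop = FALSE]
  if (ncol(sel) == 0) return(none)
  hits <- data.frame(start = tr$start[sel[1, ]], end = tr$end[sel[k, ]])
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  # sweep-merge overlapping hit spans
  loci <- hits[1, , drop = FALSE]
  for (i in seq_len(nrow(hits))[-1]) {
    j <- nrow(loci)
    if (hits$start[i] <= loci$end[j]) {
      loci$end[j] <- max(loci$end[j], hits$end[i])
    } else {
      loci <- rbind(loci, hits[i, ])
    }
  }
  rownames(hits) <- rownames(loci) <- NULL
  list(hits = hits, loci = loci)
}

random_rna <- function(len, g_prob = 0.25, seed = NULL) {
  draw <- function() {
    other <- (1 - g_prob) / 3
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE,
                 prob = c(other, other, g_prob, other)), collapse = "")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# independent translation oracle (seqinr codon table, DNA alphabet)
oracle_translate <- function(rna) {
  paste(seqinr::translate(strsplit(chartr("U", "T", rna), "")[[1]]),
        collapse = "")
}
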