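test_that("find_tracts reports maximal G-runs only", {
  expect_equal(find_tracts("AGGGA", 3)[, c("start", "end")],
               data.frame(start = 2L, end = 4L))
  expect_equal(nrow(find_tracts("", 3)), 0L)
  expect_equal(nrow(find_tracts("ACUACU", 3)), 0L)
  # the printed MLL1 probe has four tracts of 3, 4, 4 and 5 G
  tr <- find_tracts(fixture_seq("mll1_probe"), 3)
  expect_equal(tr$length, c(3L, 4L, 4L, 5L))
  expect_equal(tr$start, c(5L, 15L, 21L, 30L))
  # N terminates a run
  expect_equal(nrow(find_tracts("GGNGG", 3)), 0L)
  expect_equal(find_tracts("GGNGG", 2)$start, c(1L, 4L))
})

test_that("enumerate_hits applies the loop-length constraint", {
  tr <- find_tracts("GGGAGGGAGGGAGGG", 3)
  hits <- enumerate_hits(tr, g4_pattern())
  expect_length(hits, 1)
  expect_equal(hits[[1]]$start, 1L)
  expect_equal(hits[[1]]$end, 15L)
  expect_equal(hits[[1]]$loops$length, c(1L, 1L, 1L))
  # MLL1 G4m probe retains only two tracts >= 3 G: no hit
  expect_length(enumerate_hits(find_tracts(fixture_seq("mll1_probe_g4m"), 3),
                               g4_pattern()), 0)
  # MLL4 G4m probe keeps four tracts but one gap is 8 nt > loop_max
  tr4 <- find_tracts(fixture_seq("mll4_probe_g4m"), 3)
  expect_equal(nrow(tr4), 4L)
  expect_length(enumerate_hits(tr4, g4_pattern()), 0)
})

test_that("merge_loci takes the transitive closure of overlap", {
  mk_hit <- function(s, e) list(start = s, end = e,
                                tracts = data.frame(start = s, end = e))
  loci <- merge_loci(list(mk_hit(10L, 40L), mk_hit(100L, 130L)), "t1")
  expect_equal(nrow(loci), 2L)
  expect_equal(loci$start, c(10L, 100L))
  expect_equal(nrow(merge_loci(list())), 0L)
  # six 4-G tracts with 2-nt loops on the MLL4 probe collapse to one locus
  wt <- fixture_seq("mll4_probe")
  loci <- scan_transcript(wt)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$start, 6L)
  expect_equal(loci$end, 39L)
  expect_equal(loci$n_tracts, 6L)
  expect_equal(loci$loop_lengths, "2;2;2;2;2")
})

test_that("scan_transcript reproduces the printed match/no-match outcomes", {
  counts <- fixture_locus_counts()
  fx <- probe_fixtures()
  got <- vapply(seq_len(nrow(fx)), function(i) {
    nrow(scan_transcript(transcript_record(fx$name[i], fx$sequence[i])))
  }, 0L)
  expect_equal(setNames(got, fx$name), counts)
  # sc1 is built from two-guanine tracts: invisible at x >= 3, found at x >= 2
  expect_gte(nrow(scan_transcript(fixture_seq("sc1"), g4_pattern(min_tract = 2))), 1L)
  expect_equal(nrow(scan_transcript(strrep("A", 100))), 0L)
})

test_that("scanner agrees with the brute-force oracle on random sequences", {
  withr::with_seed(402, {
    for (i in 1:80) {
      s <- random_rna(sample(20:200, 1), g_prob = sample(c(0.25, 0.4, 0.5), 1))
      got <- scan_transcript(s)
      exp <- oracle_scan(s)
      expect_equal(nrow(got), nrow(exp$loci), info = s)
      if (nrow(got) > 0) {
        expect_equal(got$start, exp$loci$start, info = s)
        expect_equal(got$end, exp$loci$end, info = s)
      }
    }
  })
})

test_that("scanning is invariant under T-for-U substitution", {
  withr::with_seed(7, {
    for (i in 1:20) {
      s <- random_rna(150, g_prob = 0.4)
      t <- chartr("U", "T", s)
      a <- scan_transcript(s); b <- scan_transcript(t)
      expect_equal(a$start, b$start)
      expect_equal(a$end, b$end)
    }
  })
})

test_that("hit count is monotone in min_tract and loop_max", {
  n_hits <- function(s, pat) {
    sum(vapply(attr(scan_transcript(s, pat), "hits"), length, 0L))
  }
  withr::with_seed(11, {
    for (i in 1:20) {
      s <- random_rna(150, g_prob = 0.45)
      expect_gte(n_hits(s, g4_pattern(min_tract = 2)),
                 n_hits(s, g4_pattern(min_tract = 3)))
      expect_gte(n_hits(s, g4_pattern(loop_max = 9)),
                 n_hits(s, g4_pattern(loop_max = 7)))
    }
  })
})

test_that("loci from one scan never overlap each other", {
  withr::with_seed(23, {
    n_multi <- 0L
    for (i in 1:30) {
      # two cassettes far apart embedded in a random backdrop
      s <- paste0(
        random_rna(30, 0.3),
        make_pg4_cassette(loop_lens = sample(1:7, 3, TRUE),
                          seed = sample.int(1e6, 1))$sequence,
        random_rna(sample(20:60, 1), 0.3),
        make_pg4_cassette(loop_lens = sample(1:7, 3, TRUE),
                          seed = sample.int(1e6, 1))$sequence,
        random_rna(30, 0.3))
      loci <- scan_transcript(s)
      if (nrow(loci) > 1) {
        n_multi <- n_multi + 1L
        expect_true(all(loci$start[-1] > loci$end[-nrow(loci)]))
      }
    }
    expect_gt(n_multi, 0)  # the property was actually exercised
  })
})

test_that("locus loop positions exclude every tract position", {
  loci <- scan_transcript(fixture_seq("mll4_probe"))
  loops <- locus_loop_positions(loci[1, ])
  expect_equal(length(loops), 10L)  # five 2-nt loops
  tr <- find_tracts(fixture_seq("mll4_probe"), 3)
  tract_pos <- unlist(Map(seq.int, tr$start, tr$end))
  expect_length(intersect(loops, tract_pos), 0)
})

test_that("pattern parameters are validated", {
  expect_error(g4_pattern(tract_count = 1), "tract_count")
  expect_error(g4_pattern(min_tract = 1), "min_tract")
  expect_error(g4_pattern(loop_min = 0), "loop_min")
  expect_error(g4_pattern(loop_min = 5, loop_max = 3), "loop_min")
})
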