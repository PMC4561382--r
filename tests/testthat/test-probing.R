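test_that("lane normalization: none is identity, total sums to 1 and is idempotent", {
  lane <- lane_profile("s", "K", 1, c(2, 2))
  expect_identical(normalize_lane(lane, "none"), lane)
  tot <- normalize_lane(lane, "total")
  expect_equal(tot$intensities, c(0.5, 0.5))
  expect_equal(normalize_lane(tot, "total")$intensities, tot$intensities)
  expect_error(normalize_lane(lane_profile("s", "K", 1, c(0, 0)), "total"),
               "all-zero")
  expect_error(lane_profile("s", "K", 1, c(-1, 2)), ">= 0")
})

test_that("identical K and Li lanes give unit ratios and no calls", {
  x <- c(1, 2, 3, 4)
  res <- ratio_profile(lane_profile("s", "K", 1, x),
                       lane_profile("s", "Li", 1, x))
  expect_equal(res$table$mean_ratio, rep(1, 4))
  expect_false(any(res$table$call))
})

test_that("the twofold call is strict: a mean ratio of exactly 2 is not called", {
  li <- lane_profile("s", "Li", 1, c(1, 1, 1))
  k <- lane_profile("s", "K", 1, c(2, 2.001, 1.999))
  res <- ratio_profile(k, li)
  expect_equal(res$table$call, c(FALSE, TRUE, FALSE))
})

test_that("zero Li intensity flags the position instead of producing infinity", {
  k <- list(lane_profile("s", "K", 1, c(4, 4)), lane_profile("s", "K", 2, c(4, 4)))
  li <- list(lane_profile("s", "Li", 1, c(0, 1)), lane_profile("s", "Li", 2, c(1, 1)))
  res <- ratio_profile(k, li)
  expect_true(res$table$flagged[1])
  expect_false(res$table$flagged[2])
  expect_equal(res$table$mean_ratio[1], 4)    # surviving replicate only
  expect_equal(res$table$n_replicates, c(1L, 2L))
  expect_true(is.na(res$table$sd_ratio[1]))   # sd needs >= 2 replicates
  expect_false(is.na(res$table$sd_ratio[2]))
})

test_that("replicate pairing and position alignment are validated", {
  k <- lane_profile("s", "K", 1, c(1, 2))
  expect_error(ratio_profile(list(k), list()), "unpaired")
  expect_error(ratio_profile(k, lane_profile("s", "Li", 2, c(1, 2))),
               "replicate indices")
  expect_error(ratio_profile(k, lane_profile("s", "Li", 1, c(1, 2, 3))),
               "position ranges")
})

test_that("ratios scale with the K condition and cancel joint scaling", {
  withr::with_seed(37, {
    k <- lapply(1:2, function(r) lane_profile("s", "K", r, runif(10, 0.5, 2)))
    li <- lapply(1:2, function(r) lane_profile("s", "Li", r, runif(10, 0.5, 2)))
    base <- ratio_profile(k, li)
    scale_k <- lapply(k, function(p) { p$intensities <- 3 * p$intensities; p })
    scale_li <- lapply(li, function(p) { p$intensities <- 3 * p$intensities; p })
    up <- ratio_profile(scale_k, li)
    expect_equal(up$table$mean_ratio, 3 * base$table$mean_ratio)
    both <- ratio_profile(scale_k, scale_li)
    expect_equal(both$table$mean_ratio, base$table$mean_ratio)
  })
})

test_that("mean and sd agree with direct recomputation on random inputs", {
  withr::with_seed(41, {
    for (i in 1:10) {
      L <- 12
      k <- lapply(1:3, function(r) lane_profile("s", "K", r, runif(L, 0.1, 3)))
      li <- lapply(1:3, function(r) lane_profile("s", "Li", r, runif(L, 0.1, 3)))
      res <- ratio_profile(k, li)
      mat <- sapply(1:3, function(r) k[[r]]$intensities / li[[r]]$intensities)
      expect_equal(res$table$mean_ratio, rowMeans(mat))
      expect_equal(res$table$sd_ratio, apply(mat, 1, sd))
    }
  })
})

test_that("region calls require individually called predicted-loop positions", {
  li <- lane_profile("s", "Li", 1, rep(1, 10))
  quiet <- ratio_profile(lane_profile("s", "K", 1, rep(1, 10)), li)
  expect_false(call_region(quiet, c(4, 5))$region_call)
  # calls only outside the predicted loops do not support the region
  k <- lane_profile("s", "K", 1, c(5, rep(1, 9)))
  outside <- call_region(ratio_profile(k, li), c(4, 5))
  expect_false(outside$region_call)
  expect_length(outside$supporting_positions, 0)
  # calls at the loops do
  k <- lane_profile("s", "K", 1, c(1, 1, 1, 5, 5, rep(1, 5)))
  inside <- call_region(ratio_profile(k, li), c(4, 5), min_support = 2)
  expect_true(inside$region_call)
  expect_equal(inside$supporting_positions, c(4L, 5L))
  expect_error(call_region(quiet, 99), "outside")
})

test_that("a simulated MLL4 probing profile is called at its predicted loops", {
  wt <- fixture_seq("mll4_inline")
  loci <- scan_transcript(wt)
  loops <- locus_loop_positions(loci[1, ])
  sim <- simulate_probing(loops, nchar(wt), effect = 4, noise_cv = 0.05,
                          replicates = 2, seed = 404)
  res <- call_region(ratio_profile(sim$k_lanes, sim$li_lanes), loops)
  expect_true(res$region_call)
  expect_gte(length(res$supporting_positions), 1)
})

test_that("at null effect the loop call rate matches the off-loop false-positive rate", {
  loops <- 11:14
  rates <- withr::with_seed(53, {
    hits_loop <- 0; hits_off <- 0; n_loop <- 0; n_off <- 0
    for (i in 1:200) {
      sim <- simulate_probing(loops, 30, effect = 1, noise_cv = 0.05,
                              replicates = 2, seed = sample.int(1e6, 1))
      res <- ratio_profile(sim$k_lanes, sim$li_lanes)
      hits_loop <- hits_loop + sum(res$table$call[loops])
      hits_off <- hits_off + sum(res$table$call[-loops])
      n_loop <- n_loop + length(loops); n_off <- n_off + 30 - length(loops)
    }
    c(loop = hits_loop / n_loop, off = hits_off / n_off)
  })
  # CV 5% over 2 replicates puts a 2-fold change far in the tail: both rates ~ 0
  expect_lt(rates["loop"], 0.02)
  expect_lt(abs(rates["loop"] - rates["off"]), 0.02)
})

test_that("probing TSV round trips through the documented schema", {
  sim <- simulate_probing(c(4, 5), 8, replicates = 2, seed = 9)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_probing_tsv(c(sim$k_lanes, sim$li_lanes), f)
  back <- read_probing_tsv(f)
  expect_named(back, "synthetic_probe")
  expect_length(back$synthetic_probe$k_lanes, 2)
  expect_length(back$synthetic_probe$li_lanes, 2)
  res_a <- ratio_profile(sim$k_lanes, sim$li_lanes)
  res_b <- ratio_profile(back$synthetic_probe$k_lanes,
                         back$synthetic_probe$li_lanes)
  expect_equal(res_b$table$mean_ratio, res_a$table$mean_ratio,
               tolerance = 1e-3)   # 4 significant digits on disk
})
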