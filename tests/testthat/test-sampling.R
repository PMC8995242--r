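test_that("golden-angle indexing reproduces the canonical sequence", {
  expect_equal(golden_angle(0), 0)
  expect_equal(round(golden_angle(1), 2), 111.25)
  expect_equal(round(golden_angle(2), 2), 222.49)
  # full-precision invariant
  N <- 0:500
  expect_equal(golden_angle(N), (N * 360 / (1 + sqrt(5))) %% 360,
               tolerance = 1e-12)
  expect_error(golden_angle(-1), "integer")
})

test_that("serial sorting is the identity assignment", {
  plan <- serial_sort(3)
  expect_equal(plan$golden_index, 1:3)
  expect_equal(plan$angle_deg, golden_angle(1:3))
  expect_equal(attr(plan, "mode"), "serial")
  p1 <- serial_sort(1)
  expect_equal(round(p1$angle_deg, 2), 111.25)
})

test_that("bloch sorting ranks by signal with stable tie-breaks", {
  # strictly decreasing -> identity
  expect_equal(bloch_sort(fake_prediction(c(5, 4, 3, 2)))$golden_index, 1:4)
  # constant -> identity via chronological tie-break
  expect_equal(bloch_sort(fake_prediction(rep(1, 6)))$golden_index, 1:6)
  # increasing -> reversal
  expect_equal(bloch_sort(fake_prediction(c(1, 2, 3, 4)))$golden_index, 4:1)
  # property: reordering by golden index is non-increasing; oracle = stable
  # sort by decreasing signal
  set.seed(7)
  for (rep in 1:20) {
    s <- round(stats::runif(30), 2)            # duplicates likely
    plan <- bloch_sort(fake_prediction(s))
    sorted <- s[order(plan$golden_index)]
    expect_true(all(diff(sorted) <= 0))
    oracle <- order(-s)                        # order() is stable
    expect_equal(order(plan$golden_index), oracle)
  }
})

test_that("patterns report the protocol counts", {
  seq <- sequence_params()                     # 13 x 8, NR 4
  pat <- build_pattern(seq, tissue_params(T1 = 1400, T1rho0 = 40),
                       mode = "bloch")
  expect_equal(attr(pat, "n_preparations"), 104)
  expect_equal(attr(pat, "n_spokes"), 416)
  expect_equal(nrow(pat), 416)
  # golden_index is a bijection and angles follow the golden-angle rule
  expect_setequal(pat$golden_index, 1:416)
  expect_equal(pat$angle_deg, golden_angle(pat$golden_index))
  # each weighting has exactly n_prep first-readout spokes
  tab <- table(pat$weighting_id[pat$readout_pos == 1])
  expect_true(all(tab == 13))
  # degenerate single-spoke protocol
  p1 <- build_pattern(sequence_params(t_SL_list = 5, n_prep = 1, NR = 1),
                      tissue_params(), mode = "serial")
  expect_equal(attr(p1, "n_spokes"), 1)
})

test_that("serial and bloch patterns use the same angle multiset", {
  seq <- small_seq()
  tis <- tissue_params(T1 = 1400, T1rho0 = 40)
  pb <- build_pattern(seq, tis, mode = "bloch")
  ps <- build_pattern(seq, tis, mode = "serial")
  expect_equal(sort(pb$angle_deg), sort(ps$angle_deg))
})

test_that("protocol arithmetic matches the published counts", {
  pc <- protocol_counts(sequence_params(f_SL_list = seq(750, 2500,
                                                        length.out = 8)))
  expect_equal(pc$n_preparations, 104)
  expect_equal(pc$n_spokes, 416)
  expect_equal(pc$n_preparations_cartesian, 256)     # (128/4) x 8
  expect_equal(pc$n_preparations_dispersion, 832)    # 8 x 8 x 13
  expect_equal(pc$acceleration, 32 / 13)
})

test_that("consecutive golden-angle runs are azimuthally near-uniform", {
  # runs whose length is a denominator of the golden angle's continued
  # fraction (13, 55, 233) have exactly two distinct gaps; other Fibonacci
  # lengths have at most three (three-distance theorem), with the largest
  # gap below phi^3 times the smallest
  gap_stats <- function(start, F) {
    a <- sort(golden_angle(start + seq_len(F)))
    gaps <- diff(c(a, a[1] + 360))
    list(n = length(unique(round(gaps, 6))), ratio = max(gaps) / min(gaps))
  }
  phi <- (1 + sqrt(5)) / 2
  for (start in c(0, 17, 200)) {
    for (F in c(13, 55, 233)) expect_lte(gap_stats(start, F)$n, 2)
    for (F in c(21, 34)) {
      gs <- gap_stats(start, F)
      expect_lte(gs$n, 3)
      expect_lte(gs$ratio, phi^3 + 1e-9)
    }
  }
})

test_that("sorting deviation measures departure from monotone order", {
  seq <- small_seq()
  pred <- simulate_timeline(seq, tissue_params(T1 = 1400, T1rho0 = 40))
  plan <- bloch_sort(pred)
  # noiseless measured = predicted: sorted by construction
  expect_equal(sorting_deviation(plan, pred$signal), 0)
  # monotone decreasing under identity plan
  expect_equal(sorting_deviation(serial_sort(4), c(4, 3, 2, 1)), 0)
  # hand-computed: [2, 3] -> deviations (0, (3-2)/3), mean 1/6
  expect_equal(sorting_deviation(serial_sort(2), c(2, 3)), 1 / 6)
  expect_error(sorting_deviation(serial_sort(3), c(1, 2)), "per spoke")
})
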