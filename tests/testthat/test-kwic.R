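make_filter <- function(n_phi, r_hi = Inf, spokes = seq_len(n_phi),
                        matrix = 32) {
  structure(list(weighting = 1L, f_nyq = 1.1, matrix = matrix,
                 annuli = data.frame(n_phi = n_phi, r_lo = 0, r_hi = r_hi),
                 spoke_sets = list(spokes)),
            class = "kwic_filter")
}

test_that("filter design yields nested Fibonacci annuli meeting Nyquist", {
  seq <- sequence_params()                     # matrix 128, 13 x 8 x 4
  pat <- build_pattern(seq, tissue_params(T1 = 1400, T1rho0 = 40), mode = "bloch")
  fl <- design_kwic(pat, f_nyq = 1.1)
  expect_length(fl, 8)
  for (w in seq_along(fl)) {
    f <- fl[[w]]
    ann <- f$annuli
    # Fibonacci counts, strictly increasing, outermost 233 for 128 matrix
    expect_equal(ann$n_phi, c(13, 21, 34, 55, 89, 144, 233))
    # innermost: exactly the n_prep first-readout spokes of weighting w
    ctr <- pat$chronological_index[pat$weighting_id == w &
                                     pat$readout_pos == 1]
    expect_setequal(f$spoke_sets[[1]], ctr)
    # nesting and set sizes
    for (j in seq_len(nrow(ann))) {
      expect_length(f$spoke_sets[[j]], ann$n_phi[j])
      if (j > 1) expect_true(all(f$spoke_sets[[j - 1]] %in%
                                   f$spoke_sets[[j]]))
    }
    # Nyquist audit over every admitted sample radius
    k_radii <- seq(-seq$matrix / 2, seq$matrix / 2 - 1 / seq$os_read,
                   by = 1 / seq$os_read)
    expect_true(kwic_audit(f, k_radii))
    # innermost radius from the analytic inversion
    expect_equal(ann$r_hi[1], 13 / (pi * 1.1), tolerance = 1e-12)
  }
})

test_that("a matrix small enough for the center alone gives one annulus", {
  seq <- small_seq(matrix = 6, n_prep = 13, NR = 2, t_SL_list = c(10, 40))
  pat <- build_pattern(seq, tissue_params(T1 = 1400, T1rho0 = 40), mode = "bloch")
  fl <- design_kwic(pat, matrix = 6, f_nyq = 1.1)
  expect_equal(nrow(fl[[1]]$annuli), 1)
  expect_length(fl[[1]]$spoke_sets[[1]], 13)
})

test_that("insufficient spokes for the edge Nyquist condition are rejected", {
  seq <- small_seq(matrix = 128, n_prep = 2, NR = 2, t_SL_list = c(10, 40))
  pat <- build_pattern(seq, tissue_params(T1 = 1400, T1rho0 = 40), mode = "bloch")
  expect_error(design_kwic(pat, f_nyq = 1.1), "at least")
})

test_that("density weights are annulus-normalized ramps", {
  k_radii <- seq(-4, 3.5, by = 0.5)
  ang4 <- c(0, 45, 90, 135)                    # 8 uniform directions
  w4 <- density_weights(make_filter(4), k_radii, ang4)
  # ramp: same spoke, radii 1 and 2 -> ratio 2
  i1 <- which(k_radii == 1); i2 <- which(k_radii == 2)
  expect_equal(w4[1, i2] / w4[1, i1], 2)
  # doubling the spoke count halves the per-spoke weight at equal radius
  ang8 <- seq(0, 157.5, by = 22.5)
  w8 <- density_weights(make_filter(8), k_radii, ang8)
  expect_equal(w8[1, i1] / w4[1, i1], 0.5)
  # excluded spokes get zero
  wpart <- density_weights(make_filter(2, spokes = c(1, 3)), k_radii, ang4)
  expect_true(all(wpart[c(2, 4), ] == 0))
  # DC weight is the disk-area element
  idc <- which(k_radii == 0)
  expect_equal(w4[1, idc], pi / 4 * 0.5^2 / 4)
})

test_that("reconstruction is linear and zero maps to zero", {
  seq <- small_seq()
  tis <- tissue_params(T1 = 1400, T1rho0 = 40)
  pat <- build_pattern(seq, tis, mode = "bloch")
  ph <- small_phantom()
  ks1 <- simulate_kspace(ph, pat)
  fl <- design_kwic(pat)
  ks0 <- ks1; ks0$samples[] <- 0
  expect_true(all(reconstruct_series(ks0, fl)$images == 0))

  ks2 <- ks1; ks2$samples <- ks1$samples * (0.3 + 0.4i)
  r1 <- reconstruct_series(ks1, fl, magnitude = FALSE)
  r2 <- reconstruct_series(ks2, fl, magnitude = FALSE)
  expect_equal(r2$images, r1$images * (0.3 + 0.4i), tolerance = 1e-10)
})

test_that("gridding reconstruction matches the direct-sum oracle", {
  seq <- small_seq()
  tis <- tissue_params(T1 = 1400, T1rho0 = 40)
  pat <- build_pattern(seq, tis, mode = "bloch")
  ks <- simulate_kspace(small_phantom(), pat)
  fl <- design_kwic(pat)
  fast <- reconstruct_series(ks, fl)
  slow <- reconstruct_series(ks, fl, oracle = TRUE)
  for (w in seq_along(seq$t_SL_list)) {
    rel <- sqrt(mean((fast$images[, , w] - slow$images[, , w])^2)) /
      sqrt(mean(slow$images[, , w]^2))
    expect_lt(rel, 1e-3)
  }
})

test_that("tube-interior decay of the reconstructed series tracks T1rho", {
  seq <- phantom_protocol(matrix = 64)
  ph <- make_bsa_phantom(matrix = 64)
  pat <- build_pattern(seq, phantom_prior(), mode = "bloch")
  ks <- simulate_kspace(ph, pat)
  ser <- reconstruct_series(ks, design_kwic(pat))
  ref <- reference_series(ph, pat)
  ras <- rasterize_phantom(ph)
  # interior means of the KWIC series stay within ten percent of the
  # matched fully-sampled reference at every weighting
  for (i in seq_along(ras$masks)) {
    m <- erode_mask(ras$masks[[i]], 2)
    r <- vapply(1:8, function(w)
      mean(ser$images[, , w][m]) / mean(ref$images[, , w][m]), 0)
    expect_true(all(abs(r - 1) < 0.10))
  }
})
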