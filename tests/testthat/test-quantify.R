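mk_series <- function(arr, t_SL, f_SL = 1500, fov = 38.4) {
  structure(list(images = arr, t_SL_list = t_SL, f_SL = f_SL, fov = fov,
                 mode = "synthetic", f_nyq = NA), class = "image_series")
}

test_that("noiseless mono-exponential data is fitted exactly", {
  t <- seq(4, 60, length.out = 8)
  n <- 6
  arr <- array(0, c(n, n, 8))
  for (w in 1:8) arr[, , w] <- exp(-t[w] / 40)
  map <- fit_t1rho(mk_series(arr, t))
  expect_equal(unname(map$t1rho[3, 3]), 40, tolerance = 1e-6)
  expect_equal(unname(map$r2[3, 3]), 1, tolerance = 1e-6)
})

test_that("two-point fits reduce to the closed-form solution", {
  a <- 0.9; b <- 0.2
  arr <- array(c(matrix(a, 2, 2), matrix(b, 2, 2)), c(2, 2, 2))
  map <- fit_t1rho(mk_series(arr, c(4, 60)))
  expect_equal(unname(map$t1rho[1, 1]), 56 / log(a / b), tolerance = 1e-8)
})

test_that("degenerate pixels are masked, never fitted to nonsense", {
  t <- c(5, 20, 50, 90)
  arr <- array(0, c(3, 3, 4))
  arr[1, 1, ] <- 1                          # constant: no decay
  arr[2, 2, ] <- exp(-t / 30)
  arr[3, 3, ] <- c(1, -0.1, 0.5, 0.2)       # non-positive sample
  map <- fit_t1rho(mk_series(arr, t), mask_threshold = 0)
  expect_false(map$mask[1, 1])
  expect_true(map$mask[2, 2])
  expect_false(map$mask[3, 3])
  expect_true(all(is.na(map$t1rho[!map$mask])))
  expect_true(all(map$t1rho[map$mask] > 0))
})

test_that("the vectorized fitter agrees with nls pixel by pixel", {
  skip_if_not_installed("minpack.lm")
  set.seed(21)
  t <- seq(4, 102, length.out = 8)
  n <- 4
  arr <- array(0, c(n, n, 8))
  truth <- matrix(runif(n * n, 25, 90), n, n)
  for (w in 1:8) arr[, , w] <- exp(-t[w] / truth) + rnorm(n * n, sd = 0.01)
  arr <- abs(arr)
  map <- fit_t1rho(mk_series(arr, t), mask_threshold = 0)
  for (i in 1:n) for (j in 1:n) {
    y <- arr[i, j, ]
    ft <- minpack.lm::nlsLM(y ~ A * exp(-t / T1r),
                            start = list(A = y[1], T1r = 50))
    expect_equal(unname(map$t1rho[i, j]), unname(coef(ft)["T1r"]),
                 tolerance = 1e-4)
  }
})

test_that("fitting the engine's ground-truth images introduces no bias", {
  # equal pre-preparation magnetization (huge t_rec): recovery is exact
  seq <- small_seq(t_rec = 1e7, t_SL_list = seq(5, 80, length.out = 5))
  ph <- small_phantom()
  gt <- ground_truth_images(ph, seq, f_SL = 1200)
  map <- fit_t1rho(gt)
  ras <- rasterize_phantom(ph)
  for (i in 1:2) {
    tt <- t1rho_effective(ph$shapes[[i]]$tissue, 1200)
    expect_equal(mean(map$t1rho[ras$masks[[i]]]), tt, tolerance = 1e-6)
  }
})

test_that("dispersion fits recover the linear model exactly", {
  f <- seq(750, 2500, length.out = 8)
  n <- 5
  mk_map <- function(vals, fsl) {
    structure(list(t1rho = matrix(vals, n, n), s0 = matrix(1, n, n),
                   r2 = matrix(1, n, n), mask = matrix(TRUE, n, n),
                   f_SL = fsl, fov = 38.4), class = "t1rho_map")
  }
  # reference 20% tube values as ground truth
  maps <- lapply(f, function(fs) mk_map(36.11 + 5.73 * fs / 1000, fs))
  dm <- fit_dispersion(maps)
  expect_equal(unname(dm$offset[2, 2]), 36.11, tolerance = 1e-6)
  expect_equal(unname(dm$slope[2, 2]), 5.73, tolerance = 1e-6)
  expect_true(all(dm$r2_disp >= 1 - 1e-9))
  # identical maps: zero slope, offset equal to the value
  maps0 <- lapply(f, function(fs) mk_map(42, fs))
  dm0 <- fit_dispersion(maps0)
  expect_equal(unname(dm0$slope[1, 1]), 0, tolerance = 1e-12)
  expect_equal(unname(dm0$offset[1, 1]), 42, tolerance = 1e-9)
  expect_error(fit_dispersion(maps[1]), "2")
})

test_that("noisy dispersion estimates are unbiased", {
  set.seed(31)
  f <- seq(750, 2500, length.out = 8)
  n_px <- 200
  Y <- outer(rep(1, n_px), 36.11 + 5.73 * f / 1000) +
    matrix(rnorm(n_px * 8, sd = 1), n_px, 8)
  mk_map <- function(col, fsl) {
    structure(list(t1rho = matrix(Y[, col], 20, 10), s0 = matrix(1, 20, 10),
                   r2 = matrix(1, 20, 10), mask = matrix(TRUE, 20, 10),
                   f_SL = fsl, fov = 38.4), class = "t1rho_map")
  }
  dm <- fit_dispersion(lapply(seq_along(f), function(i) mk_map(i, f[i])))
  expect_lt(abs(mean(dm$slope) - 5.73), 0.1)
})

test_that("SNR follows its definition and rejects degenerate masks", {
  img <- matrix(2, 8, 8)
  sig <- matrix(FALSE, 8, 8); sig[2:3, 2:3] <- TRUE
  noi <- matrix(FALSE, 8, 8); noi[6:8, 6:8] <- TRUE
  img[sig] <- 40
  expect_error(snr_metric(img, list(sig), noi), "zero variance")
  set.seed(4)
  img[noi] <- rnorm(sum(noi), sd = 2)
  expect_equal(snr_metric(img, list(sig), noi), 40 / sd(img[noi]))
  expect_error(snr_metric(img, list(sig), sig), "disjoint")
  expect_error(snr_metric(img, list(sig & FALSE), noi), "nonempty")
})

test_that("delta-Q reports pixel-wise relative errors over an ROI", {
  ref <- matrix(50, 6, 6)
  roi <- matrix(TRUE, 6, 6)
  d0 <- delta_q(ref, ref, roi)
  expect_equal(d0$mean, 0); expect_equal(d0$std, 0)
  d2 <- delta_q(1.02 * ref, ref, roi)
  expect_equal(d2$mean, 2, tolerance = 1e-12)
  expect_equal(d2$std, 0)
  ref0 <- ref; ref0[1, 1] <- 0
  expect_error(delta_q(ref, ref0, roi), "zeros")
})

test_that("mask erosion shrinks regions by the requested margin", {
  m <- disk_mask(32, 32, c(0, 0), 8)
  e <- erode_mask(m, 2)
  expect_true(all(e[m == FALSE] == FALSE))
  expect_lt(sum(e), sum(m))
  # eroded pixels are at least 2 pixels from the boundary
  expect_true(all(erode_mask(m, 2) == (disk_mask(32, 32, c(0, 0), 8) &
                                         erode_mask(m, 2))))
})
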