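## Pixel-wise quantification: mono-exponential T1rho fitting of the weighted
## image series, linear dispersion fitting across spin-lock amplitudes, and
## the evaluation metrics (SNR, relative quantification error, ROI stats).

#' Pixel-wise mono-exponential T1rho fit
#'
#' Fits S(t_SL) = S0 * exp(-t_SL / T1rho) to each pixel of a magnitude image
#' series by unweighted nonlinear least squares. Initialization is the
#' log-linear regression of log S on t_SL; refinement uses a vectorized
#' Levenberg-Marquardt iteration over all pixels simultaneously. Pixels
#' whose shortest-t_SL signal falls below `mask_threshold` times the image
#' maximum, pixels with non-finite or non-positive signals, and pixels whose
#' fit does not yield a positive decay rate are masked out rather than
#' reported.
#'
#' @param series an `image_series` (magnitude).
#' @param mask_threshold intensity threshold, fraction of the maximum of the
#'   shortest-t_SL image.
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @return A `t1rho_map`: list with matrices `t1rho` (ms), `s0`, `r2`,
#'   logical `mask`, and `f_SL` (Hz). Unmasked entries are `NA`.
#' @export
fit_t1rho <- function(series, mask_threshold = 0.05, max_iter = 50) {
  stopifnot(inherits(series, "image_series"))
  t <- series$t_SL_list
  W <- length(t)
  if (W < 2) stop("need at least two weightings to fit T1rho")
  dims <- dim(series$images)
  S <- matrix(series$images, prod(dims[1:2]), W)   # pixels x weightings

  first <- S[, which.min(t)]
  ok <- first >= mask_threshold * max(first, na.rm = TRUE)
  ok <- ok & apply(is.finite(S) & S > 0, 1, all)
  idx <- which(ok)

  t1rho <- s0 <- r2 <- rep(NA_real_, nrow(S))
  if (length(idx)) {
    Y <- S[idx, , drop = FALSE]
    L <- log(Y)
    # log-linear init: log S = log S0 - t/T1rho
    tc <- t - mean(t)
    beta <- (L %*% tc) / sum(tc^2)                 # slope per pixel
    lnS0 <- rowMeans(L) - beta * mean(t)
    R <- pmax(as.vector(-beta), 1e-6)              # decay rate 1/ms
    A <- pmin(exp(as.vector(lnS0)), 10 * apply(Y, 1, max))

    sse <- function(A, R) {
      E <- exp(-outer(R, t))
      rowSums((Y - A * E)^2)
    }
    lambda <- rep(1e-3, length(idx))
    f_old <- sse(A, R)
    for (it in seq_len(max_iter)) {
      E <- exp(-outer(R, t))
      Resid <- Y - A * E
      # Jacobian columns: d/dA = E, d/dR = -A * t * E
      J2 <- -A * E * rep(t, each = length(A))
      a11 <- rowSums(E * E)
      a12 <- rowSums(E * J2)
      a22 <- rowSums(J2 * J2)
      g1 <- rowSums(E * Resid)
      g2 <- rowSums(J2 * Resid)
      d11 <- a11 * (1 + lambda)
      d22 <- a22 * (1 + lambda)
      det <- d11 * d22 - a12^2
      det[abs(det) < 1e-300] <- NA
      dA <- (d22 * g1 - a12 * g2) / det
      dR <- (d11 * g2 - a12 * g1) / det
      dA[is.na(dA)] <- 0; dR[is.na(dR)] <- 0
      A_new <- A + dA
      R_new <- R + dR
      bad <- !is.finite(A_new) | !is.finite(R_new) | R_new <= 0 | A_new <= 0
      A_new[bad] <- A[bad]; R_new[bad] <- R[bad]
      f_new <- sse(A_new, R_new)
      better <- f_new < f_old & !bad
      A[better] <- A_new[better]; R[better] <- R_new[better]
      f_old[better] <- f_new[better]
      lambda <- ifelse(better, pmax(lambda / 3, 1e-10),
                       pmin(lambda * 5, 1e8))
      if (max(abs(c(dA[better], dR[better])), 0) < 1e-12) break
    }
    E <- exp(-outer(R, t))
    ss_res <- rowSums((Y - A * E)^2)
    ss_tot <- rowSums((Y - rowMeans(Y))^2)
    r2v <- 1 - ss_res / ss_tot
    valid <- R > 1e-6                              # reject flat pixels
    t1rho[idx[valid]] <- 1 / R[valid]
    s0[idx[valid]] <- A[valid]
    r2[idx[valid]] <- r2v[valid]
    ok[idx[!valid]] <- FALSE
  }
  structure(list(t1rho = matrix(t1rho, dims[1], dims[2]),
                 s0 = matrix(s0, dims[1], dims[2]),
                 r2 = matrix(r2, dims[1], dims[2]),
                 mask = matrix(ok, dims[1], dims[2]),
                 f_SL = series$f_SL, fov = series$fov),
            class = "t1rho_map")
}

#' Pixel-wise linear T1rho dispersion fit
#'
#' Ordinary least squares of T1rho against spin-lock amplitude (in kHz, so
#' the slope is in ms/kHz) across two or more co-registered T1rho maps:
#' T1rho(f_SL) = offset + slope * f_SL. Pixels are fitted only where every
#' input map's mask is set.
#'
#' @param maps list of `t1rho_map` objects with distinct `f_SL`.
#' @return A `dispersion_map`: matrices `offset` (ms), `slope` (ms/kHz),
#'   `r2_disp`, logical `mask`, and `f_SL_list` (Hz).
#' @export
fit_dispersion <- function(maps) {
  stopifnot(length(maps) >= 2, all(vapply(maps, inherits, TRUE, "t1rho_map")))
  f <- vapply(maps, function(m) m$f_SL, 0) / 1000  # kHz
  if (anyDuplicated(f)) stop("maps must have distinct f_SL")
  dims <- dim(maps[[1]]$t1rho)
  Y <- vapply(maps, function(m) as.vector(m$t1rho), numeric(prod(dims)))
  mask <- Reduce(`&`, lapply(maps, function(m) as.vector(m$mask)))
  fc <- f - mean(f)
  slope <- as.vector(Y %*% fc) / sum(fc^2)
  offset <- rowMeans(Y) - slope * mean(f)
  fitted <- outer(slope, f) + offset
  ss_res <- rowSums((Y - fitted)^2)
  ss_tot <- rowSums((Y - rowMeans(Y))^2)
  r2 <- 1 - ss_res / pmax(ss_tot, .Machine$double.eps)
  slope[!mask] <- offset[!mask] <- r2[!mask] <- NA_real_
  structure(list(offset = matrix(offset, dims[1], dims[2]),
                 slope = matrix(slope, dims[1], dims[2]),
                 r2_disp = matrix(r2, dims[1], dims[2]),
                 mask = matrix(mask, dims[1], dims[2]),
                 f_SL_list = f * 1000),
            class = "dispersion_map")
}

#' Signal-to-noise ratio from signal and noise masks
#'
#' Mean over the pooled signal-mask pixels divided by the standard deviation
#' over the noise-mask pixels, on a magnitude image.
#'
#' @param image magnitude image matrix.
#' @param signal_masks list of logical matrices (pooled).
#' @param noise_mask logical matrix, disjoint from all signal masks.
#' @return SNR (a ratio).
#' @export
snr_metric <- function(image, signal_masks, noise_mask) {
  if (!is.list(signal_masks)) signal_masks <- list(signal_masks)
  sig <- Reduce(`|`, signal_masks)
  if (!any(sig) || !any(noise_mask)) stop("masks must be nonempty")
  if (any(sig & noise_mask)) stop("signal and noise masks must be disjoint")
  s <- mean(image[sig])
  n <- stats::sd(image[noise_mask])
  if (n == 0) stop("noise mask has zero variance; SNR undefined")
  s / n
}

#' Pixel-wise relative quantification error over an ROI
#'
#' Computes 100 * (test - ref) / ref per pixel and reports mean and standard
#' deviation over the ROI (restricted to pixels where both maps are fitted).
#'
#' @param map_test,map_ref `t1rho_map` objects on the same grid (or plain
#'   matrices).
#' @param roi logical matrix selecting the region of interest.
#' @param label optional ROI label.
#' @return A `roi_report`: list with `mean`, `std` (percent), `n_pixels`,
#'   `label`.
#' @export
delta_q <- function(map_test, map_ref, roi, label = "") {
  test <- if (inherits(map_test, "t1rho_map")) map_test$t1rho else map_test
  ref <- if (inherits(map_ref, "t1rho_map")) map_ref$t1rho else map_ref
  if (!all(dim(test) == dim(ref)) || !all(dim(test) == dim(roi)))
    stop("maps and ROI must share one grid")
  sel <- roi & is.finite(test) & is.finite(ref)
  if (!any(sel)) stop("ROI contains no fitted pixels")
  if (any(ref[sel] == 0)) stop("reference contains zeros in the ROI")
  dq <- 100 * (test[sel] - ref[sel]) / ref[sel]
  structure(list(mean = mean(dq), std = stats::sd(dq),
                 n_pixels = sum(sel), label = label),
            class = "roi_report")
}

#' @export
print.roi_report <- function(x, ...) {
  cat(sprintf("ROI %s: dQ = %+.2f +- %.2f %% (n = %d)\n",
              x$label, x$mean, x$std, x$n_pixels))
  invisible(x)
}

#' Circular ROI mask on the image grid
#'
#' @param matrix raster size, pixels.
#' @param fov field of view, mm.
#' @param center ROI center (x, y), mm, FOV-centered.
#' @param radius ROI radius, mm.
#' @return Logical matrix.
#' @export
disk_mask <- function(matrix, fov, center, radius) {
  d <- fov / matrix
  u <- (seq_len(matrix) - (matrix / 2 + 1)) * d
  X <- outer(u, rep(1, matrix))
  Y <- outer(rep(1, matrix), u)
  (X - center[1])^2 + (Y - center[2])^2 <= radius^2
}

#' Erode a logical mask by a number of pixels
#'
#' A pixel survives if every pixel within chessboard distance `px` is in the
#' mask; used to restrict ROIs to shape interiors away from edges.
#'
#' @param mask logical matrix.
#' @param px erosion radius, pixels.
#' @return Logical matrix.
#' @export
erode_mask <- function(mask, px = 2) {
  out <- mask
  n1 <- nrow(mask); n2 <- ncol(mask)
  for (dx in -px:px) {
    for (dy in -px:px) {
      sh <- matrix(FALSE, n1, n2)
      xs <- seq_len(n1) + dx
      ys <- seq_len(n2) + dy
      okx <- xs >= 1 & xs <= n1
      oky <- ys >= 1 & ys <= n2
      sh[okx, oky] <- mask[xs[okx], ys[oky]]
      out <- out & sh
    }
  }
  out
}
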