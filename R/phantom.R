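## Digital phantoms and the radial k-space forward model. The phantom is
## rasterized on the reconstruction grid; each spoke's k-space line is the
## forward NUFFT of the image whose per-pixel intensity equals the
## Bloch-predicted signal of that spoke's (window, readout) position for the
## pixel's tissue. This is the desk-scale stand-in for scanner data.

#' Define a geometric digital phantom
#'
#' @param shapes list of shapes; each shape is a list with `type`
#'   (`"disk"` or `"annulus"`), `center` (x, y in mm, FOV-centered),
#'   `radius` (disk, mm) or `radii` (annulus, `c(inner, outer)`, mm), and
#'   `tissue` (a [tissue_params()]). Later shapes overwrite earlier ones on
#'   overlap; the background has zero signal.
#' @param fov field of view, mm.
#' @param matrix raster size, pixels.
#' @return A `phantom_definition`.
#' @export
phantom_definition <- function(shapes, fov, matrix) {
  for (s in shapes) {
    stopifnot(s$type %in% c("disk", "annulus"),
              inherits(s$tissue, "tissue_params"))
    r_out <- if (s$type == "disk") s$radius else s$radii[2]
    if (any(abs(s$center) + r_out > fov / 2))
      stop("shape extends outside the field of view")
  }
  structure(list(shapes = shapes, fov = fov, matrix = as.integer(matrix)),
            class = "phantom_definition")
}

#' Four-tube BSA relaxometry phantom
#'
#' Emulates a quadratic array of four 17 mm cylindrical tubes filled with
#' bovine serum albumin at 10/15/20/25% concentration. The dispersion
#' parameters default to reference turbo-spin-echo values for these
#' concentrations (offset T1rho0 of 82.60/51.51/36.11/27.00 ms and slope
#' m1rho of 12.81/8.42/5.73/4.59 ms/kHz); T1 defaults to 1400 ms for all
#' tubes. Tube centers sit at (+-9.6, +-9.6) mm.
#'
#' @param fov field of view, mm.
#' @param matrix raster size, pixels.
#' @param T1 longitudinal relaxation time of all tubes, ms.
#' @return A `phantom_definition` with four disk shapes labelled by
#'   concentration.
#' @export
make_bsa_phantom <- function(fov = 38.4, matrix = 128, T1 = 1400) {
  conc <- c("10%", "15%", "20%", "25%")
  T1rho0 <- c(82.60, 51.51, 36.11, 27.00)
  m1rho <- c(12.81, 8.42, 5.73, 4.59)
  centers <- list(c(-9.6, 9.6), c(9.6, 9.6), c(-9.6, -9.6), c(9.6, -9.6))
  shapes <- lapply(1:4, function(i) {
    list(type = "disk", center = centers[[i]], radius = 17 / 2,
         tissue = tissue_params(T1 = T1, T1rho0 = T1rho0[i],
                                m1rho = m1rho[i]),
         label = conc[i])
  })
  phantom_definition(shapes, fov, matrix)
}

#' Cardiac-like ring phantom (myocardium around blood pool)
#'
#' A short-axis left-ventricle-like geometry: a central blood-pool disk
#' (T1rho0 = 48.72 ms, m1rho = 21.57 ms/kHz) surrounded by a myocardial
#' annulus (T1rho0 = 32.73 ms, m1rho = 4.76 ms/kHz), both with T1 = 1400 ms.
#' At f_SL = 1500 Hz the myocardial effective T1rho is 39.87 ms, in the
#' range reported for murine left ventricle.
#'
#' @param fov field of view, mm.
#' @param matrix raster size, pixels.
#' @return A `phantom_definition` with a disk ("blood") and an annulus
#'   ("myocardium").
#' @export
make_cardiac_phantom <- function(fov = 32, matrix = 128) {
  shapes <- list(
    list(type = "disk", center = c(0, 0), radius = 3,
         tissue = tissue_params(T1 = 1400, T1rho0 = 48.72, m1rho = 21.57),
         label = "blood"),
    list(type = "annulus", center = c(0, 0), radii = c(3, 5),
         tissue = tissue_params(T1 = 1400, T1rho0 = 32.73, m1rho = 4.76),
         label = "myocardium"))
  phantom_definition(shapes, fov, matrix)
}

#' Rasterize a phantom into per-shape masks
#'
#' Pixel centers are at FOV-centered coordinates `u * fov/matrix` with
#' `u = -matrix/2 ... matrix/2 - 1`, matching the NUFFT image convention.
#'
#' @param phantom a `phantom_definition`.
#' @return List with `masks` (list of logical matrices, one per shape, after
#'   later-shape-wins overlap resolution) and `support` (union mask).
#' @export
rasterize_phantom <- function(phantom) {
  N <- phantom$matrix
  d <- phantom$fov / N
  u <- (seq_len(N) - (N / 2 + 1)) * d
  X <- outer(u, rep(1, N))
  Y <- outer(rep(1, N), u)
  masks <- lapply(phantom$shapes, function(s) {
    r2 <- (X - s$center[1])^2 + (Y - s$center[2])^2
    if (s$type == "disk") r2 <= s$radius^2
    else r2 <= s$radii[2]^2 & r2 > s$radii[1]^2
  })
  # later shapes overwrite earlier ones
  if (length(masks) > 1) {
    for (i in seq_len(length(masks) - 1)) {
      over <- Reduce(`|`, masks[(i + 1):length(masks)])
      masks[[i]] <- masks[[i]] & !over
    }
  }
  list(masks = masks, support = Reduce(`|`, masks))
}

#' Ground-truth weighted reference images
#'
#' Per-pixel first-readout steady-state signal for each spin-lock time:
#' the "fully sampled, correctly weighted" reference an ideal acquisition
#' would produce, used in place of a scanner reference when scoring the
#' reconstruction.
#'
#' @param phantom a `phantom_definition`.
#' @param seq a [sequence_params()] object.
#' @param f_SL spin-lock amplitude, Hz.
#' @return An `image_series` (magnitude) with one image per t_SL.
#' @export
ground_truth_images <- function(phantom, seq, f_SL = seq$f_SL_list[1]) {
  stopifnot(inherits(phantom, "phantom_definition"),
            inherits(seq, "sequence_params"))
  ras <- rasterize_phantom(phantom)
  N <- phantom$matrix
  W <- length(seq$t_SL_list)
  a <- seq$alpha * pi / 180
  images <- array(0, dim = c(N, N, W))
  for (i in seq_along(phantom$shapes)) {
    tis <- phantom$shapes[[i]]$tissue
    T1rho <- t1rho_effective(tis, f_SL)
    for (w in seq_len(W)) {
      s1 <- steady_state_signals(a, seq$TR, seq$t_rec, tis$T1, T1rho,
                                 seq$t_SL_list[w], seq$NR, tis$M0)[1, 1]
      img <- images[, , w]
      img[ras$masks[[i]]] <- s1
      images[, , w] <- img
    }
  }
  structure(list(images = images, t_SL_list = seq$t_SL_list, f_SL = f_SL,
                 fov = phantom$fov, mode = "ground_truth", f_nyq = NA),
            class = "image_series")
}

#' Reference image series through the full-sampling radial chain
#'
#' The in-simulation stand-in for a fully sampled reference acquisition:
#' each ground-truth weighted image (correct contrast on every spoke, no
#' view sharing) is forward-projected onto the complete radial trajectory
#' and reconstructed with the same density-compensated adjoint NUFFT used
#' by [reconstruct_series()]. Quantification errors that any band-limited
#' magnitude acquisition shares (Gibbs cross-talk between structures,
#' magnitude-floor effects) are therefore present in both the reference and
#' the KWIC reconstruction and cancel in [delta_q()] comparisons — which is
#' how scanner studies score against a fully sampled reference scan.
#'
#' @param phantom a `phantom_definition`.
#' @param pattern a [build_pattern()] result.
#' @return An `image_series` (magnitude), one image per t_SL.
#' @export
reference_series <- function(phantom, pattern) {
  stopifnot(inherits(phantom, "phantom_definition"),
            inherits(pattern, "sampling_pattern"))
  seqp <- attr(pattern, "seq")
  if (phantom$matrix != seqp$matrix)
    stop("phantom and protocol matrix sizes differ")
  N <- phantom$matrix
  f_SL <- attr(pattern, "f_SL")
  gt <- ground_truth_images(phantom, seqp, f_SL)
  os <- seqp$os_read
  k_radii <- seq(-N / 2, N / 2 - 1 / os, by = 1 / os)
  phi <- pattern$angle_deg * pi / 180
  kx <- outer(cos(phi), k_radii)
  ky <- outer(sin(phi), k_radii)
  plan <- nufft_plan(as.vector(kx), as.vector(ky), N)
  full <- structure(list(weighting = 0L, f_nyq = NA_real_, matrix = N,
                         annuli = data.frame(n_phi = nrow(pattern),
                                             r_lo = 0, r_hi = Inf),
                         spoke_sets = list(pattern$chronological_index)),
                    class = "kwic_filter")
  wt <- as.vector(density_weights(full, k_radii, pattern$angle_deg))
  W <- length(seqp$t_SL_list)
  images <- array(0, dim = c(N, N, W))
  for (w in seq_len(W)) {
    kt <- nufft_forward(plan, gt$images[, , w])
    images[, , w] <- Mod(nufft_adjoint(plan, kt * wt))
  }
  structure(list(images = images, t_SL_list = seqp$t_SL_list, f_SL = f_SL,
                 fov = phantom$fov, mode = "reference", f_nyq = NA),
            class = "image_series")
}

#' Simulate radial k-space data for a phantom and sampling pattern
#'
#' For every spoke, the sampled k-space line is the nonuniform Fourier
#' transform of the image whose pixel intensities equal the Bloch-engine
#' signal of that spoke's chronological (window, readout) position for the
#' pixel's tissue — i.e. the per-spoke scale factors are exactly the
#' [simulate_timeline()] outputs. Optionally adds i.i.d. complex Gaussian
#' noise (standard deviation `noise_sigma` per real/imaginary channel per
#' sample).
#'
#' Implementation: one forward NUFFT per distinct tissue mask evaluated at
#' all sample locations, then a per-spoke linear combination with the
#' predicted signals.
#'
#' @param phantom a `phantom_definition`.
#' @param pattern a [build_pattern()] result (matrix/FOV conventions must
#'   match the phantom).
#' @param noise_sigma standard deviation of the added complex Gaussian
#'   noise, in units of the noiseless k-space values.
#' @param seed RNG seed; required when `noise_sigma > 0`.
#' @param oracle use the direct NDFT forward instead of gridding (slow).
#' @return A `radial_kspace` object: list with `samples`
#'   (`[n_spokes x n_read]` complex, `n_read = os_read * matrix`),
#'   `angles_deg`, `k_radii` (`-N/2 ... N/2 - 1/os_read` in steps of
#'   `1/os_read` cycles/FOV), `pattern`; attributes `seq`, `f_SL`, `mode`,
#'   `noise_sigma`.
#' @export
simulate_kspace <- function(phantom, pattern, noise_sigma = 0, seed = NULL,
                            oracle = FALSE) {
  stopifnot(inherits(phantom, "phantom_definition"),
            inherits(pattern, "sampling_pattern"))
  seqp <- attr(pattern, "seq")
  if (phantom$matrix != seqp$matrix)
    stop("phantom and protocol matrix sizes differ")
  if (noise_sigma > 0 && is.null(seed))
    stop("a seed is required when noise_sigma > 0")
  N <- phantom$matrix
  f_SL <- attr(pattern, "f_SL")
  ras <- rasterize_phantom(phantom)
  n_spokes <- nrow(pattern)
  os <- seqp$os_read
  k_radii <- seq(-N / 2, N / 2 - 1 / os, by = 1 / os)
  phi <- pattern$angle_deg * pi / 180
  kx <- outer(cos(phi), k_radii)
  ky <- outer(sin(phi), k_radii)

  # per-tissue unit-intensity k-space at all sample positions
  plan <- if (!oracle) nufft_plan(as.vector(kx), as.vector(ky), N)
  n_read <- length(k_radii)
  samples <- matrix(0 + 0i, n_spokes, n_read)
  for (i in seq_along(phantom$shapes)) {
    tis <- phantom$shapes[[i]]$tissue
    pred <- simulate_timeline(seqp, tis, f_SL)
    mask_img <- matrix(0, N, N)
    mask_img[ras$masks[[i]]] <- 1
    kt <- if (oracle) ndft_forward(mask_img, as.vector(kx), as.vector(ky))
          else nufft_forward(plan, mask_img)
    samples <- samples + matrix(kt, n_spokes, n_read) * pred$signal
  }
  if (noise_sigma > 0) {
    set.seed(seed)
    samples <- samples +
      complex(real = stats::rnorm(length(samples), sd = noise_sigma),
              imaginary = stats::rnorm(length(samples), sd = noise_sigma))
  }
  structure(list(samples = samples, angles_deg = pattern$angle_deg,
                 k_radii = k_radii, pattern = pattern),
            class = "radial_kspace",
            seq = seqp, f_SL = f_SL, mode = attr(pattern, "mode"),
            noise_sigma = noise_sigma, seed = seed)
}
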