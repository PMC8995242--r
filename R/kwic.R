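## KWIC (k-space weighted image contrast) view-sharing reconstruction.
##
## For each T1rho weighting, the k-space center is sampled exclusively by the
## n_prep first readouts acquired directly after the spin-lock preparation of
## that weighting, which fixes the image contrast. The periphery is shared
## with neighboring golden-angle indices (and thus, after Bloch sorting,
## with the spokes closest in predicted signal), in concentric annuli whose
## spoke counts follow the Fibonacci sequence so the azimuthal sampling
## density stays homogeneous. Every annulus satisfies the azimuthal Nyquist
## condition n_phi > pi * r * f_nyq at its outer radius.

fibonacci_upto <- function(max_needed, start_above = 1) {
  f <- c(1, 2)
  while (f[length(f)] < max_needed) f <- c(f, sum(utils::tail(f, 2)))
  f[f > start_above]
}

#' Design KWIC view-sharing filters, one per weighting
#'
#' Builds, for every spin-lock weighting in the pattern, the annular
#' spoke-sharing specification: the innermost annulus contains exactly the
#' `n_prep` first-readout spokes of the target weighting and extends to
#' radius `n_prep / (pi * f_nyq)`; successive annuli use the next Fibonacci
#' spoke counts (21, 34, 55, ...), each extending to `n_phi / (pi * f_nyq)`,
#' until the outermost annulus covers the k-space corner radius `matrix/2`.
#' Spoke sets grow around the center block by golden-angle-index adjacency
#' (equal to predicted-signal adjacency after Bloch sorting), clipped at the
#' index bounds with the remainder taken from the open side.
#'
#' @param pattern a [build_pattern()] result.
#' @param matrix image matrix size; default from the pattern's protocol.
#' @param f_nyq Nyquist safety factor (> 0); the azimuthal sampling condition
#'   is `n_phi > pi * r * f_nyq`.
#' @return A list of `kwic_filter` objects (one per weighting), each with
#'   `weighting`, `f_nyq`, `annuli` (data frame: `n_phi`, `r_lo`, `r_hi`) and
#'   `spoke_sets` (list of chronological spoke indices, nested increasing).
#' @export
design_kwic <- function(pattern, matrix = attr(pattern, "seq")$matrix,
                        f_nyq = 1.1) {
  stopifnot(inherits(pattern, "sampling_pattern"), f_nyq > 0)
  seqp <- attr(pattern, "seq")
  W <- length(seqp$t_SL_list)
  n_spokes <- nrow(pattern)
  r_edge <- matrix / 2

  # annulus spoke counts: center block, then Fibonacci numbers above it
  n0 <- seqp$n_prep
  counts <- n0
  if (n0 / (pi * f_nyq) < r_edge) {
    fibs <- fibonacci_upto(ceiling(pi * f_nyq * r_edge) + 1, start_above = n0)
    for (f in fibs) {
      counts <- c(counts, f)
      if (f / (pi * f_nyq) >= r_edge) break
    }
  }
  need <- counts[length(counts)]
  if (need / (pi * f_nyq) < r_edge || need > n_spokes)
    stop(sprintf(paste0("cannot satisfy the Nyquist condition at the k-space",
                        " edge: need at least %d spokes per annulus but only",
                        " %d are available"),
                 max(need, ceiling(pi * f_nyq * r_edge)), n_spokes))

  r_hi <- counts / (pi * f_nyq)
  r_hi[length(r_hi)] <- Inf                       # outermost covers the edge
  r_lo <- c(0, r_hi[-length(r_hi)])

  lapply(seq_len(W), function(w) {
    center <- pattern$chronological_index[pattern$weighting_id == w &
                                            pattern$readout_pos == 1L]
    gi <- pattern$golden_index
    # distance of every golden index to the center block's index set
    member <- logical(n_spokes)
    member[gi[center]] <- TRUE
    d <- dist_to_set(member)
    add_order <- order(d, seq_len(n_spokes))       # golden-index order
    spoke_of_gi <- integer(n_spokes)
    spoke_of_gi[gi] <- pattern$chronological_index
    sets <- lapply(counts, function(np) {
      sel_gi <- add_order[seq_len(np)]
      sort(spoke_of_gi[sel_gi])
    })
    structure(list(weighting = w, f_nyq = f_nyq, matrix = matrix,
                   annuli = data.frame(n_phi = counts, r_lo = r_lo,
                                       r_hi = r_hi),
                   spoke_sets = sets),
              class = "kwic_filter")
  })
}

# distance of each position to the nearest TRUE, by two linear sweeps
dist_to_set <- function(member) {
  n <- length(member)
  d <- rep(Inf, n)
  d[member] <- 0
  for (i in 2:n) d[i] <- min(d[i], d[i - 1] + 1)
  for (i in (n - 1):1) d[i] <- min(d[i], d[i + 1] + 1)
  d
}

#' Density-compensation weights for a KWIC-filtered radial acquisition
#'
#' Radial ramp weights with per-spoke azimuthal cells: a sample at radius
#' `r > 0` carries the k-space ring-segment area `|r| * dphi` (Cartesian
#' cell units), where `dphi` is the angular Voronoi cell of the sample's
#' projection direction within its annulus' spoke set (each spoke
#' contributes the two opposite directions `phi` and `phi + 180`). For a
#' perfectly uniform set this reduces to `pi * r / n_phi`; for golden-angle
#' sets, where consecutive-index subsets exhibit two distinct azimuthal gap
#' sizes, the cell-based weights correct the local density imbalance. The
#' DC sample carries the disk-area element `pi / 4 / n_phi_inner`. Samples
#' not admitted by the filter get weight 0.
#'
#' @param filter a `kwic_filter`.
#' @param k_radii signed radial sample coordinates, cycles/FOV (length
#'   `n_read`).
#' @param angles_deg per-spoke projection angles, degrees (length
#'   `n_spokes`).
#' @return Weight matrix `[n_spokes x n_read]`; zero entries mark samples
#'   excluded by the filter.
#' @export
density_weights <- function(filter, k_radii, angles_deg) {
  stopifnot(inherits(filter, "kwic_filter"))
  n_spokes <- length(angles_deg)
  ann <- filter$annuli
  dk <- min(diff(sort(unique(k_radii))))           # radial sample spacing
  r <- abs(k_radii)
  pos <- k_radii > 0
  neg <- k_radii < 0
  dc <- k_radii == 0
  wmat <- matrix(0, n_spokes, length(k_radii))
  for (j in seq_len(nrow(ann))) {
    in_band <- r >= ann$r_lo[j] & r < ann$r_hi[j]
    if (!any(in_band)) next
    spokes <- filter$spoke_sets[[j]]
    # angular Voronoi cells on the circle of projection directions
    dirs <- c(angles_deg[spokes], angles_deg[spokes] + 180) %% 360
    ord <- order(dirs)
    ds <- dirs[ord] * pi / 180
    gaps <- diff(c(ds, ds[1] + 2 * pi))            # gap to next direction
    cell <- (gaps + c(gaps[length(gaps)], gaps[-length(gaps)])) / 2
    cell_of <- numeric(length(dirs))
    cell_of[ord] <- cell
    np <- length(spokes)
    cell_pos <- cell_of[seq_len(np)]               # direction phi
    cell_neg <- cell_of[np + seq_len(np)]          # direction phi + 180
    bp <- in_band & pos
    if (any(bp)) wmat[spokes, bp] <- outer(cell_pos, r[bp]) * dk
    bn <- in_band & neg
    if (any(bn)) wmat[spokes, bn] <- outer(cell_neg, r[bn]) * dk
    if (any(in_band & dc))
      wmat[spokes, in_band & dc] <- pi / 4 * dk^2 / ann$n_phi[1]
  }
  wmat
}

#' Audit the azimuthal Nyquist condition of a KWIC filter
#'
#' Checks that every admitted sample lies in an annulus whose spoke count
#' satisfies `n_phi > pi * |k| * f_nyq` at that sample's radius. Annulus
#' outer radii are defined as `n_phi / (pi * f_nyq)` with half-open bands,
#' so the condition is strict for all admitted radii.
#'
#' @param filter a `kwic_filter`.
#' @param k_radii signed radial sample coordinates, cycles/FOV.
#' @return `TRUE` (invisibly) if the audit passes; otherwise an error
#'   describing the first violating annulus.
#' @export
kwic_audit <- function(filter, k_radii) {
  stopifnot(inherits(filter, "kwic_filter"))
  r <- abs(k_radii)
  ann <- filter$annuli
  for (j in seq_len(nrow(ann))) {
    r_adm <- r[r >= ann$r_lo[j] & r < ann$r_hi[j]]
    if (length(r_adm) && !all(ann$n_phi[j] > pi * r_adm * filter$f_nyq))
      stop(sprintf("annulus %d (n_phi = %d) violates Nyquist at r = %.3f",
                   j, ann$n_phi[j], max(r_adm)))
  }
  invisible(TRUE)
}

#' Reconstruct the T1rho-weighted image series from radial k-space
#'
#' For each weighting, admits only the (spoke, sample) pairs selected by the
#' corresponding KWIC filter, applies the annulus-normalized ramp density
#' weights, and applies the adjoint gridding NUFFT. Deterministic for fixed
#' input.
#'
#' @param kspace a `radial_kspace` bundle (see [simulate_kspace()]).
#' @param filters list of `kwic_filter`, one per weighting, from
#'   [design_kwic()].
#' @param magnitude return magnitude images (default) or complex.
#' @param oracle if `TRUE`, use the direct NDFT adjoint instead of gridding
#'   (slow; for validation on small matrices).
#' @return An `image_series`: list with `images` (array `[N x N x W]`),
#'   `t_SL_list`, `f_SL`, and provenance fields.
#' @export
reconstruct_series <- function(kspace, filters, magnitude = TRUE,
                               oracle = FALSE) {
  stopifnot(inherits(kspace, "radial_kspace"))
  N <- filters[[1]]$matrix
  n_spokes <- nrow(kspace$samples)
  n_read <- ncol(kspace$samples)
  if (length(kspace$k_radii) != n_read)
    stop("k_radii length does not match the sample matrix")
  phi <- kspace$angles_deg * pi / 180
  kx <- outer(cos(phi), kspace$k_radii)            # [n_spokes x n_read]
  ky <- outer(sin(phi), kspace$k_radii)

  W <- length(filters)
  images <- array(if (magnitude) 0 else 0i, dim = c(N, N, W))
  for (w in seq_len(W)) {
    wt <- density_weights(filters[[w]], kspace$k_radii, kspace$angles_deg)
    sel <- which(wt > 0)
    y <- kspace$samples[sel] * wt[sel]
    img <- if (oracle) {
      ndft_adjoint(y, kx[sel], ky[sel], N)
    } else {
      nufft_adjoint(nufft_plan(kx[sel], ky[sel], N), y)
    }
    images[, , w] <- if (magnitude) Mod(img) else img
  }
  structure(list(images = images,
                 t_SL_list = attr(kspace, "seq")$t_SL_list,
                 f_SL = attr(kspace, "f_SL"),
                 fov = attr(kspace, "seq")$fov,
                 mode = attr(kspace, "mode"),
                 f_nyq = filters[[1]]$f_nyq),
            class = "image_series")
}
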