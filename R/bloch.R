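## Longitudinal-only Bloch engine for the spin-lock-prepared radial GRE
## sequence. Perfect spoiling is assumed, so only M_z is tracked:
##   recovery:    M <- M0 + (M - M0) * exp(-t_rec / T1)
##   preparation: M <- M * exp(-t_SL / T1rho(f_SL))
##   readout k:   emit S_k = M * sin(alpha); M <- M0 + (M*cos(alpha) - M0) * exp(-TR/T1)
## The balanced spin-lock module is treated as ideal (B0/B1 imperfections,
## T2rho and off-resonance neglected); TE/T2* decay is a constant factor
## absorbed into M0.

# Affine map of one full preparation cycle acting on the magnetization just
# before the recovery period: M_out = A * M_in + B. Exact, so steady states
# are available in closed form as M* = B / (1 - A).
cycle_affine <- function(E_rec, E_sl, cos_a, E_tr, NR, M0 = 1) {
  g <- cos_a * E_tr
  # readout train: M -> g^NR * M + M0 * (1 - E_tr) * (1 + g + ... + g^(NR-1))
  geom <- ifelse(abs(1 - g) < 1e-14, NR, (1 - g^NR) / (1 - g))
  A_ro <- g^NR
  B_ro <- M0 * (1 - E_tr) * geom
  # recovery then SL then readout train
  A <- A_ro * E_sl * E_rec
  B <- A_ro * E_sl * M0 * (1 - E_rec) + B_ro
  list(A = A, B = B)
}

#' Simulate the chronological per-spoke signal timeline
#'
#' Runs the longitudinal Bloch recursion over the full acquisition: `n_dummy`
#' discarded cycles (using the parameters of the first weighting block),
#' followed by the weighting blocks in `seq$weighting_order`, each consisting
#' of `n_prep` identical preparation experiments with `NR` readouts. The
#' returned signal is the transverse magnitude `M_z * sin(alpha)` at each
#' readout, in chronological order.
#'
#' @param seq a [sequence_params()] object.
#' @param tissue a [tissue_params()] object.
#' @param f_SL spin-lock amplitude, Hz; enters only through the linear
#'   dispersion model [t1rho_effective()].
#' @return A `data.frame` of class `"signal_prediction"` with one row per
#'   counted spoke (`n_prep * W * NR` rows) and columns
#'   `chronological_index`, `window_id`, `readout_pos`, `weighting_id`,
#'   `signal`. `weighting_id` indexes into `seq$t_SL_list`.
#' @examples
#' seq <- sequence_params(n_prep = 2, t_SL_list = c(10, 40))
#' pred <- simulate_timeline(seq, tissue_params(T1rho0 = 40))
#' head(pred)
#' @export
simulate_timeline <- function(seq, tissue, f_SL = seq$f_SL_list[1]) {
  stopifnot(inherits(seq, "sequence_params"), inherits(tissue, "tissue_params"))
  T1rho <- t1rho_effective(tissue, f_SL)
  a <- seq$alpha * pi / 180
  sa <- sin(a); ca <- cos(a)
  E_tr <- exp(-seq$TR / tissue$T1)
  E_rec <- exp(-seq$t_rec / tissue$T1)
  M0 <- tissue$M0
  W <- length(seq$t_SL_list)
  NR <- seq$NR

  block_w <- seq$weighting_order                       # weighting id per block
  cycles_w <- c(rep(block_w[1], seq$n_dummy), rep(block_w, each = seq$n_prep))
  counted <- c(rep(FALSE, seq$n_dummy), rep(TRUE, W * seq$n_prep))
  E_sl_all <- exp(-seq$t_SL_list / T1rho)

  n_out <- seq$n_prep * W * NR
  signal <- numeric(n_out)
  window_id <- integer(n_out)
  readout_pos <- integer(n_out)
  weighting_id <- integer(n_out)

  M <- M0
  out <- 0L
  win <- 0L
  for (i in seq_along(cycles_w)) {
    w <- cycles_w[i]
    M <- M0 + (M - M0) * E_rec
    M <- M * E_sl_all[w]
    if (counted[i]) win <- win + 1L
    for (k in seq_len(NR)) {
      s <- M * sa
      if (counted[i]) {
        out <- out + 1L
        signal[out] <- s
        window_id[out] <- win
        readout_pos[out] <- k
        weighting_id[out] <- w
      }
      M <- M0 + (M * ca - M0) * E_tr
    }
  }
  structure(
    data.frame(chronological_index = seq_len(n_out),
               window_id = window_id, readout_pos = readout_pos,
               weighting_id = weighting_id, signal = signal),
    class = c("signal_prediction", "data.frame"),
    f_SL = f_SL)
}

# Steady-state readout signals for one weighting block repeated indefinitely:
# exact fixed point of the per-cycle affine map. Vectorized over alpha.
# Returns a matrix [length(alpha_rad) x NR] of signals S_k.
steady_state_signals <- function(alpha_rad, TR, t_rec, T1, T1rho, t_SL, NR,
                                 M0 = 1) {
  sa <- sin(alpha_rad); ca <- cos(alpha_rad)
  E_tr <- exp(-TR / T1)
  E_rec <- exp(-t_rec / T1)
  E_sl <- exp(-t_SL / T1rho)
  af <- cycle_affine(E_rec, E_sl, ca, E_tr, NR, M0)
  M_star <- af$B / (1 - af$A)                 # fixed point before recovery
  M <- (M0 + (M_star - M0) * E_rec) * E_sl    # after recovery + preparation
  S <- matrix(0, length(alpha_rad), NR)
  for (k in seq_len(NR)) {
    S[, k] <- M * sa
    M <- M0 + (M * ca - M0) * E_tr
  }
  S
}

#' Optimal readout flip angle ignoring relaxation
#'
#' For a train of `NR` identical pulses acting on a fixed prepared
#' magnetization with no recovery between pulses, the mean readout signal is
#' proportional to sum_{k=1..NR} sin(alpha) cos(alpha)^(k-1). This returns
#' the maximizing angle on (0, 90] degrees.
#'
#' @param NR number of readouts per preparation.
#' @param step grid resolution in degrees (deterministic grid search).
#' @return Optimal flip angle in degrees, at `step` resolution.
#' @examples
#' optimal_flip_norelax(4)   # 43.51
#' optimal_flip_norelax(1)   # 90
#' @export
optimal_flip_norelax <- function(NR, step = 0.01) {
  if (NR < 1 || NR != round(NR)) stop("NR must be an integer >= 1")
  grid <- seq(step, 90, by = step)
  a <- grid * pi / 180
  ca <- cos(a)
  geom <- ifelse(abs(1 - ca) < 1e-14, NR, (1 - ca^NR) / (1 - ca))
  s <- sin(a) * geom
  grid[which.max(s)]
}

#' Optimal readout flip angle from Bloch simulation
#'
#' Maximizes the mean steady-state readout signal, averaged over all
#' spin-lock times and all `NR` readouts of the train, over a grid of flip
#' angles. Relaxation during the readout train (TR/T1) and incomplete
#' recovery (t_rec/T1) are fully accounted for via the closed-form steady
#' state of the per-cycle magnetization map, which is what repeated identical
#' preparations converge to.
#'
#' @param seq a [sequence_params()] object (TR, t_rec, NR, t_SL_list used).
#' @param tissue a [tissue_params()] object.
#' @param f_SL spin-lock amplitude, Hz.
#' @param alpha_grid candidate flip angles in degrees, within (0, 90].
#' @return The grid angle maximizing the mean signal (first on ties).
#' @examples
#' seq <- sequence_params(TR = 5, t_rec = 1500, NR = 4,
#'                        t_SL_list = seq(4, 60, length.out = 8))
#' myo <- tissue_params(T1 = 1400, T1rho0 = 40)
#' optimal_flip_bloch(seq, myo)   # 39.35
#' @export
optimal_flip_bloch <- function(seq, tissue, f_SL = seq$f_SL_list[1],
                               alpha_grid = seq(0.01, 90, by = 0.01)) {
  stopifnot(inherits(seq, "sequence_params"), inherits(tissue, "tissue_params"))
  if (length(alpha_grid) == 0) stop("alpha_grid must be nonempty")
  if (any(alpha_grid <= 0 | alpha_grid > 90))
    stop("alpha_grid must lie within (0, 90] degrees")
  T1rho <- t1rho_effective(tissue, f_SL)
  a <- alpha_grid * pi / 180
  total <- numeric(length(a))
  for (t_SL in seq$t_SL_list) {
    S <- steady_state_signals(a, seq$TR, seq$t_rec, tissue$T1, T1rho, t_SL,
                              seq$NR, tissue$M0)
    total <- total + rowSums(S)
  }
  alpha_grid[which.max(total)]
}
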