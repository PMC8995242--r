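## Golden-angle schedule generation and spoke sorting.
##
## Each radial readout is assigned a golden-angle index N and the projection
## angle phi = N * 360 / (1 + sqrt(5)) mod 360. "Serial" sorting assigns
## indices chronologically; "Bloch" sorting assigns index 1 to the readout
## with the highest Bloch-predicted signal and proceeds in descending order,
## so image contrast varies smoothly between azimuthally adjacent spokes.

GOLDEN_ANGLE_DEG <- 360 / (1 + sqrt(5))   # 111.2461...

#' Golden-angle projection angle for index N
#'
#' @param N golden-angle index (integer >= 0, vectorized).
#' @return Angle in degrees in [0, 360): `(N * 360 / (1 + sqrt(5))) %% 360`.
#' @examples
#' round(golden_angle(1:3), 2)  # 111.25 222.49 333.74
#' @export
golden_angle <- function(N) {
  if (any(N < 0) || any(N != round(N))) stop("N must be integer >= 0")
  (N * GOLDEN_ANGLE_DEG) %% 360
}

new_sorting_plan <- function(golden_index, mode) {
  n <- length(golden_index)
  structure(
    data.frame(chronological_index = seq_len(n),
               golden_index = as.integer(golden_index),
               angle_deg = golden_angle(golden_index)),
    class = c("sorting_plan", "data.frame"), mode = mode)
}

#' Bloch sorting of a predicted signal timeline
#'
#' Assigns golden-angle index 1 to the spoke with the largest predicted
#' signal, index 2 to the next largest, and so on. Ties (e.g. the plateaus of
#' repeated identical preparations at steady state) are broken by
#' chronological order, so the assignment is stable and deterministic.
#' Reordering the predicted signals by golden index therefore yields a
#' monotonically non-increasing sequence.
#'
#' @param pred a `signal_prediction` from [simulate_timeline()].
#' @return A `sorting_plan` data frame (chronological rows) with columns
#'   `chronological_index`, `golden_index`, `angle_deg`; attribute
#'   `mode = "bloch"`.
#' @export
bloch_sort <- function(pred) {
  stopifnot(inherits(pred, "signal_prediction"), nrow(pred) > 0)
  ord <- order(-pred$signal, pred$chronological_index)
  gi <- integer(nrow(pred))
  gi[ord] <- seq_len(nrow(pred))
  new_sorting_plan(gi, "bloch")
}

#' Serial sorting (conventional golden-angle ordering)
#'
#' Golden-angle indices follow the chronological acquisition order, i.e. the
#' conventional golden-angle scheme (111.25 deg, 222.50 deg, 333.75 deg, ...).
#'
#' @param n_spokes total number of spokes.
#' @return A `sorting_plan` with `golden_index` equal to the chronological
#'   index and `mode = "serial"`.
#' @export
serial_sort <- function(n_spokes) {
  if (n_spokes < 1 || n_spokes != round(n_spokes))
    stop("n_spokes must be an integer >= 1")
  new_sorting_plan(seq_len(n_spokes), "serial")
}

#' Build the full sampling pattern for one spin-lock amplitude
#'
#' Combines the acquisition schedule (windows, readout positions, weighting
#' blocks) with a golden-angle sorting plan. In `"bloch"` mode the plan comes
#' from [bloch_sort()] applied to the Bloch-predicted timeline; in `"serial"`
#' mode indices are chronological. The predicted signal column is attached in
#' both modes (it drives the forward simulator and, in bloch mode, the
#' sorting).
#'
#' @param seq a [sequence_params()] object.
#' @param tissue a [tissue_params()] object (prior used for the prediction).
#' @param f_SL spin-lock amplitude, Hz.
#' @param mode `"bloch"` or `"serial"`.
#' @return A `sampling_pattern` data frame with one row per spoke and columns
#'   `chronological_index`, `window_id`, `readout_pos`, `weighting_id`,
#'   `signal`, `golden_index`, `angle_deg`. Attributes: `mode`, `f_SL`,
#'   `n_preparations`, `n_spokes`, `seq`, `tissue`.
#' @examples
#' seq <- sequence_params()
#' pat <- build_pattern(seq, tissue_params(), mode = "bloch")
#' attr(pat, "n_preparations")  # 104
#' attr(pat, "n_spokes")        # 416
#' @export
build_pattern <- function(seq, tissue, f_SL = seq$f_SL_list[1],
                          mode = c("bloch", "serial")) {
  mode <- match.arg(mode)
  pred <- simulate_timeline(seq, tissue, f_SL)
  plan <- if (mode == "bloch") bloch_sort(pred) else serial_sort(nrow(pred))
  out <- cbind(pred, plan[, c("golden_index", "angle_deg")])
  structure(out,
            class = c("sampling_pattern", "data.frame"),
            mode = mode, f_SL = f_SL,
            n_preparations = seq$n_prep * length(seq$t_SL_list),
            n_spokes = nrow(pred),
            seq = seq, tissue = tissue)
}

#' Protocol acquisition counts and acceleration factor
#'
#' Reports the preparation and spoke counts of the radial protocol, the
#' preparation count of a fully sampled Cartesian comparator with the same
#' matrix and echo-train length (`matrix / NR` phase-encode segments per
#' weighting), and the resulting acceleration factor.
#'
#' @param seq a [sequence_params()] object.
#' @return A list: `n_preparations` (radial, one amplitude), `n_spokes`,
#'   `n_preparations_cartesian`, `n_preparations_dispersion` (all
#'   amplitudes), `acceleration` (Cartesian:radial preparation ratio).
#' @examples
#' pc <- protocol_counts(sequence_params())
#' pc$n_preparations   # 104
#' pc$acceleration     # 32/13 ~ 2.46
#' @export
protocol_counts <- function(seq) {
  stopifnot(inherits(seq, "sequence_params"))
  W <- length(seq$t_SL_list)
  A <- length(seq$f_SL_list)
  seg_cart <- seq$matrix / seq$NR
  list(n_preparations = seq$n_prep * W,
       n_spokes = seq$n_prep * W * seq$NR,
       n_preparations_cartesian = seg_cart * W,
       n_preparations_dispersion = A * W * seq$n_prep,
       acceleration = seg_cart / seq$n_prep)
}

#' Mean deviation from ideal (monotone) sorting
#'
#' Orders the measured per-spoke signals by golden-angle index and measures
#' how far the sequence is from being monotonically non-increasing: for each
#' spoke, the excess of its signal over the running minimum of its
#' predecessors, relative to its own signal, averaged over all spokes. A
#' perfectly sorted (non-increasing) sequence scores 0.
#'
#' @param plan a `sorting_plan` (or `sampling_pattern`).
#' @param measured measured per-spoke signals, chronological order, same
#'   length as the plan.
#' @return Mean relative deviation (a fraction; multiply by 100 for percent).
#' @export
sorting_deviation <- function(plan, measured) {
  stopifnot(inherits(plan, "data.frame"), "golden_index" %in% names(plan))
  if (length(measured) != nrow(plan))
    stop("measured must have one value per spoke of the plan")
  s <- measured[order(plan$golden_index)]
  run_min <- cummin(s)
  prev_min <- c(Inf, run_min[-length(s)])
  dev <- pmax(0, s - prev_min) / s
  dev[1] <- 0
  mean(dev)
}
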