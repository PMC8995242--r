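# Shared small-scale fixtures. Everything is generated in code; sizes are
# kept small so single tests run in seconds.

# 5 x 3 x 4 = 60 spokes: enough for the KWIC edge annulus (55) at matrix 24
small_seq <- function(matrix = 24, n_prep = 5, NR = 4,
                      t_SL_list = c(10, 30, 60), t_rec = 800, ...) {
  sequence_params(matrix = matrix, n_prep = n_prep, NR = NR,
                  t_SL_list = t_SL_list, t_rec = t_rec, fov = 38.4, ...)
}

small_phantom <- function(matrix = 24, fov = 38.4) {
  phantom_definition(list(
    list(type = "disk", center = c(-7, 5), radius = 6,
         tissue = tissue_params(T1 = 1400, T1rho0 = 60, m1rho = 5),
         label = "a"),
    list(type = "disk", center = c(7, -5), radius = 6,
         tissue = tissue_params(T1 = 1400, T1rho0 = 30, m1rho = 5),
         label = "b")), fov = fov, matrix = matrix)
}

# construct a signal_prediction from a bare signal vector
fake_prediction <- function(signal) {
  n <- length(signal)
  structure(data.frame(chronological_index = seq_len(n),
                       window_id = seq_len(n), readout_pos = 1L,
                       weighting_id = 1L, signal = signal),
            class = c("signal_prediction", "data.frame"))
}

# phantom protocol of the tube experiments: long SL times, shorter recovery
phantom_protocol <- function(matrix = 128) {
  sequence_params(matrix = matrix, fov = 38.4, t_rec = 1000,
                  t_SL_list = seq(4, 102, length.out = 8))
}

phantom_prior <- function() tissue_params(T1 = 1400, T1rho0 = 60)
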